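#' Simulate a 3-channel confocal-like z-stack with known ground truth
#'
#' Generates a synthetic image stack mimicking the two tissue geometries used
#' for relative bacterial density measurements: a `"hub"` (roughly spherical
#' somatic cell cluster, the COI, surrounded by an annular band of germline
#' cells, the SC) or an `"egg_chamber"` (ellipsoidal germline interior, the
#' COI, enclosed by a follicle-cell shell, the SC). Bacterial puncta are
#' placed uniformly at random within each region so that the expected COI
#' voxel density divided by the expected SC voxel density equals
#' `true_ratio` before any blur or noise is applied.
#'
#' Channels are: 1 = DNA (cosmetic; not used by the quantification), 2 =
#' boundary marker (outlines the COI for hubs; labels the follicle shell,
#' i.e. the SC itself, for egg chambers), 3 = bacteria.
#'
#' When `noise_sd > 0` each voxel is drawn as Poisson(signal) plus Gaussian
#' read noise of standard deviation `noise_sd`; with `noise_sd = 0` the
#' stack is noiseless. Puncta are rendered as Gaussian blobs of width
#' `psf_sigma_xy`/`psf_sigma_z` voxels, or as single-voxel impulses when the
#' sigmas are zero. Geometry is computed in voxel units; `pixel_size_xy` and
#' `z_step` are carried as metadata only (the density ratio is unitless and
#' cancels pixel geometry).
#'
#' @param tissue `"hub"` or `"egg_chamber"`.
#' @param dim integer vector `c(nz, ny, nx)` of voxel counts.
#' @param true_ratio target ratio of COI to SC expected bacterial voxel
#'   density (>= 0; 0 means an uninfected COI).
#' @param puncta_density_sc expected puncta per SC voxel.
#' @param puncta_intensity_mean,puncta_intensity_sd punctum intensity
#'   distribution (arbitrary units; truncated at zero).
#' @param background constant background level added to every channel.
#'   Because the density ratio sums raw intensities, a nonzero background
#'   additively dilutes the ratio toward 1; compensate with
#'   `subtract_background = TRUE` in [relative_density()] when simulating
#'   realistic backgrounds.
#' @param noise_sd Gaussian read-noise standard deviation; 0 disables all
#'   noise including shot noise.
#' @param psf_sigma_xy,psf_sigma_z Gaussian point-spread sigmas in voxels;
#'   0 disables blurring.
#' @param coi_radius hub COI sphere radius in voxels (default scales with
#'   the stack); for egg chambers the ellipsoid semi-axes are derived from
#'   `dim` instead.
#' @param boundary_thickness thickness in voxels of the hub boundary ring.
#' @param sc_outer_factor hub SC annulus outer radius as a multiple of
#'   `coi_radius`.
#' @param shell_frac egg-chamber follicle-shell thickness as a fraction of
#'   the ellipsoid radius.
#' @param clustering in `[0, 1)`: 0 places puncta independently and
#'   uniformly; larger values concentrate puncta around fewer parent sites
#'   (a dispersion knob, not a calibrated biological model).
#' @param pixel_size_xy,z_step physical voxel geometry in micrometres
#'   (metadata).
#' @param seed integer seed; identical seeds and parameters give
#'   bit-identical output.
#'
#' @return A list with elements
#'   \describe{
#'     \item{stack}{an [image_stack()] object,}
#'     \item{truth}{a list with logical arrays `coi_mask` and `sc_mask`
#'       (disjoint), a `puncta` data frame (`z`, `y`, `x`, `intensity`,
#'       `region`), and `realized_ratio`, the density ratio computed
#'       directly from the placed puncta and the truth masks.}
#'   }
#' @examples
#' sim <- simulate_stack("hub", dim = c(32, 48, 48), true_ratio = 2, seed = 1)
#' sim$truth$realized_ratio
#' @export
simulate_stack <- function(tissue = c("hub", "egg_chamber"),
                           dim = c(64L, 80L, 80L),
                           true_ratio = 1,
                           puncta_density_sc = 0.04,
                           puncta_intensity_mean = 100,
                           puncta_intensity_sd = 10,
                           background = 0,
                           noise_sd = 0,
                           psf_sigma_xy = 0,
                           psf_sigma_z = 0,
                           coi_radius = NULL,
                           boundary_thickness = 2,
                           sc_outer_factor = 2,
                           shell_frac = 0.15,
                           clustering = 0,
                           pixel_size_xy = 0.207,
                           z_step = 1,
                           seed = 1L) {
  tissue <- match.arg(tissue)
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L), true_ratio >= 0,
            puncta_density_sc > 0, noise_sd >= 0,
            psf_sigma_xy >= 0, psf_sigma_z >= 0,
            clustering >= 0, clustering < 1)

  geo <- if (tissue == "hub") {
    hub_geometry(dim, coi_radius, boundary_thickness, sc_outer_factor)
  } else {
    egg_geometry(dim, shell_frac)
  }
  if (!any(geo$coi)) stop("degenerate geometry: COI region is empty")
  if (!any(geo$sc)) stop("degenerate geometry: SC region is empty")

  local_seed(seed, {
    p_sc <- draw_puncta(which(geo$sc), dim, puncta_density_sc,
                        puncta_intensity_mean, puncta_intensity_sd,
                        clustering, geo$sc)
    p_coi <- draw_puncta(which(geo$coi), dim,
                         puncta_density_sc * true_ratio,
                         puncta_intensity_mean, puncta_intensity_sd,
                         clustering, geo$coi)
    puncta <- rbind(cbind(p_coi, region = rep("coi", nrow(p_coi))),
                    cbind(p_sc, region = rep("sc", nrow(p_sc))))

    bac <- render_puncta(dim, puncta, background, psf_sigma_xy, psf_sigma_z)
    boundary <- array(background, dim)
    boundary[geo$boundary] <- boundary[geo$boundary] + 150
    dna <- array(background, dim)
    dna[geo$coi | geo$sc] <- dna[geo$coi | geo$sc] + 30

    if (noise_sd > 0) {
      bac <- add_noise(bac, noise_sd)
      boundary <- add_noise(boundary, noise_sd)
      dna <- add_noise(dna, noise_sd)
    }

    voxels <- array(0, c(3L, dim))
    voxels[1L, , , ] <- dna
    voxels[2L, , , ] <- boundary
    voxels[3L, , , ] <- bac
    stack <- image_stack(voxels, pixel_size_xy = pixel_size_xy,
                         z_step = z_step)

    coi_sum <- sum(puncta$intensity[puncta$region == "coi"])
    sc_sum <- sum(puncta$intensity[puncta$region == "sc"])
    realized <- if (sc_sum > 0) {
      (coi_sum / sum(geo$coi)) / (sc_sum / sum(geo$sc))
    } else {
      NA_real_
    }

    list(stack = stack,
         truth = list(coi_mask = geo$coi, sc_mask = geo$sc,
                      puncta = puncta, realized_ratio = realized))
  })
}

hub_geometry <- function(dim, coi_radius, boundary_thickness,
                         sc_outer_factor) {
  r_coi <- coi_radius %||% floor(0.45 * min(dim) / 2)
  stopifnot(r_coi >= 3, sc_outer_factor > 1)
  r_out <- sc_outer_factor * r_coi
  if (2 * r_out > min(dim)) {
    stop("degenerate geometry: SC annulus does not fit inside the stack")
  }
  ctr <- (dim + 1) / 2
  r <- radial_distance(dim, ctr)
  list(coi = array(r < r_coi, dim),
       boundary = array(r >= r_coi & r < r_coi + boundary_thickness, dim),
       sc = array(r >= r_coi + boundary_thickness & r < r_out, dim))
}

egg_geometry <- function(dim, shell_frac) {
  stopifnot(shell_frac > 0, shell_frac < 0.5)
  semi <- floor(dim / 2 * 0.8)
  ctr <- (dim + 1) / 2
  zi <- (seq_len(dim[1]) - ctr[1]) / semi[1]
  yi <- (seq_len(dim[2]) - ctr[2]) / semi[2]
  xi <- (seq_len(dim[3]) - ctr[3]) / semi[3]
  rho <- sqrt(outer(outer(zi^2, yi^2, `+`), xi^2, `+`))
  shell <- array(rho >= 1 - shell_frac & rho < 1, dim)
  # boundary marker and SC coincide: the shell is the follicle-cell layer
  list(coi = array(rho < 1 - shell_frac, dim), boundary = shell, sc = shell)
}

radial_distance <- function(dim, ctr) {
  z2 <- (seq_len(dim[1]) - ctr[1])^2
  y2 <- (seq_len(dim[2]) - ctr[2])^2
  x2 <- (seq_len(dim[3]) - ctr[3])^2
  sqrt(outer(outer(z2, y2, `+`), x2, `+`))
}

draw_puncta <- function(region_idx, dim, lambda, imean, isd, clustering,
                        mask) {
  n <- rpois(1L, lambda * length(region_idx))
  if (n == 0L) {
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric()))
  }
  if (clustering > 0 && n > 1L) {
    n_parents <- max(1L, round(n * (1 - clustering)))
    parents <- region_idx[sample.int(length(region_idx), n_parents,
                                     replace = TRUE)]
    pc <- arrayInd(parents, dim)
    pick <- sample.int(n_parents, n, replace = TRUE)
    coord <- pc[pick, , drop = FALSE] +
      matrix(round(rnorm(3L * n, 0, 2)), ncol = 3L)
    coord <- pmin(pmax(coord, 1L), matrix(dim, n, 3L, byrow = TRUE))
    inside <- mask[coord]
    if (any(!inside)) {  # re-draw strays uniformly inside the region
      repl <- region_idx[sample.int(length(region_idx), sum(!inside),
                                    replace = TRUE)]
      coord[!inside, ] <- arrayInd(repl, dim)
    }
  } else {
    idx <- region_idx[sample.int(length(region_idx), n, replace = TRUE)]
    coord <- arrayInd(idx, dim)
  }
  data.frame(z = coord[, 1L], y = coord[, 2L], x = coord[, 3L],
             intensity = pmax(rnorm(n, imean, isd), 0))
}

render_puncta <- function(dim, puncta, background, sxy, sz) {
  img <- array(background, dim)
  if (nrow(puncta) == 0L) return(img)
  if (sxy == 0 && sz == 0) {
    idx <- cbind(puncta$z, puncta$y, puncta$x)
    lin <- (idx[, 3L] - 1L) * dim[1L] * dim[2L] +
      (idx[, 2L] - 1L) * dim[1L] + idx[, 1L]
    add <- rowsum(puncta$intensity, lin)
    at <- as.integer(rownames(add))
    img[at] <- img[at] + add[, 1L]
    return(img)
  }
  hz <- max(1L, ceiling(3 * sz)); hxy <- max(1L, ceiling(3 * sxy))
  kz <- gauss_kernel(hz, max(sz, 1e-6))
  kxy <- gauss_kernel(hxy, max(sxy, 1e-6))
  kern <- outer(outer(kz, kxy), kxy)
  kern <- kern / sum(kern)
  off_z <- -hz:hz; off_y <- -hxy:hxy; off_x <- -hxy:hxy
  for (i in seq_len(nrow(puncta))) {
    zr <- puncta$z[i] + off_z; yr <- puncta$y[i] + off_y
    xr <- puncta$x[i] + off_x
    kz_ok <- zr >= 1 & zr <= dim[1]; ky_ok <- yr >= 1 & yr <= dim[2]
    kx_ok <- xr >= 1 & xr <= dim[3]
    img[zr[kz_ok], yr[ky_ok], xr[kx_ok]] <-
      img[zr[kz_ok], yr[ky_ok], xr[kx_ok]] +
      puncta$intensity[i] * kern[kz_ok, ky_ok, kx_ok]
  }
  img
}

gauss_kernel <- function(h, sigma) {
  x <- -h:h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

add_noise <- function(img, noise_sd) {
  d <- dim(img)
  out <- rpois(length(img), pmax(img, 0)) + rnorm(length(img), 0, noise_sd)
  array(pmax(out, 0), d)
}

#' Simulate a cohort of relative density measurements
#'
#' Draws per-specimen relative densities log-normally for each group. A
#' group whose mean log density exceeds the control's by `log(f)` has an
#' arithmetic-mean fold change of exactly `f` when all groups share
#' `sd_log` (the log-normal mean is `exp(mu + sd^2/2)`, so the variance
#' term cancels in the ratio).
#'
#' @param groups a data frame with columns `label`, `n`, `mean_log`,
#'   `sd_log` (one row per group), or a named list of numeric vectors
#'   `c(mean_log, sd_log, n)`.
#' @param tissue,stage carried into the output table (`tissue` one of
#'   `"hub"`, `"germline"`; `stage` optional integer 2-8 for egg chambers).
#' @param seed integer seed.
#' @return A data frame of class `density_cohort` with columns
#'   `specimen_id`, `group`, `tissue`, `stage`, `relative_density`.
#' @examples
#' g <- data.frame(label = c("control", "Atg1_RNAi"), n = c(37, 47),
#'                 mean_log = c(0, log(2.87)), sd_log = 0.4)
#' head(simulate_cohort(g, seed = 1))
#' @export
simulate_cohort <- function(groups, tissue = c("hub", "germline"),
                            stage = NA_integer_, seed = 1L) {
  tissue <- match.arg(tissue)
  if (is.list(groups) && !is.data.frame(groups)) {
    groups <- do.call(rbind, lapply(names(groups), function(nm) {
      g <- groups[[nm]]
      data.frame(label = nm, n = g[["n"]], mean_log = g[["mean_log"]],
                 sd_log = g[["sd_log"]])
    }))
  }
  stopifnot(is.data.frame(groups),
            all(c("label", "n", "mean_log", "sd_log") %in% names(groups)),
            all(groups$n >= 1), all(groups$sd_log >= 0))
  if (!is.na(stage)) stopifnot(stage >= 2, stage <= 8)
  local_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      data.frame(
        specimen_id = sprintf("%s_%03d", g$label, seq_len(g$n)),
        group = g$label, tissue = tissue, stage = stage,
        relative_density = rlnorm(g$n, g$mean_log, g$sd_log))
    }))
    rownames(out) <- NULL
    class(out) <- c("density_cohort", "data.frame")
    out
  })
}

#' Simulate a qPCR plate with a known knockdown level
#'
#' Produces a long-format CT table for a target and a reference gene in a
#' control and an RNAi group, constructed so that the expected relative
#' expression of the target in the RNAi group (delta-delta-Ct against the
#' control) equals `1 - knockdown_fraction`. With `noise_sd = 0` the
#' round trip through [knockdown_efficiency()] is exact.
#'
#' @param knockdown_fraction in `[0, 1)`: fraction of target expression
#'   removed in the RNAi group.
#' @param n_samples biological samples per group.
#' @param n_replicates technical replicates per sample and gene.
#' @param noise_sd per-replicate CT noise (cycles); a sample-level offset of
#'   the same sd is also applied to both genes (it cancels in delta-Ct).
#' @param target,reference gene names written into the table.
#' @param ct_reference baseline reference-gene CT (cycles).
#' @param delta_ct_control control-group target-minus-reference CT.
#' @param seed integer seed.
#' @return Data frame with columns `sample_id`, `group` (`"control"` /
#'   `"rnai"`), `gene`, `replicate`, `ct`.
#' @examples
#' plate <- simulate_qpcr(0.77, seed = 1)
#' knockdown_efficiency(plate, "Atg1", "RPL32", "control", "rnai")
#' @export
simulate_qpcr <- function(knockdown_fraction, n_samples = 3L,
                          n_replicates = 3L, noise_sd = 0,
                          target = "Atg1", reference = "RPL32",
                          ct_reference = 20, delta_ct_control = 3,
                          seed = 1L) {
  stopifnot(knockdown_fraction >= 0, knockdown_fraction < 1,
            n_samples >= 1, n_replicates >= 1, noise_sd >= 0)
  kd_shift <- -log2(1 - knockdown_fraction)
  local_seed(seed, {
    rows <- list()
    for (grp in c("control", "rnai")) {
      for (s in seq_len(n_samples)) {
        off <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
        ct_ref <- ct_reference + off
        ct_tar <- ct_reference + delta_ct_control + off +
          if (grp == "rnai") kd_shift else 0
        for (gene in c(target, reference)) {
          base <- if (gene == target) ct_tar else ct_ref
          eps <- if (noise_sd > 0) rnorm(n_replicates, 0, noise_sd) else
            numeric(n_replicates)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%d", grp, s), group = grp, gene = gene,
            replicate = seq_len(n_replicates), ct = base + eps)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate random pathway sets over a synthetic feature universe
#'
#' @param n_pathways number of pathways.
#' @param n_features size of the feature universe (`f0001`, `f0002`, ...).
#' @param size_range inclusive range of pathway sizes.
#' @param seed integer seed.
#' @return Named list of character vectors of feature ids.
#' @export
random_pathways <- function(n_pathways, n_features,
                            size_range = c(10L, 30L), seed = 1L) {
  stopifnot(n_pathways >= 1, n_features >= max(size_range),
            size_range[1] >= 1)
  universe <- sprintf("f%04d", seq_len(n_features))
  local_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    out <- lapply(sizes, function(k) sample(universe, k))
    names(out) <- sprintf("pathway_%02d", seq_len(n_pathways))
    out
  })
}

#' Simulate a two-group metabolite feature matrix with planted pathways
#'
#' Baseline feature abundances are standard normal; members of each pathway
#' named in `enriched` receive a mean shift of the stated effect size (in
#' standard-deviation units) in the second group. Everything else is null.
#'
#' @param n_features feature universe size; features are named `f0001` ...
#'   and must cover all pathway members.
#' @param pathways named list of feature-id sets (see [random_pathways()]).
#' @param enriched named numeric vector: pathway name -> effect size
#'   (positive = up in group 2). Unknown names are an error.
#' @param n_per_group samples per group.
#' @param group_labels length-2 character vector of group names.
#' @param seed integer seed.
#' @return List with `abundance` (features x samples matrix) and `groups`
#'   (factor of length `2 * n_per_group`).
#' @examples
#' pw <- random_pathways(5, 200, seed = 1)
#' sim <- simulate_metabolome(200, pw, enriched = c(pathway_01 = 2),
#'                            n_per_group = 4, seed = 1)
#' @export
simulate_metabolome <- function(n_features, pathways,
                                enriched = numeric(0), n_per_group = 3L,
                                group_labels = c("control", "treatment"),
                                seed = 1L) {
  stopifnot(n_features >= 2, n_per_group >= 3, length(group_labels) == 2)
  universe <- sprintf("f%04d", seq_len(n_features))
  bad <- setdiff(unlist(pathways), universe)
  if (length(bad) > 0) {
    stop("pathways reference unknown feature ids: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  if (length(enriched) > 0) {
    unknown <- setdiff(names(enriched), names(pathways))
    if (length(unknown) > 0) {
      stop("unknown pathway id in `enriched`: ",
           paste(unknown, collapse = ", "))
    }
  }
  n_samp <- 2L * n_per_group
  groups <- factor(rep(group_labels, each = n_per_group),
                   levels = group_labels)
  local_seed(seed, {
    mat <- matrix(rnorm(n_features * n_samp), n_features, n_samp,
                  dimnames = list(universe,
                                  sprintf("s%02d", seq_len(n_samp))))
    in_g2 <- groups == group_labels[2]
    for (pw in names(enriched)) {
      members <- pathways[[pw]]
      mat[members, in_g2] <- mat[members, in_g2] + enriched[[pw]]
    }
    list(abundance = mat, groups = groups)
  })
}
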