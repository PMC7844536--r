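#' Construct an image stack
#'
#' A lightweight container for a multi-channel confocal z-stack: a 4-D
#' array indexed `(channel, z, y, x)` plus a mapping from the three channel
#' roles used by the quantification (`dna`, `boundary`, `bacteria`) to
#' channel indices, and the physical voxel geometry.
#'
#' @param voxels 4-D numeric array `(channel, z, y, x)`, non-negative.
#' @param channels named integer vector mapping roles `dna`, `boundary`,
#'   `bacteria` to distinct channel indices.
#' @param pixel_size_xy,z_step voxel geometry in micrometres (metadata; the
#'   relative-density ratio is unit free).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels,
                        channels = c(dna = 1L, boundary = 2L, bacteria = 3L),
                        pixel_size_xy = 1, z_step = 1) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L)
  roles <- c("dna", "boundary", "bacteria")
  if (!all(roles %in% names(channels))) {
    stop("channels must assign all of: ", paste(roles, collapse = ", "))
  }
  ch <- as.integer(channels[roles])
  if (anyDuplicated(ch) || any(ch < 1) || any(ch > dim(voxels)[1])) {
    stop("channel roles must map to distinct, valid channel indices")
  }
  if (min(voxels) < 0) stop("intensities must be non-negative")
  structure(list(voxels = voxels,
                 channels = stats::setNames(ch, roles),
                 pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channels, %d slices, %d x %d px (%.3g um/px, %.3g um z-step)\n",
              d[1], d[2], d[3], d[4], x$pixel_size_xy, x$z_step))
  invisible(x)
}

get_channel <- function(stack, role) {
  d <- dim(stack$voxels)
  array(stack$voxels[stack$channels[[role]], , , , drop = FALSE], d[-1])
}

#' Segment COI and SC regions from the boundary-marker channel
#'
#' For each z slice the boundary channel is thresholded (per-slice Otsu,
#' guarded by a whole-stack Otsu threshold so that slices without boundary
#' signal stay empty), morphologically closed and hole-filled. For hubs,
#' the cell type of interest (COI) is the largest region enclosed by the
#' boundary ring and the surrounding cells (SC) are a dilation band outside
#' it whose outer radius defaults to `sc_outer_factor` times the COI
#' equivalent radius. For egg chambers the thresholded boundary signal
#' itself is the follicle shell, i.e. the SC, and the COI is the enclosed
#' interior. COI and SC are disjoint on every slice by construction.
#'
#' The regions in the original measurements were drawn from anatomy by
#' hand; this automatic rule is a stated, tunable stand-in for that manual
#' step.
#'
#' @param stack an [image_stack()].
#' @param tissue `"hub"` or `"egg_chamber"`.
#' @param sc_outer_factor hub SC band outer radius as a multiple of the
#'   per-slice COI equivalent radius.
#' @param closing_radius diameter in pixels of the disc brush used for
#'   morphological closing.
#' @return A `region_masks` object: logical arrays `coi` and `sc` of
#'   dimension `(z, y, x)` and `slices_used`, the z indices where both
#'   regions are non-empty.
#' @export
segment_regions <- function(stack, tissue = c("hub", "egg_chamber"),
                            sc_outer_factor = 2, closing_radius = 5) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(stack, "image_stack"), sc_outer_factor > 1)
  b <- get_channel(stack, "boundary")
  bmax <- max(b)
  if (bmax <= 0) stop("segmentation failed: boundary channel is blank")
  bn <- b / bmax
  th_global <- EBImage::otsu(matrix(bn, ncol = 1L), range = c(0, 1))
  d <- dim(bn)
  coi <- array(FALSE, d)
  sc <- array(FALSE, d)
  brush <- EBImage::makeBrush(odd(closing_radius), "disc")
  for (z in seq_len(d[1])) {
    sl <- bn[z, , ]
    if (max(sl) < th_global) next
    th <- max(EBImage::otsu(sl, range = c(0, 1)), 0.5 * th_global)
    raw <- sl > th
    ring <- EBImage::closing(raw, brush)
    if (!any(ring)) next
    filled <- EBImage::fillHull(ring) > 0
    interior <- largest_component(filled & !ring)
    if (!any(interior)) next
    if (tissue == "hub") {
      coi[z, , ] <- interior
      # band outer radius = sc_outer_factor x COI equivalent radius,
      # measured outward from the filled boundary so the band does not
      # overshoot into empty space beyond the SC
      r_int <- sqrt(sum(interior) / pi)
      r_fill <- sqrt(sum(filled) / pi)
      w <- max(2L, round(sc_outer_factor * r_int - r_fill))
      band <- EBImage::dilate(filled, EBImage::makeBrush(odd(2 * w + 1),
                                                         "disc")) > 0
      sc[z, , ] <- band & !filled
    } else {
      coi[z, , ] <- interior
      # the un-closed threshold is the tighter shell estimate
      sc[z, , ] <- largest_component(raw)
    }
  }
  used <- which(apply(coi, 1, any) & apply(sc, 1, any))
  if (length(used) == 0L) {
    stop("segmentation failed: no slice with both COI and SC")
  }
  region_masks(coi, sc, used)
}

odd <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n + 1L else n
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Construct region masks
#'
#' @param coi,sc logical `(z, y, x)` arrays; must be disjoint.
#' @param slices_used z indices entering the density computation; defaults
#'   to all slices where both regions are non-empty.
#' @return A `region_masks` object.
#' @export
region_masks <- function(coi, sc, slices_used = NULL) {
  stopifnot(is.array(coi), is.array(sc), identical(dim(coi), dim(sc)))
  if (any(coi & sc)) stop("COI and SC masks overlap")
  if (is.null(slices_used)) {
    slices_used <- which(apply(coi, 1, any) & apply(sc, 1, any))
  }
  if (length(slices_used) == 0L) stop("no usable slices")
  structure(list(coi = coi, sc = sc,
                 slices_used = as.integer(slices_used)),
            class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("region_masks: %d slices used (of %d); COI %d px, SC %d px\n",
              length(x$slices_used), dim(x$coi)[1],
              sum(x$coi[x$slices_used, , ]), sum(x$sc[x$slices_used, , ])))
  invisible(x)
}

#' Select the analysis slices of a segmented stack
#'
#' Hubs: all "middle" slices are kept, operationalized as slices whose COI
#' cross-sectional area is at least `min_area_frac` of the maximal COI
#' slice area (this excludes cap slices where a 2-D section poorly
#' represents the cell). Egg chambers (germline): the `k` consecutive
#' slices centred on the slice of maximal COI area are kept, shifted
#' inward when the window would run off the stack, and clamped with a
#' warning when `k` exceeds the number of available slices.
#'
#' @param masks a `region_masks` object.
#' @param tissue `"hub"` or `"egg_chamber"`.
#' @param k number of consecutive germline slices (default 5).
#' @param min_area_frac hub area threshold relative to the maximal slice.
#' @return The masks with `slices_used` updated.
#' @export
select_slices <- function(masks, tissue = c("hub", "egg_chamber"), k = 5L,
                          min_area_frac = 0.5) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(masks, "region_masks"), k >= 1,
            min_area_frac > 0, min_area_frac <= 1)
  cand <- masks$slices_used
  areas <- vapply(cand, function(z) sum(masks$coi[z, , ]), 0)
  if (tissue == "hub") {
    keep <- cand[areas >= min_area_frac * max(areas)]
  } else {
    if (k >= length(cand)) {
      if (k > length(cand)) {
        warning("k exceeds the number of usable slices; keeping all ",
                length(cand), " slices")
      }
      keep <- cand
    } else {
      ctr <- which.max(areas)  # ties: lowest z
      half <- (k - 1L) %/% 2L
      lo <- ctr - half
      lo <- max(1L, min(lo, length(cand) - k + 1L))
      keep <- cand[lo:(lo + k - 1L)]
    }
  }
  if (length(keep) == 0L) stop("no qualifying slices")
  masks$slices_used <- keep
  masks
}

#' Relative bacterial density of the COI versus the surrounding cells
#'
#' The measurement statistic: summed bacterial-channel intensity per COI
#' pixel over the selected slices, divided by the same quantity for the SC,
#'
#' \deqn{\frac{\mathrm{COI\ voxel\ density}}{\mathrm{SC\ voxel\ density}}
#'   = \frac{\sum_{COI} I / |COI|}{\sum_{SC} I / |SC|}.}
#'
#' Intensities are raw (no background subtraction) unless
#' `subtract_background = TRUE`, which subtracts the per-slice median of
#' the bacterial channel outside COI, SC and a small guard dilation.
#' Areas are pixel counts; physical units cancel in the ratio, as does any
#' global intensity scaling.
#'
#' @param stack an [image_stack()].
#' @param masks a `region_masks` object (after [select_slices()]).
#' @param specimen_id,group,tissue,stage labels carried into the output row.
#' @param subtract_background subtract the per-slice exterior median from
#'   the bacterial channel before summation.
#' @return A one-row data frame: `specimen_id`, `group`, `tissue`, `stage`,
#'   `coi_density`, `sc_density`, `relative_density`, `saturation_fraction`
#'   (QC: fraction of in-mask voxels at the channel maximum).
#' @export
relative_density <- function(stack, masks, specimen_id = "specimen",
                             group = NA_character_, tissue = NA_character_,
                             stage = NA_integer_,
                             subtract_background = FALSE) {
  stopifnot(inherits(stack, "image_stack"), inherits(masks, "region_masks"))
  bac <- get_channel(stack, "bacteria")
  stopifnot(identical(dim(bac), dim(masks$coi)))
  zs <- masks$slices_used
  coi_sum <- 0; sc_sum <- 0; coi_n <- 0L; sc_n <- 0L; sat <- 0L
  vmax <- max(bac)
  for (z in zs) {
    sl <- bac[z, , ]
    cm <- masks$coi[z, , ]; sm <- masks$sc[z, , ]
    if (subtract_background) {
      ext <- !(cm | sm)
      sl <- pmax(sl - median(sl[ext]), 0)
    }
    coi_sum <- coi_sum + sum(sl[cm]); coi_n <- coi_n + sum(cm)
    sc_sum <- sc_sum + sum(sl[sm]); sc_n <- sc_n + sum(sm)
    sat <- sat + sum(bac[z, , ][cm | sm] >= vmax)
  }
  if (coi_n == 0L || sc_n == 0L) stop("empty region over the used slices")
  if (sc_sum <= 0) stop("undefined normalization: zero SC intensity")
  coi_d <- coi_sum / coi_n
  sc_d <- sc_sum / sc_n
  data.frame(specimen_id = specimen_id, group = group, tissue = tissue,
             stage = stage, coi_density = coi_d, sc_density = sc_d,
             relative_density = coi_d / sc_d,
             saturation_fraction = sat / (coi_n + sc_n))
}

#' Quantify a stack end to end
#'
#' Convenience wrapper: [segment_regions()], [select_slices()],
#' [relative_density()].
#'
#' @inheritParams segment_regions
#' @inheritParams select_slices
#' @inheritParams relative_density
#' @param ... passed on to [relative_density()].
#' @return A one-row data frame (see [relative_density()]).
#' @examples
#' sim <- simulate_stack("hub", dim = c(32, 48, 48), true_ratio = 2,
#'                       coi_radius = 8, seed = 1)
#' quantify_stack(sim$stack, "hub")$relative_density
#' @export
quantify_stack <- function(stack, tissue = c("hub", "egg_chamber"),
                           k = 5L, min_area_frac = 0.5,
                           sc_outer_factor = 2, ...) {
  tissue <- match.arg(tissue)
  masks <- segment_regions(stack, tissue, sc_outer_factor = sc_outer_factor)
  masks <- select_slices(masks, tissue, k = k,
                         min_area_frac = min_area_frac)
  relative_density(stack, masks, tissue = tissue, ...)
}

#' Write / read an image stack as a multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...); channel roles and geometry go in a YAML-like sidecar text file
#' `<path>.meta` so a round trip restores the object. Intensities are
#' scaled to `[0, 1]` by the recorded `intensity_max`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  vmax <- max(stack$voxels, 1e-12)
  pages <- list()
  for (ch in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[length(pages) + 1L]] <- stack$voxels[ch, z, , ] / vmax
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(sprintf("n_channels: %d", d[1]), sprintf("n_slices: %d", d[2]),
            sprintf("channel_%s: %d", names(stack$channels),
                    stack$channels),
            sprintf("pixel_size_xy: %.10g", stack$pixel_size_xy),
            sprintf("z_step: %.10g", stack$z_step),
            sprintf("intensity_max: %.10g", vmax))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta_lines <- readLines(paste0(path, ".meta"))
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  nc <- as.integer(meta[["n_channels"]])
  nz <- as.integer(meta[["n_slices"]])
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == nc * nz)
  d <- dim(pages[[1]])
  voxels <- array(0, c(nc, nz, d[1], d[2]))
  i <- 1L
  for (ch in seq_len(nc)) {
    for (z in seq_len(nz)) {
      voxels[ch, z, , ] <- pages[[i]]
      i <- i + 1L
    }
  }
  voxels <- voxels * as.numeric(meta[["intensity_max"]])
  image_stack(voxels,
              channels = c(dna = as.integer(meta[["channel_dna"]]),
                           boundary = as.integer(meta[["channel_boundary"]]),
                           bacteria = as.integer(meta[["channel_bacteria"]])),
              pixel_size_xy = as.numeric(meta[["pixel_size_xy"]]),
              z_step = as.numeric(meta[["z_step"]]))
}
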