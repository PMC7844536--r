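#' Relative quantification from a qPCR CT table (delta-delta-Ct)
#'
#' Technical replicates are averaged on the CT scale per sample and gene;
#' each sample's delta-Ct is `CT(target) - CT(reference)` (e.g. wsp
#' normalized to 14-3-3 for bacterial titre, or an RNAi target normalized
#' to RPL32 for knockdown); delta-delta-Ct subtracts the calibrator
#' group's mean delta-Ct, and the relative quantity is
#' `efficiency^(-ddCt)` with the amplification efficiency fixed at 2
#' (perfect doubling; no efficiency correction) unless overridden.
#'
#' Adding a constant to every CT on the plate leaves all relative
#' quantities unchanged (the reference gene and calibrator cancel it).
#'
#' @param plate data frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (and optionally `replicate`); CT in cycles, > 0.
#' @param target,reference gene names; every sample must carry both.
#' @param calibrator_group group whose mean delta-Ct anchors relative
#'   quantity 1.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return Data frame: `sample_id`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `rel_quantity`.
#' @examples
#' plate <- simulate_qpcr(0.5, seed = 1)
#' relative_quantity(plate, "Atg1", "RPL32", "control")
#' @export
relative_quantity <- function(plate, target, reference, calibrator_group,
                              efficiency = 2) {
  plate <- check_plate(plate)
  stopifnot(efficiency > 1)
  sub <- plate[plate$gene %in% c(target, reference), ]
  if (nrow(sub) == 0) stop("target/reference genes not found in plate")
  avg <- aggregate(ct ~ sample_id + group + gene, data = sub, FUN = mean)
  samples <- unique(avg[, c("sample_id", "group")])
  get_ct <- function(sid, gene) {
    v <- avg$ct[avg$sample_id == sid & avg$gene == gene]
    if (length(v) != 1) {
      stop("sample ", sid, " lacks a CT for gene ", gene)
    }
    v
  }
  dct <- vapply(samples$sample_id, function(sid) {
    get_ct(sid, target) - get_ct(sid, reference)
  }, 0)
  if (!calibrator_group %in% samples$group) {
    stop("calibrator group not present: ", calibrator_group)
  }
  cal_mean <- mean(dct[samples$group == calibrator_group])
  ddct <- dct - cal_mean
  data.frame(sample_id = samples$sample_id, group = samples$group,
             delta_ct = unname(dct), delta_delta_ct = unname(ddct),
             rel_quantity = efficiency^(-unname(ddct)))
}

check_plate <- function(plate) {
  stopifnot(is.data.frame(plate))
  names(plate) <- tolower(names(plate))
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss) > 0) {
    stop("plate is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(plate$ct)) || any(plate$ct <= 0)) {
    stop("CT values must be positive and finite")
  }
  plate
}

#' RNAi knockdown efficiency from a qPCR plate
#'
#' Efficiency (percent) is `(1 - mean relative quantity of the RNAi
#' group) * 100`, with the control group as calibrator, clipped at 0. A
#' mean relative quantity above 1 (apparent over-expression) yields 0 with
#' the `overexpression` attribute set and a warning.
#'
#' @inheritParams relative_quantity
#' @param control_group,rnai_group group labels.
#' @return Knockdown efficiency in percent (numeric scalar, attribute
#'   `overexpression` logical).
#' @examples
#' plate <- simulate_qpcr(0.77, seed = 1)
#' knockdown_efficiency(plate, "Atg1", "RPL32", "control", "rnai")  # 77
#' @export
knockdown_efficiency <- function(plate, target, reference, control_group,
                                 rnai_group, efficiency = 2) {
  rq <- relative_quantity(plate, target, reference,
                          calibrator_group = control_group,
                          efficiency = efficiency)
  if (!rnai_group %in% rq$group) {
    stop("RNAi group not present: ", rnai_group)
  }
  m <- mean(rq$rel_quantity[rq$group == rnai_group])
  over <- m > 1
  if (over) {
    warning("mean relative quantity exceeds 1 in the RNAi group ",
            "(apparent over-expression); reporting 0% knockdown")
  }
  structure(max(0, (1 - m) * 100), overexpression = over)
}
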