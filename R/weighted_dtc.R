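# Dual-task cost (DTC) and its commitment-weighted variant DTC*.
#
# DTC is the percent change of a motor feature under cognitive load relative
# to its single-task baseline. The weighted variant multiplies the dual-task
# feature value by a bounded min-max rescaling of the subject's correct
# counting responses before taking the percent change, so that a subject who
# preserves motor output only by abandoning the cognitive task (near-zero
# classical DTC, near-minimum weight) is flagged by a strongly negative
# DTC* instead of passing as normal.

#' Bounds for the correct-response rescaling
#'
#' @param a Lower bound of the rescaled weight (default 0.01, kept strictly
#'   positive so the weighted value never vanishes exactly).
#' @param b Upper bound (default 1: the best counter in the sample keeps the
#'   feature value unchanged).
#' @return A list of class `mcdt_rescale_bounds`.
#' @export
rescale_bounds <- function(a = 0.01, b = 1) {
  if (!(a > 0 && a < b)) {
    abort("Rescale bounds require 0 < a < b.",
          class = "mcdt_validation_error")
  }
  structure(list(a = a, b = b), class = "mcdt_rescale_bounds")
}

#' Classical dual-task cost
#'
#' Percent change of a dual-task feature value relative to its single-task
#' baseline: `(task - baseline) / baseline * 100`. Vectorised.
#'
#' @param task_value Feature value under cognitive load.
#' @param baseline_value Feature value at the single-task baseline; must be
#'   nonzero.
#' @return Percent change.
#' @export
#' @examples
#' compute_dtc(12, 10) # 20
compute_dtc <- function(task_value, baseline_value) {
  if (any(baseline_value == 0)) {
    abort("Degenerate baseline: baseline feature value is exactly 0, percent change undefined.",
          class = "mcdt_degenerate_baseline")
  }
  (task_value - baseline_value) / baseline_value * 100
}

#' Bounded min-max rescaling of correct-response counts
#'
#' Maps the counts of all subjects at one (exercise, load) to `[a, b]` by an
#' affine min-max transform: the worst counter gets `a`, the best gets `b`.
#' When all counts are equal the map is undefined (0/0); all weights are
#' then set to `b`, treating uniform performance as full commitment, which
#' preserves DTC* = DTC in that uninformative case.
#'
#' @param nc Vector of correct-response counts over subjects at one
#'   (exercise, load).
#' @param bounds A [rescale_bounds()].
#' @return Vector of weights in `[a, b]`.
#' @export
rescale_counts <- function(nc, bounds = rescale_bounds()) {
  if (length(nc) == 0) {
    abort("Empty count vector.", class = "mcdt_validation_error")
  }
  if (any(nc < 0)) {
    abort("Counts must be nonnegative.", class = "mcdt_validation_error")
  }
  rng <- range(nc)
  if (rng[1] == rng[2]) {
    return(rep(bounds$b, length(nc)))
  }
  (bounds$b - bounds$a) * (nc - rng[1]) / (rng[2] - rng[1]) + bounds$a
}

#' Commitment-weight a dual-task feature value
#'
#' `f* = f * zc`. Defined only for dual-task loads (no counting happens at
#' baseline, so there is no weight there).
#'
#' @param f Feature value at load k >= 1.
#' @param zc Rescaled weight in (0, 1].
#' @param load Load level; supplying 0 is an error.
#' @return Weighted value.
#' @export
weight_feature <- function(f, zc, load = 1L) {
  if (any(load == 0)) {
    abort("Weighting is undefined at the single-task baseline (load 0).",
          class = "mcdt_validation_error")
  }
  f * zc
}

#' Compute classical and weighted dual-task costs for a cohort
#'
#' For every (subject, exercise, feature, load k in 1..3) cell: the weight
#' `zc` is the min-max rescaled correct-response count over subjects at that
#' (exercise, load); `f* = f * zc`; classical `dtc` and weighted `dtc_star`
#' are percent changes of `f` and `f*` against the unweighted single-task
#' baseline. Cells whose baseline is exactly zero are flagged (`flagged =
#' TRUE`, costs `NA`) rather than producing infinities, and are excluded by
#' downstream stages.
#'
#' @param features An `mcdt_feature_table` with complete baseline blocks and
#'   counts.
#' @param bounds A [rescale_bounds()].
#' @return An object of class `mcdt_dtc_table`: tibble with columns
#'   `subject, exercise, load, feature, baseline, value, nc, zc, f_star,
#'   dtc, dtc_star, flagged`, carrying the orientation metadata as an
#'   attribute.
#' @export
compute_dtc_star <- function(features, bounds = rescale_bounds()) {
  stopifnot(inherits(features, "mcdt_feature_table"))
  feats <- features$features
  base <- feats[feats$load == 0,
                c("subject", "exercise", "feature", "value")]
  names(base)[names(base) == "value"] <- "baseline"
  task <- feats[feats$load != 0, ]
  miss <- dplyr::anti_join(unique(task[c("subject", "exercise", "feature")]),
                           base[c("subject", "exercise", "feature")],
                           by = c("subject", "exercise", "feature"))
  if (nrow(miss)) {
    abort(paste0(nrow(miss), " (subject, exercise, feature) block(s) lack a ",
                 "baseline value, e.g. ",
                 paste(sprintf("%s/%s/%s", miss$subject[1], miss$exercise[1],
                               miss$feature[1]))),
          class = "mcdt_schema_error")
  }

  counts <- features$counts
  counts <- dplyr::group_by(counts, .data$exercise, .data$load)
  counts <- dplyr::mutate(counts, zc = rescale_counts(.data$nc, bounds))
  counts <- dplyr::ungroup(counts)

  out <- dplyr::left_join(task, base,
                          by = c("subject", "exercise", "feature"))
  out <- dplyr::left_join(out, counts,
                          by = c("subject", "exercise", "load"))
  if (any(is.na(out$zc))) {
    abort("Missing Nc count for some (subject, exercise, load) cells.",
          class = "mcdt_schema_error")
  }
  out$flagged <- out$baseline == 0
  if (any(out$flagged)) {
    warn(paste0(sum(out$flagged),
                " cell(s) flagged for a degenerate (zero) baseline and excluded."))
  }
  out$f_star <- weight_feature(out$value, out$zc, out$load)
  safe_base <- ifelse(out$flagged, NA_real_, out$baseline)
  out$dtc <- (out$value - safe_base) / safe_base * 100
  out$dtc_star <- (out$f_star - safe_base) / safe_base * 100
  out <- out[c("subject", "exercise", "load", "feature", "baseline", "value",
               "nc", "zc", "f_star", "dtc", "dtc_star", "flagged")]
  structure(as_tibble(out),
            orientation = features$orientation,
            bounds = bounds,
            class = c("mcdt_dtc_table", class(as_tibble(out))))
}
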