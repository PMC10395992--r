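# Pooled-index (PI) construction. A PI summarises a subject's dual-task
# degradation over one exercise family as the average of up to six
# normalised, orientation-aligned DTC* component variables, the components
# being chosen by iterative Spearman-correlation screening: repeatedly
# delete the candidate with the most pairwise |rho| at or above the
# threshold, breaking ties by the weakest class-discriminating effect size
# (Cohen's d), then by an explicit priority list.

#' Configuration of the PI component-selection procedure
#'
#' @param rho_threshold Absolute Spearman correlation at or above which a
#'   pair counts as correlated (default 0.4; the keep condition is
#'   |rho| < 0.4).
#' @param max_components Maximum PI size (default 6).
#' @param tie_break_manual Ordered character vector of candidate identities
#'   to drop first when correlation counts and effect sizes both tie (the
#'   stand-in for clinical judgement). Candidates not listed fall back to
#'   the lexicographically smallest identity, with a loud warning.
#' @param candidate_mode `"per_load"` (default): each (feature, load) DTC*
#'   is a distinct candidate; `"load_averaged"`: the mean DTC* over loads
#'   1-3 per feature.
#' @param normalization `"minmax"` (default, PI scores in \[0, 1\]) or
#'   `"zscore"`.
#' @return List of class `mcdt_selection_config`.
#' @export
selection_config <- function(rho_threshold = 0.4, max_components = 6L,
                             tie_break_manual = character(),
                             candidate_mode = c("per_load", "load_averaged"),
                             normalization = c("minmax", "zscore")) {
  if (!(rho_threshold > 0 && rho_threshold < 1)) {
    abort("`rho_threshold` must lie in (0, 1).",
          class = "mcdt_validation_error")
  }
  if (max_components < 1) {
    abort("`max_components` must be >= 1.", class = "mcdt_validation_error")
  }
  structure(list(rho_threshold = rho_threshold,
                 max_components = as.integer(max_components),
                 tie_break_manual = tie_break_manual,
                 candidate_mode = match.arg(candidate_mode),
                 normalization = match.arg(normalization)),
            class = "mcdt_selection_config")
}

# Row-subset a candidate matrix without losing its orientation attribute.
candidate_rows <- function(m, idx) {
  ov <- attr(m, "orientation")
  out <- m[idx, , drop = FALSE]
  attr(out, "orientation") <- ov[colnames(out)]
  out
}

pi_exercises <- function(name) {
  switch(name,
         FTAP = "FTAP", TTHP = "TTHP", GAIT = "GAIT",
         TAPPING = c("FTAP", "TTHP"),
         TOTAL = EXERCISES,
         abort(paste0("Unknown pooled index name: ", name),
               class = "mcdt_validation_error"))
}

#' Assemble the DTC* candidate matrix for a pooled index
#'
#' One column per candidate variable, one row per subject. In `per_load`
#' mode a candidate is one (exercise, feature, load) DTC* value; in
#' `load_averaged` mode the mean over loads 1-3. Each candidate carries an
#' orientation sign (+1 if a higher value already means better functioning:
#' the DTC* of a higher-is-better feature; -1 otherwise) in the
#' `"orientation"` attribute. Cells flagged for a degenerate baseline
#' become `NA`.
#'
#' @param dtc An `mcdt_dtc_table` (from [compute_dtc_star()]).
#' @param exercises Character vector of exercises to draw from, or a PI
#'   name via [build_all_pis()].
#' @param config A [selection_config()].
#' @return Numeric matrix (subjects x candidates) with rownames = subject
#'   ids, colnames = candidate identities (`EX_fNN_CL<k>` or `EX_fNN`), and
#'   attribute `orientation` (named +/-1 vector).
#' @export
assemble_candidates <- function(dtc, exercises, config = selection_config()) {
  stopifnot(inherits(dtc, "mcdt_dtc_table"))
  missing_ex <- setdiff(exercises, unique(dtc$exercise))
  if (length(missing_ex)) {
    abort(paste0("Requested exercise(s) absent from DTC table: ",
                 paste(missing_ex, collapse = ", ")),
          class = "mcdt_validation_error")
  }
  d <- dtc[dtc$exercise %in% exercises, ]
  d$dtc_star[d$flagged] <- NA_real_
  orient_tab <- attr(dtc, "orientation")
  if (is.null(orient_tab) || any(is.na(orient_tab$higher_better))) {
    abort("Candidate assembly needs complete feature orientation metadata.",
          class = "mcdt_validation_error")
  }
  d <- dplyr::left_join(d, orient_tab, by = c("exercise", "feature"))

  if (config$candidate_mode == "per_load") {
    d$candidate <- sprintf("%s_%s_CL%d", d$exercise, d$feature, d$load)
  } else {
    d <- dplyr::summarise(
      dplyr::group_by(d, .data$subject, .data$exercise, .data$feature,
                      .data$higher_better),
      dtc_star = mean(.data$dtc_star), .groups = "drop")
    d$candidate <- sprintf("%s_%s", d$exercise, d$feature)
  }
  wide <- tidyr::pivot_wider(d[c("subject", "candidate", "dtc_star")],
                             names_from = "candidate",
                             values_from = "dtc_star")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject
  m <- m[, sort(colnames(m)), drop = FALSE]
  orient <- unique(d[c("candidate", "higher_better")])
  ov <- setNames(ifelse(orient$higher_better, 1, -1), orient$candidate)
  attr(m, "orientation") <- ov[colnames(m)]
  m
}

#' Pairwise Spearman correlation matrix of candidates
#'
#' Average-rank tie handling; diagonal exactly 1. A constant candidate has
#' undefined correlations: those entries are `NA` and are counted as
#' exceeding any threshold downstream (worst case).
#'
#' @param candidates Subjects x candidates matrix (>= 3 subjects, >= 2
#'   candidates).
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(candidates) {
  if (nrow(candidates) < 3 || ncol(candidates) < 2) {
    abort("Spearman screening needs >= 3 subjects and >= 2 candidates.",
          class = "mcdt_validation_error")
  }
  use <- if (anyNA(candidates)) "pairwise.complete.obs" else "everything"
  rho <- suppressWarnings(
    stats::cor(candidates, method = "spearman", use = use))
  diag(rho) <- 1
  rho
}

#' Count per-candidate threshold exceedances
#'
#' For each candidate, the number of OTHER candidates whose absolute
#' correlation with it is at or above the threshold (`NA` counts as
#' exceeding).
#'
#' @param rho_matrix Symmetric correlation matrix.
#' @param threshold Absolute-correlation threshold.
#' @return Named integer vector.
#' @export
count_exceedances <- function(rho_matrix, threshold = 0.4) {
  if (!is.matrix(rho_matrix) || nrow(rho_matrix) != ncol(rho_matrix)) {
    abort("`rho_matrix` must be square.", class = "mcdt_validation_error")
  }
  exceeds <- is.na(rho_matrix) | abs(rho_matrix) >= threshold
  diag(exceeds) <- FALSE
  setNames(as.integer(rowSums(exceeds)), rownames(rho_matrix))
}

#' Cohen's d effect size
#'
#' `(mean_a - mean_b) / s_pooled` with the usual (n-1)-weighted pooled
#' standard deviation. Zero pooled SD yields 0 with a warning.
#'
#' @param values_group_a,values_group_b Numeric vectors (each n >= 2).
#' @return Signed effect size (selection uses its absolute value).
#' @export
cohens_d <- function(values_group_a, values_group_b) {
  a <- values_group_a[!is.na(values_group_a)]
  b <- values_group_b[!is.na(values_group_b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Cohen's d needs >= 2 values per group.",
          class = "mcdt_validation_error")
  }
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) {
    warn("Zero pooled SD in Cohen's d; returning 0.")
    return(0)
  }
  (mean(a) - mean(b)) / sp
}

# Class-discrimination strength of one candidate: the largest absolute
# pairwise Cohen's d over the class pairs with >= 2 values each.
candidate_effect_size <- function(values, labels) {
  labels <- as.character(labels)
  pairs <- combn(DIAGNOSES[DIAGNOSES %in% unique(labels)], 2,
                 simplify = FALSE)
  ds <- vapply(pairs, function(p) {
    va <- values[labels == p[1]]
    vb <- values[labels == p[2]]
    if (sum(!is.na(va)) < 2 || sum(!is.na(vb)) < 2) {
      abort("Effect-size tie-break needs >= 2 subjects per class.",
            class = "mcdt_validation_error")
    }
    abs(suppressWarnings(cohens_d(va, vb)))
  }, 0)
  max(ds)
}

#' Select the components of one pooled index
#'
#' Iterative correlation screening: while more candidates remain than
#' `max_components` or any pairwise |rho| reaches the threshold, delete one
#' candidate — the unique holder of the highest exceedance count
#' (criterion 2); on a tie, the tied candidate with the weakest
#' class-discriminating effect size (criterion 3, max pairwise |Cohen's d|
#' over CNA/SCI/MCI pairs); on a further tie, the first match in
#' `tie_break_manual`, else the lexicographically smallest identity with a
#' loud warning (criterion 4). The correlation matrix is recomputed after
#' every deletion. The full elimination history is returned as an audit
#' trail.
#'
#' @param candidates Subjects x candidates matrix with orientation
#'   attribute (see [assemble_candidates()]).
#' @param labels Per-subject diagnosis labels aligned with the matrix rows.
#' @param config A [selection_config()].
#' @param name PI name stored on the model (default `"PI"`).
#' @return An object of class `mcdt_pi_model`: list with `name`,
#'   `components`, `orientation` (named +/-1), `normalization` (type;
#'   parameters filled by [score_pi()]), `audit_trail` (tibble of
#'   eliminations plus the termination record) and `config`.
#' @export
select_components <- function(candidates, labels,
                              config = selection_config(), name = "PI") {
  stopifnot(is.matrix(candidates))
  if (nrow(candidates) != length(labels)) {
    abort("`labels` must align with candidate matrix rows.",
          class = "mcdt_validation_error")
  }
  orientation <- attr(candidates, "orientation")
  keep <- colnames(candidates)
  trail <- list()
  step <- 0L
  repeat {
    if (length(keep) < 2) {
      trail[[length(trail) + 1L]] <- tibble(
        step = step, action = "stop", candidate = NA_character_,
        criterion = NA_integer_,
        detail = "fewer than two candidates remain")
      break
    }
    rho <- spearman_matrix(candidates[, keep, drop = FALSE])
    exc <- count_exceedances(rho, config$rho_threshold)
    if (length(keep) <= config$max_components && all(exc == 0)) {
      trail[[length(trail) + 1L]] <- tibble(
        step = step, action = "stop", candidate = NA_character_,
        criterion = NA_integer_,
        detail = sprintf(
          "all pairwise |rho| < %.3g and %d component(s) <= max %d",
          config$rho_threshold, length(keep), config$max_components))
      break
    }
    step <- step + 1L
    mx <- max(exc)
    tied <- names(exc)[exc == mx]
    if (length(tied) == 1) {
      drop <- tied
      crit <- 2L
      detail <- sprintf("unique max exceedance count %d", mx)
    } else {
      es <- vapply(tied, function(cd) {
        candidate_effect_size(candidates[, cd], labels)
      }, 0)
      weakest <- tied[es == min(es)]
      if (length(weakest) == 1) {
        drop <- weakest
        crit <- 3L
        detail <- sprintf(
          "tie on exceedance count %d; weakest effect size |d| = %.4g",
          mx, min(es))
      } else {
        manual <- intersect(config$tie_break_manual, weakest)
        if (length(manual)) {
          drop <- manual[1]
          crit <- 4L
          detail <- "manual priority list"
        } else {
          drop <- sort(weakest)[1]
          crit <- 4L
          detail <- "no manual priority given; lexicographic fallback"
          warn(paste0(
            "PI ", name, ": criteria 2-3 tied among {",
            paste(weakest, collapse = ", "),
            "}; no manual priority supplied, dropping lexicographically ",
            "smallest candidate ", drop, "."))
        }
      }
    }
    keep <- setdiff(keep, drop)
    trail[[length(trail) + 1L]] <- tibble(
      step = step, action = "delete", candidate = drop,
      criterion = crit, detail = detail)
  }
  structure(
    list(name = name, components = keep,
         orientation = orientation[keep],
         normalization = list(type = config$normalization, params = NULL),
         audit_trail = dplyr::bind_rows(trail),
         config = config),
    class = "mcdt_pi_model")
}

#' @export
print.mcdt_pi_model <- function(x, ...) {
  cat(sprintf("<mcdt_pi_model> PI_(%s): %d component(s)\n", x$name,
              length(x$components)))
  cat(paste0("  ", x$components, " (", ifelse(x$orientation > 0, "+", "-"),
             ")", collapse = "\n"), "\n")
  invisible(x)
}

fit_pi_normalization <- function(model, candidates) {
  vals <- candidates[, model$components, drop = FALSE]
  oriented <- sweep(vals, 2, model$orientation[model$components], `*`)
  params <- lapply(seq_len(ncol(oriented)), function(j) {
    v <- oriented[, j]
    if (model$normalization$type == "minmax") {
      list(lo = min(v, na.rm = TRUE), hi = max(v, na.rm = TRUE))
    } else {
      list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    }
  })
  names(params) <- model$components
  model$normalization$params <- params
  model
}

#' Score subjects on a pooled index
#'
#' Orients each component so that a higher value means better functioning,
#' normalises it (min-max to \[0, 1\] by default; parameters are fitted on
#' the supplied matrix on first use and stored in the model), and averages
#' the normalised components into one PI score per subject. Subjects
#' missing any component value get `NA` (logged).
#'
#' @param model An `mcdt_pi_model`.
#' @param candidates Candidate matrix containing the model's components.
#' @return List: `scores` tibble (`subject`, `pi`) and the (possibly
#'   updated) `model` with normalization parameters.
#' @export
score_pi <- function(model, candidates) {
  miss <- setdiff(model$components, colnames(candidates))
  if (length(miss)) {
    abort(paste0("Candidate matrix lacks model component(s): ",
                 paste(miss, collapse = ", ")),
          class = "mcdt_validation_error")
  }
  if (is.null(model$normalization$params)) {
    model <- fit_pi_normalization(model, candidates)
  }
  vals <- candidates[, model$components, drop = FALSE]
  oriented <- sweep(vals, 2, model$orientation[model$components], `*`)
  normed <- vapply(seq_along(model$components), function(j) {
    p <- model$normalization$params[[model$components[j]]]
    v <- oriented[, j]
    if (model$normalization$type == "minmax") {
      if (p$hi == p$lo) rep(0.5, length(v)) else (v - p$lo) / (p$hi - p$lo)
    } else {
      if (p$sd == 0) rep(0, length(v)) else (v - p$mean) / p$sd
    }
  }, numeric(nrow(vals)))
  normed <- matrix(normed, nrow = nrow(vals))
  pi_score <- unname(rowMeans(normed))
  n_miss <- sum(is.na(pi_score))
  if (n_miss) {
    inform(paste0("PI ", model$name, ": ", n_miss,
                  " subject(s) missing a component value; PI set to NA."))
  }
  list(scores = tibble(subject = rownames(candidates), pi = pi_score),
       model = model)
}

#' Build all five pooled indices
#'
#' Constructs PI_(FTAP), PI_(TTHP), PI_(GAIT), PI_(TAPPING) (FTAP + TTHP
#' candidates) and PI_(TOTAL) (all three exercises) from a DTC* table:
#' candidate assembly, component selection, orientation, normalization and
#' scoring for each index.
#'
#' @param dtc An `mcdt_dtc_table`.
#' @param labels Per-subject diagnosis labels, named by subject id or
#'   aligned with the DTC table's subjects.
#' @param config A [selection_config()].
#' @return List with `models` (named list of five `mcdt_pi_model`) and
#'   `scores` (tibble: `subject`, one column per PI name).
#' @export
build_all_pis <- function(dtc, labels, config = selection_config()) {
  subjects <- sort(unique(dtc$subject))
  if (!is.null(names(labels))) labels <- labels[subjects]
  models <- list()
  scores <- tibble(subject = subjects)
  for (nm in PI_NAMES) {
    cand <- assemble_candidates(dtc, pi_exercises(nm), config)
    cand <- candidate_rows(cand, subjects)
    model <- select_components(cand, labels, config, name = nm)
    sc <- score_pi(model, cand)
    models[[nm]] <- sc$model
    stopifnot(identical(sc$scores$subject, subjects))
    scores[[nm]] <- sc$scores$pi
  }
  list(models = models, scores = scores)
}
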