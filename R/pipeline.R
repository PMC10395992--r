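# One-call orchestration: generate (or load) the cohort, compute DTC*,
# build the five pooled indices, run the descriptive statistics and the
# 20-evaluation model battery, and write every artifact with provenance.

#' Full pipeline configuration
#'
#' @param input `"synthetic"` (default) or a list
#'   `list(features = <path>, subjects = <path>, orientation = <path>)` of
#'   files readable by [read_feature_table()] / [read_subject_records()].
#' @param cohort A [cohort_spec()] used when `input = "synthetic"`; its
#'   `seed` is overridden by `seed` below.
#' @param bounds A [rescale_bounds()].
#' @param selection A [selection_config()].
#' @param ridge L2 stabiliser for the logistic fits.
#' @param alpha Significance level for the descriptive post hocs.
#' @param out_dir Output directory (created; default `tempfile()`).
#' @param seed Integer seed controlling every random draw of the run.
#' @param fold_safe If `TRUE`, the battery refits PI selection and
#'   normalization inside every LOOCV training fold (slower, leakage-free)
#'   instead of the single-pass construction.
#' @param ... Unknown arguments are rejected, not silently ignored.
#' @return List of class `mcdt_pipeline_config`.
#' @export
pipeline_config <- function(input = "synthetic", cohort = cohort_spec(),
                            bounds = rescale_bounds(),
                            selection = selection_config(),
                            ridge = 1e-6, alpha = 0.05,
                            out_dir = tempfile("mcdt_run_"),
                            seed = 1L, fold_safe = FALSE, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("Unknown pipeline config key(s): ",
                 paste(names(extra), collapse = ", ")),
          class = "mcdt_validation_error")
  }
  if (!identical(input, "synthetic")) {
    if (!is.list(input) || !all(c("features", "subjects") %in% names(input))) {
      abort("`input` must be \"synthetic\" or list(features=, subjects=, orientation=).",
            class = "mcdt_validation_error")
    }
  }
  cohort$seed <- as.integer(seed)
  structure(list(input = input, cohort = validate_cohort_spec(cohort),
                 bounds = bounds, selection = selection, ridge = ridge,
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
                 fold_safe = fold_safe),
            class = "mcdt_pipeline_config")
}

config_hash <- function(config) {
  c2 <- config
  c2$out_dir <- NULL
  rlang::hash(lapply(unclass(c2), function(x) {
    if (is.list(x)) unclass(x) else x
  }))
}

#' Run the full MCDT analysis pipeline
#'
#' Stages: (1) generate or load the cohort; (2) compute classical and
#' weighted dual-task costs; (3) build the five pooled indices; (4)
#' descriptive group statistics; (5) the ten-model two- and three-class
#' LOOCV battery. All machine-readable artifacts (long DTC table, PI
#' models with audit trails, PI scores, descriptives, battery report,
#' run manifest) are written under `config$out_dir`. Deterministic given
#' the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the in-memory artifacts
#'   are attached as the `"artifacts"` attribute.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "mcdt_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)),
            class = "mcdt_pipeline_error", parent = e)
    })
  }

  if (identical(config$input, "synthetic")) {
    cohort <- stage("cohort", generate_cohort(config$cohort))
    tables <- cohort_to_tables(cohort)
  } else {
    tables <- stage("cohort", list(
      features = read_feature_table(
        config$input$features,
        orientation = config$input$orientation %||% NULL),
      subjects = read_subject_records(config$input$subjects)))
  }
  features <- tables$features
  subjects <- tables$subjects
  write_feature_table(
    features, file.path(config$out_dir, "feature_table.csv"),
    orientation_path = file.path(config$out_dir, "orientation.csv"))
  write_subject_records(subjects,
                        file.path(config$out_dir, "subjects.csv"))

  dtc <- stage("dtc", compute_dtc_star(features, config$bounds))
  readr::write_csv(dtc, file.path(config$out_dir, "dtc_table.csv"))
  inform(sprintf("dtc: %d cells, %d flagged degenerate", nrow(dtc),
                 sum(dtc$flagged)))

  labels <- setNames(as.character(subjects$diagnosis), subjects$subject)
  pis <- stage("pooled_index", suppressWarnings(
    build_all_pis(dtc, labels, config$selection)))
  write_report(pis$models, file.path(config$out_dir, "pi_models.csv"),
               seed = config$seed, config_hash = chash)
  readr::write_csv(pis$scores, file.path(config$out_dir, "pi_scores.csv"))
  inform(sprintf("pooled_index: %s",
                 paste(sprintf("%s=%d", names(pis$models),
                               vapply(pis$models, function(m)
                                 length(m$components), 0L)),
                       collapse = " ")))

  descriptives <- stage("group_stats",
                        summarize_cohort(subjects, alpha = config$alpha))
  write_report(descriptives,
               file.path(config$out_dir, "descriptives.csv"),
               seed = config$seed, config_hash = chash)

  battery <- stage("classification", {
    if (config$fold_safe) {
      run_battery_fold_safe(dtc, subjects, config)
    } else {
      run_model_battery(pis$scores, subjects, ridge = config$ridge)
    }
  })
  write_report(battery, file.path(config$out_dir, "battery_report.csv"),
               seed = config$seed, config_hash = chash)
  readr::write_csv(battery$per_class,
                   file.path(config$out_dir, "per_class_metrics.csv"))

  manifest <- list(
    package = "mcdtpi",
    version = as.character(utils::packageVersion("mcdtpi")),
    seed = config$seed, config_hash = chash,
    fold_safe = config$fold_safe,
    n_subjects = nrow(subjects),
    n_dtc_cells = nrow(dtc), n_flagged = sum(dtc$flagged),
    pi_sizes = vapply(pis$models, function(m) length(m$components), 0L))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    config$out_dir,
    artifacts = list(features = features, subjects = subjects,
                     dtc = dtc, pis = pis, descriptives = descriptives,
                     battery = battery, manifest = manifest)))
}

# Fold-safe battery: every model evaluation re-selects and re-normalises
# the PI inside each training fold.
run_battery_fold_safe <- function(dtc, subjects, config) {
  combos <- list(c("PI", "AGE"), c("PI", "AGE", "FAB"))
  rows <- list()
  per_class <- list()
  confusions <- list()
  for (regs in combos) {
    for (nm in PI_NAMES) {
      for (prob in c("two_class", "three_class")) {
        spec <- model_spec(nm, regs, prob, ridge = config$ridge)
        cv <- loocv_fold_safe(dtc, subjects, spec, config$selection)
        met <- compute_metrics(cv$confusion, prob)
        key <- paste0("PI_", nm, "+", paste(setdiff(regs, "PI"),
                                            collapse = "+"), ":", prob)
        confusions[[key]] <- cv$confusion
        base <- tibble(
          model = paste0("PI_(", nm, "), ",
                         paste(setdiff(regs, "PI"), collapse = ", ")),
          pi = nm, regressors = paste(regs, collapse = "+"),
          problem = prob, n = sum(cv$confusion))
        if (prob == "two_class") {
          rows[[key]] <- dplyr::mutate(base, sen = met$sen, spe = met$spe,
                                       acc = met$acc, rec_w = NA_real_,
                                       prec_w = NA_real_, f1_w = NA_real_)
        } else {
          rows[[key]] <- dplyr::mutate(base, sen = NA_real_, spe = NA_real_,
                                       acc = met$acc, rec_w = met$recall_w,
                                       prec_w = met$precision_w,
                                       f1_w = met$f1_w)
          pc <- met$per_class
          pc$pi <- nm
          pc$regressors <- paste(regs, collapse = "+")
          per_class[[key]] <- pc
        }
      }
    }
  }
  structure(list(summary = dplyr::bind_rows(rows),
                 per_class = dplyr::bind_rows(per_class),
                 confusions = confusions),
            class = "mcdt_metrics_report")
}
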