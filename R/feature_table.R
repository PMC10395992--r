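# Containers for the per-subject motor feature tensor f_i(Ex, CL_k, s_j),
# the correct-response counts Nc(Ex, CL_k, s_j), and per-feature orientation
# metadata (whether a higher raw value indicates greater functioning).

#' Construct a validated MCDT feature table
#'
#' Bundles the long-format motor feature values, the correct-response counts
#' and the per-feature orientation metadata into one validated object.
#'
#' @param features Tibble/data frame with columns `subject`, `exercise`
#'   (one of FTAP/TTHP/GAIT), `load` (integer 0-3), `feature` (e.g. "f01"),
#'   `value` (numeric).
#' @param counts Tibble with columns `subject`, `exercise`, `load` (1-3 only:
#'   no counting happens at the single-task baseline), `nc` (integer >= 0).
#' @param orientation Tibble with columns `exercise`, `feature`,
#'   `higher_better` (logical). Defaults to `NA` orientation for features not
#'   listed; pooled-index construction requires it to be complete.
#' @param canonical If `TRUE` (default), require the full canonical design:
#'   exactly 32 feature identities (8 FTAP + 8 TTHP + 16 GAIT), all four
#'   loads, a complete block per subject, and counts for every subject x
#'   exercise x dual-task load. Set `FALSE` for reduced tables in unit
#'   fixtures.
#' @return An object of class `mcdt_feature_table`: a list with elements
#'   `features`, `counts`, `orientation` (tibbles) and `subjects` (character
#'   vector of subject ids in first-appearance order).
#' @export
feature_table <- function(features, counts, orientation = NULL,
                          canonical = TRUE) {
  features <- as_tibble(features)
  counts <- as_tibble(counts)
  req <- c("subject", "exercise", "load", "feature", "value")
  if (!all(req %in% names(features))) {
    abort(paste0("`features` must have columns ",
                 paste(req, collapse = ", "), "; missing: ",
                 paste(setdiff(req, names(features)), collapse = ", ")),
          class = "mcdt_schema_error")
  }
  reqc <- c("subject", "exercise", "load", "nc")
  if (!all(reqc %in% names(counts))) {
    abort(paste0("`counts` must have columns ",
                 paste(reqc, collapse = ", "), "; missing: ",
                 paste(setdiff(reqc, names(counts)), collapse = ", ")),
          class = "mcdt_schema_error")
  }
  features$subject <- as.character(features$subject)
  counts$subject <- as.character(counts$subject)
  features$load <- as.integer(features$load)
  counts$load <- as.integer(counts$load)

  bad_ex <- setdiff(unique(features$exercise), EXERCISES)
  if (length(bad_ex)) {
    abort(paste0("Unknown exercise label(s): ",
                 paste(bad_ex, collapse = ", "),
                 ". Allowed: ", paste(EXERCISES, collapse = ", ")),
          class = "mcdt_schema_error")
  }
  if (!is.numeric(features$value)) {
    abort("Feature `value` column must be numeric.",
          class = "mcdt_parse_error")
  }
  if (any(!features$load %in% LOADS)) {
    abort("Feature `load` must be one of 0, 1, 2, 3.",
          class = "mcdt_schema_error")
  }
  if (any(!counts$load %in% DT_LOADS)) {
    bad <- which(!counts$load %in% DT_LOADS)
    abort(paste0("Nc counts are defined only for dual-task loads 1-3 ",
                 "(no counting at baseline load 0); offending rows: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "mcdt_schema_error")
  }
  if (any(counts$nc < 0) || any(counts$nc != round(counts$nc))) {
    abort("Nc must be a nonnegative integer.", class = "mcdt_schema_error")
  }
  counts$nc <- as.integer(counts$nc)

  dup <- duplicated(features[c("subject", "exercise", "load", "feature")])
  if (any(dup)) {
    abort(paste0("Duplicated (subject, exercise, load, feature) cells at rows: ",
                 paste(head(which(dup), 5), collapse = ", ")),
          class = "mcdt_schema_error")
  }
  dupc <- duplicated(counts[c("subject", "exercise", "load")])
  if (any(dupc)) {
    abort("Duplicated (subject, exercise, load) count cells.",
          class = "mcdt_schema_error")
  }

  ids <- feature_identities()
  if (is.null(orientation)) {
    orientation <- ids
    orientation$higher_better <- NA
  }
  orientation <- as_tibble(orientation)

  subjects <- unique(features$subject)
  if (canonical && length(subjects) > 0) {
    want <- merge(merge(ids, data.frame(load = LOADS)),
                  data.frame(subject = subjects))
    have <- features[c("subject", "exercise", "load", "feature")]
    missing <- dplyr::anti_join(
      as_tibble(want), have,
      by = c("subject", "exercise", "load", "feature"))
    if (nrow(missing)) {
      ex1 <- missing[seq_len(min(5, nrow(missing))), ]
      abort(paste0(
        nrow(missing), " missing mandatory feature cell(s), e.g. ",
        paste(sprintf("%s/%s/CL%d/%s", ex1$subject, ex1$exercise,
                      ex1$load, ex1$feature), collapse = "; ")),
        class = "mcdt_schema_error")
    }
    extra <- dplyr::anti_join(have, as_tibble(want),
                              by = c("subject", "exercise", "load", "feature"))
    if (nrow(extra)) {
      abort(paste0(nrow(extra),
                   " feature cell(s) outside the 32-identity canonical design."),
            class = "mcdt_schema_error")
    }
    wantc <- merge(merge(data.frame(exercise = EXERCISES),
                         data.frame(load = DT_LOADS)),
                   data.frame(subject = subjects))
    missc <- dplyr::anti_join(as_tibble(wantc),
                              counts[c("subject", "exercise", "load")],
                              by = c("subject", "exercise", "load"))
    if (nrow(missc)) {
      abort(paste0(nrow(missc), " missing Nc count cell(s)."),
            class = "mcdt_schema_error")
    }
  }

  structure(
    list(features = features, counts = counts, orientation = orientation,
         subjects = subjects),
    class = "mcdt_feature_table")
}

#' @export
print.mcdt_feature_table <- function(x, ...) {
  nid <- nrow(unique(x$features[c("exercise", "feature")]))
  ncol_ <- nrow(unique(x$features[c("exercise", "feature", "load")]))
  cat(sprintf(
    "<mcdt_feature_table> %d subject(s), %d feature identit%s, %d feature column(s)\n",
    length(x$subjects), nid, if (nid == 1) "y" else "ies", ncol_))
  invisible(x)
}

#' Validate a table of subject records
#'
#' @param subjects Tibble with columns `subject`, `age`, `fab`, `diagnosis`
#'   (one of CNA/SCI/MCI) and optionally `sex`, `education`.
#' @return The validated tibble with `diagnosis` as an ordered-level factor
#'   (CNA < SCI < MCI).
#' @export
subject_records <- function(subjects) {
  subjects <- as_tibble(subjects)
  req <- c("subject", "age", "fab", "diagnosis")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) {
    abort(paste0("Subject records missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "mcdt_schema_error")
  }
  subjects$subject <- as.character(subjects$subject)
  bad <- setdiff(unique(as.character(subjects$diagnosis)), DIAGNOSES)
  if (length(bad)) {
    abort(paste0("Unknown diagnosis label(s): ", paste(bad, collapse = ", "),
                 ". Allowed labels: ", paste(DIAGNOSES, collapse = ", ")),
          class = "mcdt_schema_error")
  }
  subjects$diagnosis <- factor(subjects$diagnosis, levels = DIAGNOSES)
  if (any(!is.finite(subjects$age)) || any(subjects$age <= 0)) {
    abort("`age` must be positive and finite.", class = "mcdt_schema_error")
  }
  if (any(subjects$fab < 0 | subjects$fab > 18)) {
    abort("`fab` must lie in [0, 18] (FAB is an 18-point battery).",
          class = "mcdt_schema_error")
  }
  if (anyDuplicated(subjects$subject)) {
    abort("Duplicated subject ids in subject records.",
          class = "mcdt_schema_error")
  }
  subjects
}
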