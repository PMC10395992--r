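# Tabular input/output. Canonical storage is long format (one row per
# subject x exercise x load x feature); a wide layout (one column per
# exercise_feature_load) is supported for interoperability with
# spreadsheet-shaped exports. CSV is read and written; XLSX is read-only
# (first sheet by default). All writers add a JSON sidecar carrying
# provenance (content hash, package version, optional seed).

read_table_any <- function(path, format = c("csv", "xlsx"), sheet = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "mcdt_io_error")
  }
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readxl::read_excel(path, sheet = sheet)
  }
}

#' Read an MCDT feature table
#'
#' @param path File path (CSV or XLSX).
#' @param format `"csv"` or `"xlsx"` (XLSX is read-only in this package).
#' @param schema `"long"`: columns `subject, exercise, load, feature, value`
#'   plus optional `nc` (non-missing only where load >= 1, constant within
#'   subject x exercise x load); `"wide"`: one `value_<EX>_<fNN>_CL<k>`
#'   column per feature column and one `nc_<EX>_CL<k>` column per count.
#' @param orientation Optional tibble (`exercise`, `feature`,
#'   `higher_better`) or path to a CSV holding it. Feature orientation is
#'   study metadata, not derivable from values.
#' @param canonical Enforce the full 32-identity design (default `TRUE`).
#' @param sheet XLSX sheet (name or index).
#' @return An `mcdt_feature_table`.
#' @export
read_feature_table <- function(path, format = c("csv", "xlsx"),
                               schema = c("long", "wide"),
                               orientation = NULL, canonical = TRUE,
                               sheet = 1) {
  schema <- match.arg(schema)
  raw <- read_table_any(path, format, sheet)
  if (is.character(orientation) && length(orientation) == 1) {
    orientation <- readr::read_csv(orientation, show_col_types = FALSE)
  }
  if (schema == "long") {
    req <- c("subject", "exercise", "load", "feature", "value")
    miss <- setdiff(req, names(raw))
    if (length(miss)) {
      abort(paste0("Long schema requires columns ",
                   paste(req, collapse = ", "), "; missing: ",
                   paste(miss, collapse = ", ")),
            class = "mcdt_schema_error")
    }
    unknown <- setdiff(names(raw), c(req, "nc"))
    if (length(unknown)) {
      warn(paste0("Ignoring unknown column(s): ",
                  paste(unknown, collapse = ", ")))
    }
    if (!is.numeric(raw$value)) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw$value))))
      abort(paste0("Non-numeric feature value(s) at row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "mcdt_parse_error")
    }
    feats <- raw[c("subject", "exercise", "load", "feature", "value")]
    counts <- tibble(subject = character(), exercise = character(),
                     load = integer(), nc = integer())
    if ("nc" %in% names(raw)) {
      withnc <- raw[!is.na(raw$nc), ]
      if (any(withnc$load == 0)) {
        abort(paste0("Nc given at baseline load 0 (rows ",
                     paste(head(which(raw$load == 0 & !is.na(raw$nc)), 5),
                           collapse = ", "),
                     "): counts are defined only for dual-task loads 1-3."),
              class = "mcdt_schema_error")
      }
      counts <- unique(withnc[c("subject", "exercise", "load", "nc")])
      dup <- duplicated(counts[c("subject", "exercise", "load")])
      if (any(dup)) {
        abort("Inconsistent Nc within a (subject, exercise, load) block.",
              class = "mcdt_schema_error")
      }
    }
    feature_table(feats, counts, orientation = orientation,
                  canonical = canonical)
  } else {
    if (!"subject" %in% names(raw)) {
      abort("Wide schema requires a `subject` column.",
            class = "mcdt_schema_error")
    }
    vcols <- grep("^value_", names(raw), value = TRUE)
    ncols <- grep("^nc_", names(raw), value = TRUE)
    if (!length(vcols)) {
      abort("Wide schema: no `value_<EX>_<fNN>_CL<k>` columns found.",
            class = "mcdt_schema_error")
    }
    feats <- tidyr::pivot_longer(raw[c("subject", vcols)], -"subject",
                                 names_to = c("exercise", "feature", "load"),
                                 names_pattern = "^value_([A-Z]+)_(f\\d+)_CL(\\d)$",
                                 values_to = "value")
    feats$load <- as.integer(feats$load)
    feats <- feats[c("subject", "exercise", "load", "feature", "value")]
    counts <- tibble(subject = character(), exercise = character(),
                     load = integer(), nc = integer())
    if (length(ncols)) {
      counts <- tidyr::pivot_longer(raw[c("subject", ncols)], -"subject",
                                    names_to = c("exercise", "load"),
                                    names_pattern = "^nc_([A-Z]+)_CL(\\d)$",
                                    values_to = "nc")
      counts$load <- as.integer(counts$load)
      if (any(counts$load == 0)) {
        abort("Nc given at baseline load 0: counts exist only for loads 1-3.",
              class = "mcdt_schema_error")
      }
    }
    feature_table(feats, counts, orientation = orientation,
                  canonical = canonical)
  }
}

#' Write an MCDT feature table
#'
#' @param x An `mcdt_feature_table`.
#' @param path Output CSV path.
#' @param schema `"long"` (default) or `"wide"`.
#' @param orientation_path Optional path for the orientation metadata CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, schema = c("long", "wide"),
                                orientation_path = NULL) {
  stopifnot(inherits(x, "mcdt_feature_table"))
  schema <- match.arg(schema)
  if (schema == "long") {
    out <- dplyr::left_join(x$features, x$counts,
                            by = c("subject", "exercise", "load"))
    readr::write_csv(out, path)
  } else {
    vals <- x$features
    vals$col <- sprintf("value_%s_%s_CL%d", vals$exercise, vals$feature,
                        vals$load)
    wide_v <- tidyr::pivot_wider(vals[c("subject", "col", "value")],
                                 names_from = "col", values_from = "value")
    cts <- x$counts
    if (nrow(cts)) {
      cts$col <- sprintf("nc_%s_CL%d", cts$exercise, cts$load)
      wide_c <- tidyr::pivot_wider(cts[c("subject", "col", "nc")],
                                   names_from = "col", values_from = "nc")
      wide_v <- dplyr::left_join(wide_v, wide_c, by = "subject")
    }
    readr::write_csv(wide_v, path)
  }
  if (!is.null(orientation_path)) {
    readr::write_csv(x$orientation, orientation_path)
  }
  invisible(path)
}

#' Read subject records
#'
#' @inheritParams read_feature_table
#' @return Validated tibble of subject records (see [subject_records()]).
#' @export
read_subject_records <- function(path, format = c("csv", "xlsx"), sheet = 1) {
  subject_records(read_table_any(path, format, sheet))
}

#' Write subject records
#' @param subjects Validated subject tibble.
#' @param path Output CSV path.
#' @export
write_subject_records <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an analysis report with a JSON provenance sidecar
#'
#' Writes the human-readable CSV form of a report and a machine-readable
#' JSON sidecar holding the full artifact plus provenance (content hash,
#' package version, optional seed and config hash).
#'
#' @param report An `mcdt_metrics_report`, `mcdt_pi_model`, list of PI
#'   models, `mcdt_descriptives`, or plain data frame.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param seed,config_hash Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL, config_hash = NULL) {
  tab <- report_as_table(report)
  readr::write_csv(tab, path)
  payload <- list(
    artifact = report_as_list(report),
    provenance = list(
      content_hash = rlang::hash(report_as_list(report)),
      package = "mcdtpi",
      version = as.character(utils::packageVersion("mcdtpi")),
      seed = seed, config_hash = config_hash))
  jsonlite::write_json(payload, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back the JSON sidecar of a written report
#' @param path The CSV path passed to [write_report()].
#' @return The parsed sidecar list.
#' @export
read_report_sidecar <- function(path) {
  jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
}

report_as_table <- function(report) {
  if (inherits(report, "mcdt_metrics_report")) return(report$summary)
  if (inherits(report, "mcdt_descriptives")) return(report$continuous)
  if (inherits(report, "mcdt_pi_model")) {
    return(tibble(index = report$name, component = report$components,
                  orientation = unname(report$orientation[report$components])))
  }
  if (is.list(report) && length(report) &&
      all(vapply(report, inherits, TRUE, "mcdt_pi_model"))) {
    return(dplyr::bind_rows(lapply(report, report_as_table)))
  }
  as_tibble(report)
}

report_as_list <- function(report) {
  if (is.data.frame(report)) return(as.list(as_tibble(report)))
  unclass_deep <- function(x) {
    if (is.table(x)) return(as.list(as.data.frame(x)))
    if (is.data.frame(x)) return(as.list(as_tibble(x)))
    if (is.list(x)) return(lapply(unclass(x), unclass_deep))
    x
  }
  unclass_deep(report)
}
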