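# Descriptive group comparisons: Kruskal-Wallis omnibus tests across the
# three diagnostic groups, Bonferroni-corrected pairwise Mann-Whitney post
# hocs, and chi-squared tests for categorical variables, summarised in the
# median (IQR) layout of a clinical characteristics table.

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with the chi-squared approximation. When every
#' value is identical across all groups the statistic is 0 and p = 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 nonempty).
#' @return List with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (sum(lengths(groups) > 0) < 2) {
    abort("Kruskal-Wallis needs >= 2 nonempty groups.",
          class = "mcdt_validation_error")
  }
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(x, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided U tests for every group pair; adjusted p is `min(1, m * p)`
#' with m the number of pairs. Exact p-values are used for small untied
#' samples (both n <= 8, no ties), the tie-corrected normal approximation
#' otherwise.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param alpha Significance level applied to adjusted p-values.
#' @return Tibble: `group_a, group_b, u, p_value, p_adjusted, significant`.
#' @export
pairwise_mannwhitney_bonferroni <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  if (any(lengths(groups) < 2)) {
    abort("Each group needs >= 2 values for the Mann-Whitney post hoc.",
          class = "mcdt_validation_error")
  }
  pairs <- combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(p) {
    a <- groups[[p[1]]]
    b <- groups[[p[2]]]
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = exact, correct = !exact))
    padj <- min(1, m * wt$p.value)
    tibble(group_a = p[1], group_b = p[2], u = unname(wt$statistic),
           p_value = wt$p.value, p_adjusted = padj,
           significant = padj < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Pearson chi-squared test of a contingency table
#'
#' No continuity correction; df = (r-1)(c-1).
#'
#' @param contingency Matrix/table of nonnegative integer counts, at least
#'   2x2, with no all-zero row or column.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("Contingency table must be at least 2x2.",
          class = "mcdt_validation_error")
  }
  if (any(m < 0) || any(m != round(m))) {
    abort("Contingency table must hold nonnegative integer counts.",
          class = "mcdt_validation_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Contingency table has an all-zero row or column.",
          class = "mcdt_validation_error")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

iqr_linear <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE)
  unname(q[2] - q[1])
}

#' Descriptive group comparison report
#'
#' Per-group median and IQR (linear-interpolation quantiles) for continuous
#' variables with the Kruskal-Wallis omnibus p-value and
#' Bonferroni-corrected pairwise Mann-Whitney post hocs (flags a/b/c for
#' CNA-SCI, CNA-MCI, SCI-MCI); counts/percentages and chi-squared tests for
#' categorical variables.
#'
#' @param subjects Validated subject records.
#' @param continuous Continuous variable names (default age, fab).
#' @param categorical Categorical variable names present in `subjects`
#'   (default: whichever of sex/education exist).
#' @param alpha Significance level for post hoc flags.
#' @return Object of class `mcdt_descriptives`: `continuous`, `pairwise`,
#'   `categorical` tibbles.
#' @export
summarize_cohort <- function(subjects, continuous = c("age", "fab"),
                             categorical = intersect(c("sex", "education"),
                                                     names(subjects)),
                             alpha = 0.05) {
  subjects <- subject_records(subjects)
  groups_of <- function(v) {
    lapply(setNames(DIAGNOSES, DIAGNOSES), function(d) {
      subjects[[v]][subjects$diagnosis == d]
    })
  }
  flag_letter <- c("CNA-SCI" = "a", "CNA-MCI" = "b", "SCI-MCI" = "c")

  cont_rows <- list()
  pw_rows <- list()
  for (v in continuous) {
    gs <- groups_of(v)
    empty <- lengths(gs) == 0
    med <- vapply(gs, function(g) if (length(g)) median(g) else NA_real_, 0)
    iqr <- vapply(gs, function(g) if (length(g)) iqr_linear(g) else NA_real_, 0)
    singletons <- any(lengths(gs) == 1)
    if (sum(!empty) >= 2 && !singletons) {
      kw <- kruskal_wallis(gs[!empty])
      pw <- pairwise_mannwhitney_bonferroni(gs[!empty], alpha)
      pw$pair <- paste(pw$group_a, pw$group_b, sep = "-")
      pw$flag <- unname(flag_letter[pw$pair])
      pw$variable <- v
      pw_rows[[v]] <- pw
      omni_p <- kw$p_value
      flags <- paste(pw$flag[pw$significant], collapse = ",")
    } else {
      if (singletons) {
        abort(paste0("Variable `", v, "`: a group has a single subject; ",
                     "omnibus and post hoc tests are not computable."),
              class = "mcdt_validation_error")
      }
      omni_p <- NA_real_
      flags <- ""
    }
    cont_rows[[v]] <- tibble(
      variable = v, group = names(med), n = unname(lengths(gs)),
      median = unname(med), iqr = unname(iqr),
      omnibus_p = omni_p, significant_pairs = flags)
  }

  cat_rows <- list()
  for (v in categorical) {
    tab <- table(subjects[[v]], subjects$diagnosis)
    test <- tryCatch(chi_square(tab), error = function(e) NULL)
    counts <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
    names(counts) <- c("level", "group", "n")
    counts$variable <- v
    counts$pct <- 100 * counts$n /
      vapply(counts$group, function(g) sum(subjects$diagnosis == g), 0)
    counts$chisq_p <- if (is.null(test)) NA_real_ else test$p_value
    cat_rows[[v]] <- counts
  }

  structure(list(continuous = dplyr::bind_rows(cont_rows),
                 pairwise = dplyr::bind_rows(pw_rows),
                 categorical = dplyr::bind_rows(cat_rows)),
            class = "mcdt_descriptives")
}

#' @export
print.mcdt_descriptives <- function(x, ...) {
  cat("<mcdt_descriptives>\n")
  print(as.data.frame(x$continuous), row.names = FALSE)
  invisible(x)
}
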