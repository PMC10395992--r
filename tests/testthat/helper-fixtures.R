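# In-code fixtures shared across test files.

# A small non-canonical feature table: `n` subjects, one exercise (FTAP),
# two features, all four loads, counts decreasing with load.
small_feature_table <- function(n = 3, seed = 42) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(subject = sprintf("P%d", seq_len(n)),
                               exercise = "FTAP", load = 0:3,
                               feature = c("f01", "f02"))
    grid$value <- runif(nrow(grid), 5, 15)
    counts <- tidyr::expand_grid(subject = sprintf("P%d", seq_len(n)),
                                 exercise = "FTAP", load = 1:3)
    counts$nc <- sample(0:15, nrow(counts), replace = TRUE)
    orient <- data.frame(exercise = "FTAP", feature = c("f01", "f02"),
                         higher_better = c(TRUE, FALSE))
    feature_table(grid, counts, orientation = orient, canonical = FALSE)
  })
}

# A random candidate matrix with orientation metadata and class labels.
random_candidates <- function(n_sub = 20, n_cand = 10, seed = 1,
                              block = 0) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_sub * n_cand), n_sub, n_cand)
    if (block > 0) {
      base <- rnorm(n_sub)
      for (j in seq_len(block)) {
        x[, j] <- base + rnorm(n_sub, 0, 0.2)
      }
    }
    colnames(x) <- sprintf("C%02d", seq_len(n_cand))
    rownames(x) <- sprintf("P%02d", seq_len(n_sub))
    attr(x, "orientation") <- setNames(rep(1, n_cand), colnames(x))
    labels <- rep(c("CNA", "SCI", "MCI"), length.out = n_sub)
    list(x = x, labels = labels)
  })
}

# A cohort spec whose labels are fully exchangeable: no motor or count
# effect and class-independent age/FAB distributions.
null_cohort_spec <- function(seed) {
  cohort_spec(effect_size = 0,
              age_params = list(CNA = c(70, 9), SCI = c(70, 9),
                                MCI = c(70, 9)),
              fab_params = list(CNA = c(16, 1.5), SCI = c(16, 1.5),
                                MCI = c(16, 1.5)),
              seed = seed)
}
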