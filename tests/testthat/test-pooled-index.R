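test_that("Spearman matrix matches the rank-then-Pearson oracle", {
  x <- withr::with_seed(9, matrix(rnorm(15), 5, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  rho <- spearman_matrix(x)
  expect_equal(rho, oracle_spearman(x), tolerance = 1e-12)
  expect_equal(diag(rho), setNames(rep(1, 3), c("a", "b", "c")))
  expect_equal(rho, t(rho))
  # rank invariance and antisymmetry
  y <- cbind(u = x[, 1], v = exp(x[, 1]), w = -x[, 1])
  rho2 <- spearman_matrix(y)
  expect_equal(unname(rho2["u", "v"]), 1)
  expect_equal(unname(rho2["u", "w"]), -1)
  expect_error(spearman_matrix(x[1:2, ]), ">= 3 subjects",
               class = "mcdt_validation_error")
})

test_that("exceedance counting matches an exhaustive pair loop", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      x <- matrix(rnorm(60), 10, 6,
                  dimnames = list(NULL, sprintf("c%d", 1:6)))
      rho <- spearman_matrix(x)
      expect_equal(count_exceedances(rho, 0.4), oracle_exceed(rho, 0.4))
    }
  })
  # forced cases
  lowrho <- diag(3) * 0.99 + 0.01
  dimnames(lowrho) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(count_exceedances(lowrho, 0.4)), c(0L, 0L, 0L))
  dup <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(count_exceedances(dup, 0.4)), c(1L, 1L, 0L))
  # a constant candidate's undefined correlations count as exceedances
  xc <- cbind(a = rnorm(6), b = rep(2, 6), c = rnorm(6))
  rhoc <- spearman_matrix(xc)
  expect_true(all(is.na(rhoc["b", c("a", "c")])))
  expect_equal(unname(count_exceedances(rhoc, 0.4)["b"]), 2L)
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(-1, 0, 1) # mean 0, sd 1
  b <- c(0, 1, 2)  # mean 1, sd 1
  expect_equal(abs(cohens_d(a, b)), 1)
  # unequal n against the textbook formula
  a2 <- c(2.3, 4.1, 3.3, 5.0, 2.8)
  b2 <- c(4.6, 5.9, 5.1)
  expect_equal(cohens_d(a2, b2), oracle_cohens_d(a2, b2), tolerance = 1e-12)
  expect_warning(d0 <- cohens_d(c(2, 2, 2), c(2, 2)), "Zero pooled SD")
  expect_equal(d0, 0)
  expect_error(cohens_d(1, c(1, 2)), ">= 2",
               class = "mcdt_validation_error")
})

test_that("selection stops immediately when no pair reaches the threshold", {
  withr::with_seed(8, {
    x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, letters[1:4]))
    attr(x, "orientation") <- setNames(rep(1, 4), letters[1:4])
  })
  labels <- rep(c("CNA", "SCI", "MCI"), length.out = 100)
  m <- select_components(x, labels)
  expect_setequal(m$components, letters[1:4])
  expect_equal(sum(m$audit_trail$action == "delete"), 0)
})

test_that("a duplicated candidate loses one member first", {
  withr::with_seed(3, {
    x <- matrix(rnorm(800), 100, 8)
    x[, 8] <- x[, 1] + rnorm(100, 0, 1e-6)
    colnames(x) <- sprintf("c%d", 1:8)
    attr(x, "orientation") <- setNames(rep(1, 8), colnames(x))
  })
  labels <- rep(c("CNA", "SCI", "MCI"), length.out = 100)
  m <- select_components(x, labels)
  first_del <- m$audit_trail$candidate[m$audit_trail$action == "delete"][1]
  expect_true(first_del %in% c("c1", "c8"))
  expect_false(all(c("c1", "c8") %in% m$components))
})

test_that("selection equals the brute-force flowchart oracle", {
  for (s in 1:20) {
    rc <- random_candidates(n_sub = 21, n_cand = 10, seed = 100 + s,
                            block = 4)
    m <- suppressWarnings(
      select_components(rc$x, rc$labels, selection_config()))
    expect_equal(sort(m$components),
                 oracle_select(rc$x, rc$labels, 0.4, 6),
                 info = paste("fixture seed", 100 + s))
  }
})

test_that("the audit trail records every elimination and the stop branch", {
  rc <- random_candidates(n_sub = 21, n_cand = 10, seed = 77, block = 5)
  m <- suppressWarnings(select_components(rc$x, rc$labels))
  tr <- m$audit_trail
  expect_equal(sum(tr$action == "delete"),
               ncol(rc$x) - length(m$components))
  expect_equal(tr$action[nrow(tr)], "stop")
  expect_true(all(tr$criterion[tr$action == "delete"] %in% 2:4))
  # after termination all retained pairwise |rho| are below the threshold
  rho <- spearman_matrix(rc$x[, m$components])
  off <- abs(rho[upper.tri(rho)])
  expect_true(all(off < 0.4))
})

test_that("manual tie-break priority is honoured, fallback is loud", {
  # two identical pairs of constant-rank candidates force a full tie
  x <- cbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(1, 2, 3, 4, 5, 6),
             c = c(6, 5, 4, 3, 2, 1),
             d = c(6, 5, 4, 3, 2, 1))
  attr(x, "orientation") <- setNames(rep(1, 4), colnames(x))
  labels <- rep(c("CNA", "MCI"), 3)
  cfgm <- selection_config(tie_break_manual = c("d", "b"))
  # the manual list is consulted first; once exhausted the lexicographic
  # fallback takes over (loudly)
  m1 <- suppressWarnings(select_components(x, labels, cfgm))
  dels <- m1$audit_trail$candidate[m1$audit_trail$action == "delete"]
  expect_equal(dels[1:2], c("d", "b"))
  warns <- testthat::capture_warnings(
    select_components(x, labels, selection_config()))
  expect_true(any(grepl("lexicographic", warns)))
})

test_that("PI scores are oriented, bounded and polarity-invariant", {
  rc <- random_candidates(n_sub = 30, n_cand = 5, seed = 12)
  m <- select_components(rc$x, rc$labels)
  sc <- score_pi(m, rc$x)
  expect_true(all(sc$scores$pi >= 0 & sc$scores$pi <= 1))
  # the subject at the maximum of every oriented component scores 1
  xmax <- rc$x
  xmax[1, ] <- apply(rc$x, 2, max) + 1
  attr(xmax, "orientation") <- attr(rc$x, "orientation")
  sc2 <- score_pi(m, xmax) # params refit on xmax (model carries none yet)
  expect_equal(sc2$scores$pi[1], 1)
  # single-component model: PI equals the normalized component
  m1c <- m
  m1c$components <- m$components[1]
  m1c$orientation <- m$orientation[m$components[1]]
  m1c$normalization$params <- NULL
  sc1 <- score_pi(m1c, rc$x)
  v <- rc$x[, m$components[1]]
  expect_equal(sc1$scores$pi, unname((v - min(v)) / (max(v) - min(v))))
  # flipping a component's raw polarity (and its orientation flag) does
  # not change the PI
  flip <- rc$x
  j <- m$components[2]
  flip[, j] <- -flip[, j]
  attr(flip, "orientation") <- attr(rc$x, "orientation")
  mflip <- m
  mflip$orientation[j] <- -1
  mflip$normalization$params <- NULL
  mref <- m
  mref$normalization$params <- NULL
  expect_equal(score_pi(mflip, flip)$scores$pi,
               score_pi(mref, rc$x)$scores$pi, tolerance = 1e-12)
})

test_that("candidate assembly counts and pooling sets are correct", {
  coh <- generate_cohort(cohort_spec(seed = 14))
  dtc <- compute_dtc_star(coh$features)
  cfg <- selection_config()
  tthp <- assemble_candidates(dtc, "TTHP", cfg)
  expect_equal(ncol(tthp), 8 * 3)
  total_avg <- assemble_candidates(
    dtc, c("FTAP", "TTHP", "GAIT"),
    selection_config(candidate_mode = "load_averaged"))
  expect_equal(ncol(total_avg), 32)
  tapping <- assemble_candidates(dtc, c("FTAP", "TTHP"), cfg)
  ftap <- assemble_candidates(dtc, "FTAP", cfg)
  expect_true(all(colnames(ftap) %in% colnames(tapping)))
  expect_error(assemble_candidates(dtc, "SWIM", cfg), "SWIM",
               class = "mcdt_validation_error")
  # orientation metadata propagates with the right sign convention
  ov <- attr(tthp, "orientation")
  orient <- coh$features$orientation
  hb <- orient$higher_better[orient$exercise == "TTHP" &
                               orient$feature == "f01"]
  expect_equal(unname(ov["TTHP_f01_CL1"]), if (hb) 1 else -1)
})

test_that("build_all_pis yields exactly the five named indices, each <= 6", {
  coh <- generate_cohort(cohort_spec(seed = 15))
  dtc <- compute_dtc_star(coh$features)
  labels <- setNames(as.character(coh$subjects$diagnosis),
                     coh$subjects$subject)
  pis <- suppressWarnings(build_all_pis(dtc, labels))
  expect_equal(names(pis$models),
               c("FTAP", "TTHP", "GAIT", "TAPPING", "TOTAL"))
  sizes <- vapply(pis$models, function(m) length(m$components), 0L)
  expect_true(all(sizes >= 1 & sizes <= 6))
  expect_equal(names(pis$scores),
               c("subject", "FTAP", "TTHP", "GAIT", "TAPPING", "TOTAL"))
  expect_true(all(vapply(pis$scores[-1],
                         function(v) all(v >= 0 & v <= 1), TRUE)))
})

test_that("selection is invariant to monotone transforms when only
           correlation counts drive deletions", {
  # a hub candidate correlated with two mutually independent satellites:
  # the hub holds the unique maximum exceedance count, so the whole
  # elimination path is criterion 2 and rank-based
  withr::with_seed(61, {
    u <- rnorm(200)
    v <- rnorm(200)
    x <- cbind(hub = u + v, sat1 = u, sat2 = v,
               d = rnorm(200), e = rnorm(200), f = rnorm(200))
  })
  attr(x, "orientation") <- setNames(rep(1, 6), colnames(x))
  labels <- rep(c("CNA", "SCI", "MCI"), length.out = 200)
  m <- select_components(x, labels)
  expect_true(all(
    m$audit_trail$criterion[m$audit_trail$action == "delete"] == 2))
  expect_false("hub" %in% m$components)
  y <- exp(x) # strictly monotone transform of every candidate
  attr(y, "orientation") <- attr(x, "orientation")
  m2 <- select_components(y, labels)
  expect_setequal(m2$components, m$components)
})
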