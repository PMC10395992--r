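test_that("LOOCV equals an explicit manual loop on a small set", {
  withr::with_seed(31, {
    X <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "PI"))
    y <- factor(rep(c("CNA", "MCI"), 4), levels = c("CNA", "SCI", "MCI"))
  })
  spec <- model_spec("TOTAL", "PI", "two_class")
  cv <- loocv(X, y, spec)
  manual <- character(8)
  for (i in 1:8) {
    fit <- fit_logistic(X[-i, , drop = FALSE], droplevels(y[-i]), spec)
    pr <- predict(fit, X[i, , drop = FALSE])
    manual[i] <- colnames(pr)[which.max(pr[1, ])]
  }
  expect_equal(as.character(cv$predictions$predicted), manual)
  expect_equal(sum(cv$confusion), 8)
})

test_that("fits are deterministic and consistent for duplicated rows", {
  withr::with_seed(5, {
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("PI", "AGE")))
    X[11:20, ] <- X[1:10, ] # exact duplicates
    y <- factor(rep(rep(c("CNA", "MCI"), 5), 2))
  })
  f1 <- fit_logistic(X, y)
  f2 <- fit_logistic(X, y)
  expect_identical(coef(f1$fit), coef(f2$fit))
  pr <- unname(predict(f1, X))
  expect_equal(pr[1:10, ], pr[11:20, ], tolerance = 1e-12)
})

test_that("permuted labels give near-zero coefficients and chance accuracy", {
  withr::with_seed(99, {
    X <- matrix(rnorm(400 * 2), 400, 2, dimnames = list(NULL, c("PI", "AGE")))
    y <- factor(sample(rep(c("CNA", "MCI"), c(150, 250))))
  })
  fit <- fit_logistic(X, y)
  slopes <- coef(fit$fit)[-1]
  expect_true(all(abs(slopes) < 0.4))
  cv <- loocv(X[1:60, ], y[1:60], model_spec("TOTAL"))
  acc <- 100 * sum(diag(cv$confusion)) / sum(cv$confusion)
  expect_gt(acc, 25)
  expect_lt(acc, 80)
})

test_that("linearly separable two-class data is classified almost perfectly", {
  withr::with_seed(7, {
    X <- matrix(c(rnorm(20, 0, 0.5), rnorm(20, 5, 0.5)), ncol = 1,
                dimnames = list(NULL, "PI"))
    y <- factor(rep(c("CNA", "MCI"), each = 20))
  })
  cv <- loocv(X, y, model_spec("TOTAL", "PI"))
  acc <- 100 * sum(diag(cv$confusion)) / sum(cv$confusion)
  expect_gte(acc, 95)
})

test_that("two-class metrics use MCI as the positive class", {
  perfect <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE,
                    dimnames = list(c("CNA", "MCI"), c("CNA", "MCI")))
  m <- compute_metrics(perfect, "two_class")
  expect_equal(c(m$sen, m$spe, m$acc), c(100, 100, 100))
  allpos <- matrix(c(0, 5, 0, 5), 2, byrow = TRUE,
                   dimnames = list(c("CNA", "MCI"), c("CNA", "MCI")))
  m2 <- compute_metrics(allpos, "two_class")
  expect_equal(c(m2$sen, m2$spe, m2$acc), c(100, 0, 50))
  skew <- matrix(c(8, 2, 3, 14), 2, byrow = TRUE,
                 dimnames = list(c("CNA", "MCI"), c("CNA", "MCI")))
  m3 <- compute_metrics(skew, "two_class")
  expect_equal(m3$sen, 100 * 14 / 17)
  expect_equal(m3$spe, 100 * 8 / 10)
  expect_error(compute_metrics(matrix(0, 2, 2), "two_class"),
               "Empty", class = "mcdt_validation_error")
})

test_that("three-class weighted metrics match hand-computed values", {
  cm <- matrix(c(3, 1, 0, 1, 2, 1, 0, 1, 3), 3, byrow = TRUE,
               dimnames = list(c("CNA", "SCI", "MCI"),
                               c("CNA", "SCI", "MCI")))
  m <- compute_metrics(cm, "three_class")
  expect_equal(unname(m$per_class$recall), c(75, 50, 75))
  expect_equal(unname(m$per_class$precision), c(75, 50, 75))
  expect_equal(m$recall_w, (75 + 50 + 75) / 3)
  expect_equal(m$acc, 100 * 8 / 12)
  expect_equal(m$f1_w, (75 + 50 + 75) / 3)
})

test_that("metrics agree with the loop oracle on random confusions", {
  withr::with_seed(13, {
    for (r in 1:100) {
      cm <- matrix(rpois(9, 5), 3, 3,
                   dimnames = list(c("CNA", "SCI", "MCI"),
                                   c("CNA", "SCI", "MCI")))
      if (any(rowSums(cm) == 0)) next
      m <- compute_metrics(cm, "three_class")
      o <- oracle_metrics3(cm)
      expect_equal(m$recall_w, o$recall_w, tolerance = 1e-12)
      expect_equal(m$precision_w, o$precision_w, tolerance = 1e-12)
      expect_equal(m$f1_w, o$f1_w, tolerance = 1e-12)
      expect_equal(m$acc, o$acc, tolerance = 1e-12)
    }
  })
})

test_that("a constant FAB column reproduces the two-regressor model", {
  coh <- generate_cohort(cohort_spec(seed = 44))
  dtc <- compute_dtc_star(coh$features)
  labels <- setNames(as.character(coh$subjects$diagnosis),
                     coh$subjects$subject)
  pis <- suppressWarnings(build_all_pis(dtc, labels))
  subjects <- coh$subjects
  subjects$fab <- 15L
  bat <- suppressMessages(run_model_battery(pis$scores, subjects))
  s <- bat$summary
  for (nm in c("TOTAL", "TTHP")) {
    two <- s[s$pi == nm & s$regressors == "PI+AGE" &
               s$problem == "two_class", ]
    three <- s[s$pi == nm & s$regressors == "PI+AGE+FAB" &
                 s$problem == "two_class", ]
    expect_equal(three$acc, two$acc, tolerance = 0.5)
  }
})

test_that("adding a pure-noise regressor does not inflate LOOCV accuracy", {
  diffs <- vapply(1:50, function(s) {
    withr::with_seed(3000 + s, {
      X <- matrix(c(rnorm(20, 0, 1), rnorm(20, 1.5, 1)), ncol = 1,
                  dimnames = list(NULL, "PI"))
      noise <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "AGE"))
      y <- factor(rep(c("CNA", "MCI"), each = 20))
    })
    a1 <- loocv(X, y, model_spec("TOTAL", "PI"))
    a2 <- loocv(cbind(X, noise), y, model_spec("TOTAL", c("PI", "AGE")))
    (sum(diag(a2$confusion)) - sum(diag(a1$confusion))) / 40 * 100
  }, 0)
  expect_lt(mean(diffs), 5)
})

test_that("folds that lose a class are flagged but still predicted", {
  withr::with_seed(2, {
    X <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "PI"))
    y <- factor(c("CNA", rep(c("SCI", "MCI"), c(5, 6))),
                levels = c("CNA", "SCI", "MCI"))
  })
  cv <- loocv(X, y, model_spec("TOTAL", "PI", "three_class"))
  expect_true(cv$predictions$flagged[1])
  expect_false(any(cv$predictions$flagged[-1]))
  expect_false(is.na(cv$predictions$predicted[1]))
  expect_equal(sum(cv$confusion), 12)
})

test_that("fold-safe evaluation never sees the held-out subject", {
  coh <- generate_cohort(
    cohort_spec(n_per_class = c(CNA = 8L, SCI = 0L, MCI = 8L), seed = 9))
  dtc <- compute_dtc_star(coh$features)
  spec <- model_spec("FTAP", c("PI", "AGE"), "two_class")
  cfg <- selection_config(max_components = 3)
  cv <- suppressMessages(loocv_fold_safe(dtc, coh$subjects, spec, cfg))
  expect_equal(sum(cv$confusion), 16)
  # perturbing the held-out subject's feature values must not change that
  # fold's training inputs: the selection and normalization fitted on the
  # remaining subjects are identical
  ft2 <- coh$features
  idx <- ft2$features$subject == coh$subjects$subject[1] &
    ft2$features$load > 0
  ft2$features$value[idx] <- ft2$features$value[idx] * 1.5
  dtc2 <- compute_dtc_star(ft2)
  c1 <- assemble_candidates(dtc, "FTAP", cfg)
  c2 <- assemble_candidates(dtc2, "FTAP", cfg)
  expect_equal(c1[-1, ], c2[-1, ]) # training rows untouched
  y <- coh$subjects$diagnosis
  tr1 <- mcdtpi:::candidate_rows(c1, -1)
  tr2 <- mcdtpi:::candidate_rows(c2, -1)
  m1 <- score_pi(select_components(tr1, y[-1], cfg), tr1)
  m2 <- score_pi(select_components(tr2, y[-1], cfg), tr2)
  expect_equal(m1$model$components, m2$model$components)
  expect_equal(m1$model$normalization$params, m2$model$normalization$params)
})
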