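# Logistic model battery. Ten regressor combinations (each of the five PIs
# with age, and with age + FAB) evaluated on two problems: two-class
# (CNA vs MCI) and three-class (CNA vs SCI vs MCI), under leave-one-out
# cross-validation pooled into a single confusion matrix. Fits are
# multinomial logits (a binomial logit in the two-class case) with a small
# L2 ridge for separability, via nnet::multinom.

#' Specification of one logistic model
#'
#' @param pi_name One of FTAP, TTHP, GAIT, TAPPING, TOTAL.
#' @param regressors Ordered subset of `c("PI", "AGE", "FAB")`; `"PI"` is
#'   always included.
#' @param problem `"two_class"` (CNA vs MCI) or `"three_class"`.
#' @param ridge Small L2 stabiliser (default 1e-6).
#' @param max_iter,tol Optimizer controls.
#' @return List of class `mcdt_model_spec`.
#' @export
model_spec <- function(pi_name, regressors = c("PI", "AGE"),
                       problem = c("two_class", "three_class"),
                       ridge = 1e-6, max_iter = 100000L, tol = 1e-10) {
  problem <- match.arg(problem)
  if (!pi_name %in% PI_NAMES) {
    abort(paste0("`pi_name` must be one of ",
                 paste(PI_NAMES, collapse = ", ")),
          class = "mcdt_validation_error")
  }
  if (!"PI" %in% regressors ||
      !all(regressors %in% c("PI", "AGE", "FAB"))) {
    abort("`regressors` must include PI and be a subset of {PI, AGE, FAB}.",
          class = "mcdt_validation_error")
  }
  structure(list(pi_name = pi_name, regressors = regressors,
                 problem = problem, ridge = ridge,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcdt_model_spec")
}

#' Fit a (multinomial) logistic model
#'
#' Regressors are standardized to the training mean/SD (stored for
#' prediction); the fit is a maximum-likelihood multinomial logit with a
#' small L2 ridge, deterministic given its inputs. With two classes this is
#' the ordinary binomial logit.
#'
#' @param X Numeric design matrix (no intercept column).
#' @param y Factor of class labels (>= 2 levels present).
#' @param spec A [model_spec()] (only `ridge`, `max_iter`, `tol` are used).
#' @return List of class `mcdt_logit_fit` with elements `fit`, `center`,
#'   `scale`, `levels`.
#' @export
fit_logistic <- function(X, y, spec = model_spec("TOTAL")) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) {
    abort("Cannot fit: fewer than 2 classes present in `y`.",
          class = "mcdt_validation_error")
  }
  if (anyNA(X) || anyNA(y)) {
    abort("Missing values in design matrix or labels.",
          class = "mcdt_validation_error")
  }
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center, scl)
  df <- data.frame(.y = y, Xs)
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                        decay = spec$ridge, maxit = spec$max_iter,
                        reltol = spec$tol)
  if (!isTRUE(fit$convergence == 0)) {
    abort(paste0("Logistic fit did not converge (code ", fit$convergence,
                 ", ", fit$maxit %||% spec$max_iter, " iterations)."),
          class = "mcdt_fit_error")
  }
  structure(list(fit = fit, center = center, scale = scl,
                 levels = levels(y), vars = colnames(X)),
            class = "mcdt_logit_fit")
}

#' Class probabilities from a fitted logistic model
#' @param object An `mcdt_logit_fit`.
#' @param newdata Design matrix with the training columns.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns = trained levels).
#' @export
predict.mcdt_logit_fit <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata)[, object$vars, drop = FALSE],
              object$center, object$scale)
  pr <- predict(object$fit, newdata = as.data.frame(Xs), type = "probs")
  if (is.null(dim(pr))) {
    if (length(object$levels) == 2) {
      pr <- cbind(1 - pr, pr)   # multinom returns P(second level)
    } else {
      pr <- matrix(pr, nrow = 1)
    }
  }
  colnames(pr) <- object$levels
  pr
}

# Argmax with deterministic tie-break: first level in canonical order wins.
argmax_class <- function(prob_row, levels_all) {
  present <- intersect(levels_all, names(prob_row))
  pv <- prob_row[present]
  win <- present[pv == max(pv)]
  if (length(win) > 1) {
    inform(paste0("Tied class probabilities; keeping canonical-order first: ",
                  win[1]))
  }
  win[1]
}

#' Leave-one-out cross-validation of a logistic model
#'
#' Fits n models, each excluding one subject, predicts the held-out subject
#' as the class with maximal probability (ties broken toward the canonical
#' CNA < SCI < MCI order), and pools predictions into one confusion matrix.
#' A training fold that loses an entire class is still fitted on the
#' remaining classes and the fold is flagged.
#'
#' @param X Design matrix. @param y Label factor.
#' @param spec A [model_spec()].
#' @return List of class `mcdt_loocv`: `predictions` tibble
#'   (`index, truth, predicted, flagged`), `confusion` (rows = truth,
#'   columns = predicted, over the levels of `y`).
#' @export
loocv <- function(X, y, spec = model_spec("TOTAL")) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  n <- nrow(X)
  if (n < ncol(X) + 2) {
    abort("Too few subjects for LOOCV with this many regressors.",
          class = "mcdt_validation_error")
  }
  preds <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    flagged[i] <- nlevels(yi) < nlevels(y)
    fit <- fit_logistic(X[-i, , drop = FALSE], yi, spec)
    pr <- predict(fit, X[i, , drop = FALSE])
    preds[i] <- argmax_class(pr[1, ], levels(y))
  }
  predicted <- factor(preds, levels = levels(y))
  confusion <- table(truth = y, predicted = predicted)
  structure(list(
    predictions = tibble(index = seq_len(n), truth = y,
                         predicted = predicted, flagged = flagged),
    confusion = confusion),
    class = "mcdt_loocv")
}

#' Classification metrics from a pooled confusion matrix
#'
#' Two-class problem (rows/columns CNA, MCI): MCI is the positive class, so
#' sensitivity is the MCI recall and specificity the CNA recall.
#' Three-class problem: per-class one-vs-rest recall, precision and F1 plus
#' their support-weighted averages and overall accuracy. All values are
#' percentages (0-100), unrounded; round only when reporting.
#'
#' @param confusion Square table/matrix, rows = truth, columns = predicted,
#'   in canonical class order.
#' @param problem `"two_class"` or `"three_class"`.
#' @return For two_class: list(sen, spe, acc). For three_class:
#'   list(per_class = tibble(class, recall, precision, f1, support),
#'   recall_w, precision_w, f1_w, acc).
#' @export
compute_metrics <- function(confusion, problem = c("two_class",
                                                   "three_class")) {
  problem <- match.arg(problem)
  cm <- as.matrix(confusion)
  if (length(cm) == 0 || sum(cm) == 0) {
    abort("Empty confusion matrix.", class = "mcdt_validation_error")
  }
  if (nrow(cm) != ncol(cm)) {
    abort("Confusion matrix must be square (all classes on both axes).",
          class = "mcdt_validation_error")
  }
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  if (problem == "two_class") {
    if (nrow(cm) != 2) {
      abort("two_class metrics need a 2x2 confusion (CNA, MCI).",
            class = "mcdt_validation_error")
    }
    sen <- 100 * cm[2, 2] / sum(cm[2, ])   # MCI recall
    spe <- 100 * cm[1, 1] / sum(cm[1, ])   # CNA recall
    list(sen = sen, spe = spe, acc = acc)
  } else {
    support <- unname(rowSums(cm))
    recall <- unname(100 * diag(cm) / support)
    predn <- unname(colSums(cm))
    precision <- ifelse(predn == 0, 0, unname(100 * diag(cm)) / predn)
    f1 <- ifelse(recall + precision == 0, 0,
                 2 * recall * precision / (recall + precision))
    w <- support / total
    list(per_class = tibble(class = rownames(cm), recall = recall,
                            precision = precision, f1 = f1,
                            support = as.integer(support)),
         recall_w = sum(w * recall), precision_w = sum(w * precision),
         f1_w = sum(w * f1), acc = acc)
  }
}

battery_design <- function(pi_scores, subjects, spec) {
  df <- dplyr::inner_join(pi_scores, subjects, by = "subject")
  keep <- !is.na(df[[spec$pi_name]])
  dropped <- sum(!keep)
  if (dropped) {
    inform(paste0("Model PI_(", spec$pi_name, "): dropped ", dropped,
                  " subject(s) with missing PI."))
  }
  df <- df[keep, ]
  if (spec$problem == "two_class") {
    df <- df[df$diagnosis %in% c("CNA", "MCI"), ]
  }
  cols <- c(PI = spec$pi_name, AGE = "age", FAB = "fab")[spec$regressors]
  X <- as.matrix(df[unname(cols)])
  colnames(X) <- spec$regressors
  list(X = X, y = droplevels(factor(df$diagnosis,
                                    levels = DIAGNOSES)),
       subjects = df$subject)
}

#' Run the full ten-model battery on both problems
#'
#' Evaluates, under LOOCV, the ten regressor combinations (each PI with
#' age; each PI with age and FAB) for the two-class (CNA vs MCI) and
#' three-class problems: 20 model evaluations in total, reported in the
#' standard layout (Sen/Spe/Acc for two-class; weighted Rec/Prec/F1 and
#' Acc for three-class) plus the per-class three-class metrics.
#'
#' @param pi_scores Tibble from [build_all_pis()] (`subject` + five PI
#'   columns).
#' @param subjects Validated subject records.
#' @param ridge,max_iter,tol Passed to each [model_spec()].
#' @return Object of class `mcdt_metrics_report`: `summary` tibble (one row
#'   per model x problem), `per_class` tibble (three-class models), and
#'   `confusions` (named list of confusion tables).
#' @export
run_model_battery <- function(pi_scores, subjects, ridge = 1e-6,
                              max_iter = 100000L, tol = 1e-10) {
  combos <- list(c("PI", "AGE"), c("PI", "AGE", "FAB"))
  rows <- list()
  per_class <- list()
  confusions <- list()
  for (regs in combos) {
    for (nm in PI_NAMES) {
      for (prob in c("two_class", "three_class")) {
        spec <- model_spec(nm, regs, prob, ridge = ridge,
                           max_iter = max_iter, tol = tol)
        des <- battery_design(pi_scores, subjects, spec)
        cv <- loocv(des$X, des$y, spec)
        met <- compute_metrics(cv$confusion, prob)
        key <- paste0("PI_", nm, "+", paste(setdiff(regs, "PI"),
                                            collapse = "+"), ":", prob)
        confusions[[key]] <- cv$confusion
        if (prob == "two_class") {
          rows[[key]] <- tibble(
            model = paste0("PI_(", nm, "), ",
                           paste(setdiff(regs, "PI"), collapse = ", ")),
            pi = nm, regressors = paste(regs, collapse = "+"),
            problem = prob, n = sum(cv$confusion),
            sen = met$sen, spe = met$spe, acc = met$acc,
            rec_w = NA_real_, prec_w = NA_real_, f1_w = NA_real_)
        } else {
          rows[[key]] <- tibble(
            model = paste0("PI_(", nm, "), ",
                           paste(setdiff(regs, "PI"), collapse = ", ")),
            pi = nm, regressors = paste(regs, collapse = "+"),
            problem = prob, n = sum(cv$confusion),
            sen = NA_real_, spe = NA_real_, acc = met$acc,
            rec_w = met$recall_w, prec_w = met$precision_w,
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

#' @export
print.mcdt_metrics_report <- function(x, ...) {
  cat("<mcdt_metrics_report>\n")
  s <- x$summary
  s[c("sen", "spe", "acc", "rec_w", "prec_w", "f1_w")] <-
    lapply(s[c("sen", "spe", "acc", "rec_w", "prec_w", "f1_w")],
           function(v) round(v))
  print(as.data.frame(s[c("model", "problem", "sen", "spe", "rec_w",
                          "prec_w", "f1_w", "acc")]), row.names = FALSE)
  invisible(x)
}

#' Fold-safe LOOCV: PI selection and normalization refit per fold
#'
#' The default evaluation builds each PI once on the full sample (matching
#' the single-pass construction of the original analysis) before LOOCV,
#' which leaks the held-out subject into component selection and
#' normalization. This variant removes that leakage: for every fold, the
#' component selection, the orientation/normalization parameters and the
#' model fit use only the training subjects; the held-out subject is scored
#' with the training fold's parameters.
#'
#' @param dtc An `mcdt_dtc_table`.
#' @param subjects Validated subject records.
#' @param spec A [model_spec()].
#' @param config A [selection_config()].
#' @return An `mcdt_loocv` object (see [loocv()]).
#' @export
loocv_fold_safe <- function(dtc, subjects, spec, config = selection_config()) {
  cand <- assemble_candidates(dtc, pi_exercises(spec$pi_name), config)
  subjects <- subjects[match(rownames(cand), subjects$subject), ]
  stopifnot(identical(subjects$subject, rownames(cand)))
  if (spec$problem == "two_class") {
    keep <- subjects$diagnosis %in% c("CNA", "MCI")
    cand <- candidate_rows(cand, keep)
    subjects <- subjects[keep, ]
  }
  y <- droplevels(factor(subjects$diagnosis, levels = DIAGNOSES))
  n <- nrow(cand)
  preds <- character(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    tr <- candidate_rows(cand, -i)
    model <- suppressWarnings(
      select_components(tr, y[-i], config, name = spec$pi_name))
    sc_tr <- score_pi(model, tr)
    sc_te <- score_pi(sc_tr$model, cand[i, , drop = FALSE])
    covs <- cbind(PI = c(sc_tr$scores$pi, sc_te$scores$pi),
                  AGE = c(subjects$age[-i], subjects$age[i]),
                  FAB = c(subjects$fab[-i], subjects$fab[i]))
    covs <- covs[, spec$regressors, drop = FALSE]
    yi <- droplevels(y[-i])
    flagged[i] <- nlevels(yi) < nlevels(y)
    fit <- fit_logistic(covs[seq_len(n - 1), , drop = FALSE], yi, spec)
    pr <- predict(fit, covs[n, , drop = FALSE])
    preds[i] <- argmax_class(pr[1, ], levels(y))
  }
  predicted <- factor(preds, levels = levels(y))
  structure(list(
    predictions = tibble(index = seq_len(n), truth = y,
                         predicted = predicted, flagged = flagged),
    confusion = table(truth = y, predicted = predicted)),
    class = "mcdt_loocv")
}
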