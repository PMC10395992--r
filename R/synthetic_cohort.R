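# Synthetic MCDT cohort generator. Emulates the statistical structure the
# downstream analysis assumes: class-graded degradation of motor features
# under increasing cognitive load, load- and impairment-dependent
# correct-response counts, and demographics/clinical scores whose per-class
# medians and IQRs match the study population (CNA younger, FAB ordered
# CNA > SCI > MCI).

#' Specification of a synthetic MCDT cohort
#'
#' All defaults are the study conditions: group sizes 10/17/17
#' (CNA/SCI/MCI), ages and FAB scores located at the published group medians
#' with scale IQR/1.349, 5% feature degradation per load step, 6% relative
#' trial noise, and a correct-response model that loses 4 responses per load
#' step plus an impairment-graded deficit.
#'
#' @param n_per_class Named integer vector `c(CNA=, SCI=, MCI=)`.
#' @param effect_size Nonnegative scalar: standardized mean shift (in units
#'   of the trial noise SD, at the hardest load) of dual-task degradation
#'   between adjacent severity classes. 0 makes class labels exchangeable in
#'   every motor feature and count.
#' @param load_slope Fractional feature degradation per unit cognitive load
#'   common to all classes (default 0.05).
#' @param age_params,fab_params Named lists of `c(location, scale)` per
#'   class. FAB values are rounded to integers and clamped to [0, 18].
#' @param count_params List with `base` (mean correct responses of a CNA
#'   subject at load 1), `load_drop` (mean decrease per extra load step),
#'   `class_gap` (mean decrease per severity grade per unit effect size) and
#'   `sd`. Counts are rounded Gaussians truncated at zero.
#' @param noise_sd Relative (fractional) SD of trial-level feature noise.
#' @param between_sd Relative SD of the stable between-subject level.
#' @param seed Integer RNG seed.
#' @return An object of class `mcdt_cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(CNA = 10L, SCI = 17L, MCI = 17L),
                        effect_size = 1.5,
                        load_slope = 0.05,
                        age_params = list(CNA = c(63, 6.7),
                                          SCI = c(72, 10.0),
                                          MCI = c(73, 9.5)),
                        fab_params = list(CNA = c(18, 0.74),
                                          SCI = c(17, 0.93),
                                          MCI = c(15, 0.93)),
                        count_params = list(base = 20, load_drop = 4,
                                            class_gap = 1.5, sd = 3),
                        noise_sd = 0.06,
                        between_sd = 0.10,
                        seed = 1L) {
  spec <- structure(
    list(n_per_class = n_per_class, effect_size = effect_size,
         load_slope = load_slope, age_params = age_params,
         fab_params = fab_params, count_params = count_params,
         noise_sd = noise_sd, between_sd = between_sd,
         seed = as.integer(seed)),
    class = "mcdt_cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg) {
    abort(paste0("Invalid cohort spec field `", field, "`: ", msg),
          class = "mcdt_validation_error")
  }
  n <- spec$n_per_class
  if (!all(DIAGNOSES %in% names(n))) {
    fail("n_per_class", "must name counts for CNA, SCI and MCI")
  }
  if (any(n < 0) || any(n != round(n))) {
    fail("n_per_class", "counts must be nonnegative integers")
  }
  if (!is.numeric(spec$effect_size) || spec$effect_size < 0) {
    fail("effect_size", "must be a nonnegative scalar")
  }
  if (!is.numeric(spec$noise_sd) || spec$noise_sd <= 0) {
    fail("noise_sd", "must be strictly positive")
  }
  if (spec$between_sd < 0) fail("between_sd", "must be nonnegative")
  cp <- spec$count_params
  for (f in c("base", "load_drop", "class_gap", "sd")) {
    if (is.null(cp[[f]]) || !is.numeric(cp[[f]])) {
      fail("count_params", paste0("missing numeric element `", f, "`"))
    }
  }
  if (cp$sd <= 0) fail("count_params", "`sd` must be strictly positive")
  for (p in c("age_params", "fab_params")) {
    pars <- spec[[p]]
    if (!all(DIAGNOSES %in% names(pars))) {
      fail(p, "must provide c(location, scale) per class")
    }
    if (any(vapply(pars, function(x) length(x) != 2 || x[2] < 0, TRUE))) {
      fail(p, "each entry must be c(location, scale >= 0)")
    }
  }
  spec
}

# Fixed per-identity latent scale and orientation. Deterministic metadata,
# not seeded: half the features are oriented "higher is worse" (e.g. timing
# variability) to exercise the orientation stage downstream.
feature_metadata <- function() {
  ids <- feature_identities()
  ids$mu <- 20 + 3 * seq_len(nrow(ids))
  ids$higher_better <- seq_len(nrow(ids)) %% 2L == 1L
  ids
}

#' Generate a synthetic MCDT cohort
#'
#' Draws a complete cohort: per-subject demographics (age, FAB, sex,
#' education), a full 32-feature x 4-load motor block, and correct-response
#' counts for the three dual-task loads. Baseline features are
#' class-independent; for load k >= 1 each feature is degraded by
#' `load_slope * k` plus a class-severity shift of
#' `effect_size * noise_sd * severity * k / 3` (severity 0/1/2 for
#' CNA/SCI/MCI), in the direction of its orientation, plus trial noise.
#' Counts decrease in load and (when `effect_size > 0`) in severity.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `mcdt_cohort`: list with `subjects` (validated
#'   subject records), `features` (an [feature_table()]) and `truth` (the
#'   generating spec plus per-subject latent severity).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 7))
#' length(coh$features$subjects) # 44
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_per_class[DIAGNOSES]
  diagnosis <- rep(DIAGNOSES, times = n)
  nsub <- length(diagnosis)
  severity <- setNames(0:2, DIAGNOSES)[diagnosis]
  subject <- sprintf("S%02d", seq_len(nsub))

  draw2 <- function(pars) rnorm(1, pars[1], pars[2])
  age <- unname(vapply(diagnosis, function(d) draw2(spec$age_params[[d]]), 0))
  age <- round(pmax(age, 40))
  fab <- unname(vapply(diagnosis, function(d) draw2(spec$fab_params[[d]]), 0))
  fab <- pmin(pmax(round(fab), 0), 18)
  # Female proportions and education mix loosely matched to the study table
  p_female <- c(CNA = 0.60, SCI = 0.41, MCI = 0.76)[diagnosis]
  sex <- ifelse(runif(nsub) < p_female, "F", "M")
  edu_probs <- list(CNA = c(0.00, 0.20, 0.80), SCI = c(0.06, 0.23, 0.71),
                    MCI = c(0.18, 0.35, 0.47))
  education <- unname(vapply(diagnosis, function(d) {
    sample(c("primary", "secondary", "superior"), 1, prob = edu_probs[[d]])
  }, ""))

  subjects <- subject_records(tibble(
    subject = subject, age = age, fab = fab, diagnosis = diagnosis,
    sex = sex, education = education))

  meta <- feature_metadata()
  nfeat <- nrow(meta)

  # subject x feature stable level, then one trial draw per load
  level <- outer(rep(1, nsub), meta$mu) *
    (1 + matrix(rnorm(nsub * nfeat, 0, spec$between_sd), nsub, nfeat))
  dir <- ifelse(meta$higher_better, 1, -1)

  blocks <- lapply(LOADS, function(k) {
    delta <- spec$load_slope * k +
      spec$effect_size * spec$noise_sd * severity * k / 3
    eps <- matrix(rnorm(nsub * nfeat, 0, spec$noise_sd), nsub, nfeat)
    vals <- level * (1 - outer(delta, dir)) * (1 + eps)
    tibble(
      subject = rep(subject, nfeat),
      exercise = rep(meta$exercise, each = nsub),
      load = k,
      feature = rep(meta$feature, each = nsub),
      value = as.vector(vals))
  })
  features <- dplyr::bind_rows(blocks)

  cp <- spec$count_params
  counts <- dplyr::bind_rows(lapply(DT_LOADS, function(k) {
    dplyr::bind_rows(lapply(EXERCISES, function(ex) {
      mu <- cp$base - cp$load_drop * (k - 1) -
        cp$class_gap * spec$effect_size * severity
      nc <- pmax(round(rnorm(nsub, mu, cp$sd)), 0)
      tibble(subject = subject, exercise = ex, load = k, nc = as.integer(nc))
    }))
  }))

  ft <- feature_table(features, counts,
                      orientation = meta[c("exercise", "feature",
                                           "higher_better")])
  structure(
    list(subjects = subjects, features = ft,
         truth = list(spec = spec, severity = setNames(severity, subject))),
    class = "mcdt_cohort")
}

#' @export
print.mcdt_cohort <- function(x, ...) {
  tab <- table(x$subjects$diagnosis)
  cat(sprintf("<mcdt_cohort> %d subjects (%s)\n", nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Split a cohort into its plain tables
#'
#' Emits exactly the two artifacts the readers/writers consume: the
#' feature table and the subject records.
#'
#' @param cohort An `mcdt_cohort`.
#' @return List with elements `features` (`mcdt_feature_table`) and
#'   `subjects` (tibble of subject records).
#' @export
cohort_to_tables <- function(cohort) {
  stopifnot(inherits(cohort, "mcdt_cohort"))
  list(features = cohort$features, subjects = cohort$subjects)
}
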