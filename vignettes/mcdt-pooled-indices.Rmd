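---
title: "Motor-cognitive dual-task pooled indices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-cognitive dual-task pooled indices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdtpi)
```

## The problem

Motor-cognitive dual-task (MCDT) protocols have a subject perform an
instrumented motor exercise — forefinger tapping (FTAP, 15 s), toe tapping
with the heel pinned (TTHP, 15 s), or a 10 m straight walk (GAIT) — while
simultaneously counting backwards by ones, threes or sevens (cognitive
loads CL1–CL3; CL0 is the single-task baseline). Because the motor and the
cognitive task compete for shared resources, the degradation of motor
performance under load is a sensitive probe of the motor-cognitive
interface, and is informative about early cognitive decline: cognitively
normal adults (CNA), adults with subjective cognitive impairment (SCI) and
adults with mild cognitive impairment (MCI) degrade differently.

`mcdtpi` implements the full analysis chain from a per-subject motor
feature table (32 feature identities — 8 per tapping task, 16 for gait —
at 4 load levels, i.e. 128 feature columns) to cross-validated diagnostic
classification, together with a synthetic cohort generator that makes the
whole chain testable without access to clinical records.

## The commitment-weighted dual-task cost

The classical dual-task cost of feature $f_i(Ex, CL_k, s_j)$ is the
percent change against the single-task baseline:

$$\mathrm{DTC}_i(Ex, CL_k, s_j) =
  \frac{f_i(Ex, CL_k, s_j) - f_i(Ex, CL_0, s_j)}{f_i(Ex, CL_0, s_j)}
  \times 100 .$$

This ignores the cognitive half of the protocol: a subject who simply
stops counting preserves motor output, shows a near-zero DTC, and passes
as normal. The package therefore also computes a weighted cost: the number
of correct counting responses $N_c(Ex, CL_k, s_j)$ — a joint proxy for
cognitive efficiency and task commitment — is rescaled across the cohort
at each (exercise, load) with a bounded min-max map

$$Z_c = (b - a)\,\frac{N_c - \min N_c}{\max N_c - \min N_c} + a,
  \qquad a = 0.01,\; b = 1,$$

the dual-task feature value is multiplied by this weight,
$f^\* = f \cdot Z_c$ (defined only for $k \ge 1$; no counting happens at
baseline), and the weighted cost $\mathrm{DTC}^\*$ is the percent change
of $f^\*$ against the *unweighted* baseline. The non-counting subject now
collapses to $\mathrm{DTC}^\* \approx -99\%$ instead of $0\%$ and is
flagged rather than masked.

Numerical choices worth stating explicitly:

* The lower bound $a = 0.01$ keeps weights strictly positive; the
  best-counting subject ($Z_c = 1$) keeps its feature value unchanged, so
  $\mathrm{DTC}^\* = \mathrm{DTC}$ at full commitment.
* When every subject has the same count, the min-max map is 0/0. All
  weights are then set to $b = 1$: uniform counting carries no
  between-subject information and the weighted cost falls back to the
  classical one.
* A baseline value of exactly 0 makes percent change undefined. Such
  cells are flagged and excluded downstream, never turned into
  infinities. Features that can legitimately cross zero should be shifted
  or excluded upstream.
* Despite the historical "Z-scored" name for $Z_c$, the map is a bounded
  rescaling, not a standard score, and the implementation follows the
  bounded form.

## Pooled indices

Each of five pooled indices — PI(FTAP), PI(TTHP), PI(GAIT), PI(TAPPING)
(tapping tasks combined) and PI(TOTAL) (all three exercises) — summarises
a family of $\mathrm{DTC}^\*$ candidate variables as the equal-weight mean
of up to six normalised components. Components are chosen by iterative
Spearman screening, so that the retained variables are mutually weakly
correlated (target: all pairwise $|\rho| < 0.4$):

1. While more than six candidates remain or any pair reaches the
   threshold, one candidate is deleted per pass.
2. The candidate with the single highest count of $|\rho| \ge 0.4$
   exceedances is deleted.
3. On a tie, the tied candidate with the weakest class separation is
   deleted, measured as the largest absolute Cohen's $d$ (pooled-SD form)
   over the three class pairs CNA–SCI, CNA–MCI, SCI–MCI.
4. On a further tie the original procedure appealed to clinical
   judgement, which is not reproducible from a published description. The
   package substitutes a user-supplied priority list
   (`selection_config(tie_break_manual = ...)`); if the list does not
   resolve the tie, the lexicographically smallest identity is deleted
   with a loud warning, so runs are deterministic and auditable. Every
   deletion (candidate, criterion, rationale) is recorded in the model's
   audit trail.

Scoring orients every component so that higher values mean better
functioning (the orientation of each raw feature is study metadata, not
derivable from the data; the synthetic generator produces it, and
file-based runs must supply it), min-max normalises each component to
$[0,1]$ on the construction sample, and averages. PI scores therefore lie
in $[0, 1]$. A z-score normalisation is available as an option.

Two design points were genuinely open:

* **Candidate granularity.** Whether the original indices pooled
  per-(feature, load) costs or load-averaged costs is not stated in the
  published description. The default (`candidate_mode = "per_load"`)
  keeps each (feature, load) pair as a separate candidate, preserving
  load-specific signal; `"load_averaged"` averages the three loads per
  feature. Both are first-class modes.
* **Selection-time information.** The indices are built once on the full
  sample by default, reproducing the original single-pass construction.
  This leaks the held-out subject into selection and normalisation during
  cross-validation, so a fold-safe mode (`fold_safe = TRUE` in the
  pipeline, or `loocv_fold_safe()`) refits selection and normalisation
  inside every training fold. The default reproduces; the option is the
  honest-evaluation variant. (Count rescaling happens upstream at the
  cohort level in both modes.)

## Classification battery

Ten logistic models — each PI with age, and each PI with age plus the
Frontal Assessment Battery (FAB) score — are evaluated on two problems:
two-class (CNA vs MCI) and three-class (CNA vs SCI vs MCI). Fits are
maximum-likelihood multinomial logits (the two-class case reduces to the
ordinary binomial logit) with a small L2 ridge (default $10^{-6}$) so that
perfectly separable training folds still have a finite optimum; regressors
are standardised to training-fold mean/SD for conditioning. Whether the
original three-class model was multinomial or ordinal is unstated; the
multinomial reading of "multivariate logistic regression" is used.

Validation is leave-one-out: each subject is predicted by a model fitted
on all the others, and the $n$ out-of-fold predictions are pooled into one
confusion matrix. Ties in the predicted class probability break toward the
canonical order CNA < SCI < MCI (logged); a training fold that loses an
entire class — reachable with only 10 CNA subjects in small simulations —
is fitted on the remaining classes and flagged. Two-class metrics treat
MCI as the positive class (sensitivity = MCI recall, specificity = CNA
recall); three-class metrics are per-class one-vs-rest recall, precision
and F1 plus their support-weighted averages and overall accuracy. All
metrics are kept as unrounded percentages and rounded only for display.

## Group statistics

Descriptive comparisons mirror a standard clinical characteristics table:
per-group median and IQR (linear-interpolation, type-7 quantiles — the
original quantile convention is unstated, so the most common default is
used and documented), Kruskal-Wallis omnibus tests with tie correction,
pairwise two-sided Mann-Whitney post hocs with Bonferroni correction
($p_{adj} = \min(1, 3p)$; exact enumeration for small untied samples,
tie-corrected normal approximation otherwise, since group sizes 10–17
straddle small-sample territory), and Pearson chi-squared tests (no
continuity correction) for categorical variables.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the study's design conditions, which are its fixed defaults:

* **Group sizes** 10 CNA / 17 SCI / 17 MCI (44 subjects).
* **Ages** drawn per class from normals located at the published group
  medians (63 / 72 / 73 years) with scale IQR/1.349 (IQRs 9 / 13.5 /
  12.75), so CNA subjects are younger; **FAB** likewise (medians 18 / 17 /
  15, IQRs 1 / 1.25 / 1.25), rounded and clamped to the 0–18 range.
* **Motor features**: each of the 32 identities has a fixed latent scale;
  subjects get a stable level (10% between-subject SD) and each trial adds
  6% relative noise (`noise_sd = 0.06`). Under load $k$ the feature
  degrades by a common fraction `load_slope * k` (default 5% per load
  step) plus a class-graded shift `effect_size * noise_sd * severity *
  k/3` (severity 0/1/2 for CNA/SCI/MCI), applied in the direction of the
  feature's orientation. `effect_size` is therefore a standardised
  adjacent-class mean shift, in trial-noise SD units at the hardest load.
  The default `effect_size = 1.5` produces moderate separation, placing
  the two-class battery in the upper range reported for wearable
  dual-task discrimination; recovery checks use 2 (strong) and 0 (null).
* **Counts**: the published description gives no distribution for
  $N_c$, so a deliberately simple model is used — a rounded Gaussian
  truncated at zero with mean `base − load_drop·(k−1) −
  class_gap·effect_size·severity` (defaults 20, 4, 1.5, SD 3). Counts
  fall with load, and with impairment only when `effect_size > 0`, so the
  null cohort stays exchangeable.
* **Orientation metadata** alternates higher-is-better /
  higher-is-worse across feature indices, deterministically, so the
  orientation stage is always exercised.

What the generator does *not* emulate: raw inertial signals, within-
session learning, feature-specific distributional shapes, realistic
cross-feature correlation structure beyond the shared subject level and
the shared count weight, or missingness. Passing recovery tests therefore
show that the pipeline recovers planted class structure of the assumed
form — not that the original study's effect sizes are correct.

A fully exchangeable null requires class-independent age and FAB
parameters as well as `effect_size = 0`: with the default (study-matched)
demographics, age and FAB remain informative even when the motor signal
carries nothing. The null checks use such a spec.

## Problem sizes and determinism

All randomness flows through a single integer seed (`withr::with_seed`,
so the global RNG state is untouched). The test suite and the acceptance
script use the study-sized cohort (44 subjects, 128 feature columns,
$\le 96$ candidates per index); seed-averaged checks use 20 independent
cohorts for the recovery and null conditions, 10 for directional
comparisons, and 2000 draws for the nominal-rate check of the omnibus
test. A full pipeline run takes a few seconds; the complete acceptance
script runs in about a minute.

## Known limitations

* The published per-model results were computed from the study's own
  deposited records; those are not shipped, so numeric reproduction of
  that table is out of reach here. The acceptance surface is the
  property-based suite plus the synthetic-recovery quantities.
* Criterion 4 (clinical judgement) is inherently irreproducible; the
  deterministic stand-in is documented above.
* The default evaluation inherits the original construction's leakage of
  the full sample into PI selection/normalisation; use the fold-safe mode
  for unbiased error estimates.
* With 10 CNA subjects, LOOCV metrics are quantised in steps of ~4
  percentage points; small differences between models are not
  meaningful at this cohort size.
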