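# Independent oracles: deliberately naive re-implementations used only to
# check the package's results. They share no code with the implementation.

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x) {
  r <- apply(x, 2, rank, ties.method = "average")
  p <- ncol(x)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ri <- r[, i] - mean(r[, i])
      rj <- r[, j] - mean(r[, j])
      out[i, j] <- sum(ri * rj) / sqrt(sum(ri^2) * sum(rj^2))
    }
  }
  diag(out) <- 1
  out
}

# Exceedance counts by exhaustive pair loop.
oracle_exceed <- function(rho, thr) {
  p <- nrow(rho)
  counts <- integer(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j && (is.na(rho[i, j]) || abs(rho[i, j]) >= thr)) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  names(counts) <- rownames(rho)
  counts
}

# Textbook pooled-SD Cohen's d.
oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Brute-force re-implementation of the component-selection flowchart:
# loop until <= max_comp candidates remain and no pair reaches the
# threshold; each pass deletes the candidate with the most threshold
# exceedances, ties broken by the smallest max-pairwise-|d|, then
# lexicographically.
oracle_select <- function(x, labels, thr = 0.4, max_comp = 6) {
  labels <- as.character(labels)
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    rho <- oracle_spearman(x[, keep, drop = FALSE])
    counts <- oracle_exceed(rho, thr)
    if (length(keep) <= max_comp && max(counts) == 0) break
    tied <- names(counts)[counts == max(counts)]
    if (length(tied) > 1) {
      es <- sapply(tied, function(cd) {
        classes <- unique(labels)
        dmax <- 0
        for (i in seq_along(classes)) {
          for (j in seq_along(classes)) {
            if (i < j) {
              d <- abs(oracle_cohens_d(x[labels == classes[i], cd],
                                       x[labels == classes[j], cd]))
              dmax <- max(dmax, d)
            }
          }
        }
        dmax
      })
      tied <- tied[es == min(es)]
      if (length(tied) > 1) tied <- sort(tied)[1]
    }
    keep <- setdiff(keep, tied[1])
  }
  sort(keep)
}

# Per-class and weighted classification metrics by explicit loops,
# as percentages.
oracle_metrics3 <- function(cm) {
  k <- nrow(cm)
  n <- sum(cm)
  rec <- prec <- f1 <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    rec[i] <- 100 * tp / sum(cm[i, ])
    pd <- sum(cm[, i])
    prec[i] <- if (pd == 0) 0 else 100 * tp / pd
    f1[i] <- if (rec[i] + prec[i] == 0) 0 else
      2 * rec[i] * prec[i] / (rec[i] + prec[i])
  }
  w <- rowSums(cm) / n
  list(recall = rec, precision = prec, f1 = f1,
       recall_w = sum(w * rec), precision_w = sum(w * prec),
       f1_w = sum(w * f1), acc = 100 * sum(diag(cm)) / n)
}

# Tie-corrected Kruskal-Wallis H from the textbook formula.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  offs <- cumsum(c(0, head(lengths(groups), -1)))
  h <- 12 / (n * (n + 1)) *
    sum(mapply(function(o, m) sum(r[(o + 1):(o + m)])^2 / m,
               offs, lengths(groups))) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_idx <- combn(n1 + n2, n1)
  us <- apply(all_idx, 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Pearson chi-squared from hand-computed expected counts.
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Median and IQR from an explicit sort (type-7 quantiles).
oracle_median_iqr <- function(x) {
  s <- sort(x)
  n <- length(s)
  q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(median = q(0.5), iqr = q(0.75) - q(0.25))
}
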