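# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive, direct transcriptions of the defining
# formulas, not as calls into the code paths they check.

# Exact HWE p-value by direct enumeration of the conditional distribution
# of heterozygote counts given the allele counts.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  hets <- seq(n_A %% 2, min(n_A, 2 * n - n_A), by = 2)
  pr <- sapply(hets, function(h) {
    hom_A <- (n_A - h) / 2
    hom_a <- n - h - hom_A
    exp(lfactorial(n) - lfactorial(hom_A) - lfactorial(h) -
          lfactorial(hom_a) + h * log(2) +
          lfactorial(n_A) + lfactorial(2 * n - n_A) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Full conditional heterozygote-count distribution for given (n, n_A),
# used to sweep every genotype triple at once.
oracle_hwe_dist <- function(n, n_A) {
  hets <- seq(n_A %% 2, min(n_A, 2 * n - n_A), by = 2)
  pr <- sapply(hets, function(h) {
    hom_A <- (n_A - h) / 2
    hom_a <- n - h - hom_A
    exp(lfactorial(n) - lfactorial(hom_A) - lfactorial(h) -
          lfactorial(hom_a) + h * log(2) +
          lfactorial(n_A) + lfactorial(2 * n - n_A) - lfactorial(2 * n))
  })
  list(hets = hets, pr = pr / sum(pr))
}

# Textbook Benjamini-Hochberg step-up adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(sapply(i:m, function(j) m * p[o[j]] / j))
  }
  pmin(1, q_sorted)[order(o)]
}

# Exhaustive cutoff search: every midpoint between distinct sorted scores,
# statistics recomputed from scratch.
oracle_cutoff <- function(scores, delta_bfm, min_class_size,
                          criterion = "mean_diff") {
  uq <- sort(unique(scores))
  cands <- (uq[-1] + uq[-length(uq)]) / 2
  best <- NULL
  best_stat <- -Inf
  for (cut in cands) {
    hi <- scores > cut
    if (sum(hi) < min_class_size || sum(!hi) < min_class_size) next
    s <- if (criterion == "mean_diff") {
      abs(mean(delta_bfm[hi]) - mean(delta_bfm[!hi]))
    } else {
      abs(stats::t.test(delta_bfm[hi], delta_bfm[!hi])$statistic)
    }
    better <- s > best_stat + 1e-10
    tie <- !is.null(best) && abs(s - best_stat) <= 1e-10 &&
      abs(cut - median(scores)) < abs(best - median(scores)) - 1e-12
    if (better || tie) {
      best <- cut
      best_stat <- max(s, best_stat)
    }
  }
  best
}

# OLS by explicit normal equations.
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
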