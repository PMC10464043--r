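# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, all-pairs enumeration, and
# bisection on distribution functions.

# Per-value loop version of the 2x2 contingency table.
brute_contingency <- function(edi, group, cutoff, strict = TRUE) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(edi)) {
    pos <- if (strict) edi[i] > cutoff else edi[i] >= cutoff
    if (group[i] == "SGS") {
      if (pos) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (pos) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# All-pairs Mann-Whitney AUC with half-credit ties.
brute_auc <- function(pos, neg) {
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}

# Clopper-Pearson bounds by bisection on the binomial tail probabilities
# (independent of qbeta): the lower bound solves P(X >= x | p) = alpha/2,
# the upper bound solves P(X <= x | p) = alpha/2.
brute_clopper_pearson <- function(x, n, level = 0.95, tol = 1e-10) {
  alpha <- 1 - level
  bisect <- function(f) {
    lo <- 0
    hi <- 1
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else {
    bisect(function(p) (1 - pbinom(x - 1, n, p)) - alpha / 2)
  }
  upper <- if (x == n) 1 else {
    bisect(function(p) alpha / 2 - pbinom(x, n, p))
  }
  c(lower = lower, upper = upper)
}

# Two-sided Fisher p-value by hypergeometric enumeration: sum the
# probabilities of all tables (with the observed margins) no more likely
# than the observed one.
brute_fisher_p <- function(m) {
  stopifnot(all(dim(m) == c(2, 2)))
  k_obs <- m[1, 1]
  row1 <- sum(m[1, ])
  col1 <- sum(m[, 1])
  col2 <- sum(m[, 2])
  ks <- max(0, row1 - col2):min(row1, col1)
  probs <- dhyper(ks, col1, col2, row1)
  p_obs <- dhyper(k_obs, col1, col2, row1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A small random labeled EDI cohort for property tests.
random_edi_cohort <- function(n_sgs, n_asthma, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      group = c(rep("SGS", n_sgs), rep("asthma", n_asthma)),
      edi = c(rlnorm(n_sgs, log(60), 0.3), rlnorm(n_asthma, log(38), 0.25))
    )
  })
}

study_closed_form_auc <- function() {
  specs <- study_group_specs()
  lognormal_auc(specs$mu[specs$group == "SGS"], specs$sigma[specs$group == "SGS"],
                specs$mu[specs$group == "asthma"], specs$sigma[specs$group == "asthma"])
}
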