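# ROC/AUC construction, binomial intervals, cutoff selection and group
# comparison tests, each checked against an independent oracle.

test_that("contingency counts equal a per-value enumeration oracle", {
  # all-positive limit
  sim <- random_edi_cohort(10, 8, seed = 1)
  tab <- build_contingency(sim, cutoff = min(sim$edi) - 1)
  expect_equal(tab$fn + tab$tn, 0)
  expect_equal(tab$tp, 10)
  expect_equal(tab$fp, 8)

  for (seed in 1:5) {
    sim <- random_edi_cohort(12, 8, seed = seed)
    for (cutoff in c(30, 48, 60)) {
      for (strict in c(TRUE, FALSE)) {
        got <- unlist(build_contingency(sim, cutoff, strict = strict))
        want <- brute_contingency(sim$edi, sim$group, cutoff, strict)
        expect_identical(unname(got), unname(as.integer(want)))
      }
    }
  }
  expect_error(
    build_contingency(tibble::tibble(group = rep("SGS", 3), edi = 1:3 * 20), 48),
    "both conditions required"
  )
})

test_that("sensitivity and specificity are the plain ratios", {
  got <- sensitivity_specificity(tibble::tibble(tp = 44, fn = 6, fp = 5, tn = 27))
  expect_identical(got$sensitivity, 44 / 50)
  expect_identical(got$specificity, 27 / 32)
  perfect <- sensitivity_specificity(tibble::tibble(tp = 9, fn = 0, fp = 0, tn = 4))
  expect_identical(c(perfect$sensitivity, perfect$specificity), c(1, 1))
  for (seed in 1:5) {
    tab <- withr::with_seed(seed, tibble::tibble(
      tp = sample(0:50, 1), fn = sample(1:20, 1),
      fp = sample(0:20, 1), tn = sample(1:30, 1)
    ))
    got <- sensitivity_specificity(tab)
    expect_equal(got$sensitivity, tab$tp / (tab$tp + tab$fn))
    expect_equal(got$specificity, tab$tn / (tab$fp + tab$tn))
  }
  expect_error(sensitivity_specificity(tibble::tibble(tp = 0, fn = 0, fp = 1, tn = 2)),
               "undefined metric")
})

test_that("Clopper-Pearson intervals hit the boundaries exactly and match a tail-probability oracle", {
  expect_identical(proportion_ci(10, 10)$upper, 1)
  expect_identical(proportion_ci(0, 10)$lower, 0)
  for (case in list(c(44, 50), c(27, 32), c(1, 20), c(19, 20))) {
    got <- proportion_ci(case[1], case[2], method = "clopper_pearson")
    want <- brute_clopper_pearson(case[1], case[2])
    expect_equal(got$lower, unname(want["lower"]), tolerance = 1e-6)
    expect_equal(got$upper, unname(want["upper"]), tolerance = 1e-6)
  }
  expect_error(proportion_ci(5, 10, level = 1.2), "level")
  expect_error(proportion_ci(11, 10), "0..n")
})

test_that("Wilson bounds are the roots of the score equation", {
  z <- qnorm(0.975)
  for (case in list(c(44, 50), c(5, 32), c(15, 40))) {
    ci <- proportion_ci(case[1], case[2], method = "wilson")
    p_hat <- case[1] / case[2]
    for (p in c(ci$lower, ci$upper)) {
      expect_equal((p_hat - p)^2, z^2 * p * (1 - p) / case[2], tolerance = 1e-10)
    }
  }
})

test_that("exact-interval coverage stays at or above the nominal level", {
  # conservatism of Clopper-Pearson at p = 0.85, n = 50
  x <- withr::with_seed(2024, rbinom(2000, 50, 0.85))
  covered <- vapply(x, function(xi) {
    ci <- proportion_ci(xi, 50)
    ci$lower <= 0.85 && 0.85 <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("ROC points carry both endpoints, are monotone, and match brute-force tabulation", {
  # perfect separation passes through (sens 1, spec 1)
  sep <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 3),
                        edi = c(60, 65, 70, 30, 35, 40))
  roc <- roc_points(sep)
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))

  # no-information limit: identical values, AUC 1/2
  flat <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 4), edi = rep(50, 8))
  expect_equal(edi_auc(flat), 0.5)
  roc_flat <- roc_points(flat)
  expect_true(any(roc_flat$sensitivity == 1 & roc_flat$specificity == 0))
  expect_true(any(roc_flat$sensitivity == 0 & roc_flat$specificity == 1))

  for (seed in 1:5) {
    sim <- random_edi_cohort(18, 12, seed = seed)
    sim$edi[1:3] <- sim$edi[4:6]  # inject ties
    roc <- roc_points(sim)
    expect_true(all(diff(roc$sensitivity) <= 0))
    expect_true(all(diff(roc$specificity) >= 0))
    expect_equal(roc$sensitivity[1], 1)
    expect_equal(roc$specificity[1], 0)
    expect_equal(roc$sensitivity[nrow(roc)], 0)
    expect_equal(roc$specificity[nrow(roc)], 1)
    for (i in unique(round(seq(1, nrow(roc), length.out = 8)))) {
      tab <- build_contingency(sim, cutoff = max(roc$threshold[i], min(sim$edi) - 1))
      ss <- sensitivity_specificity(tab)
      if (is.finite(roc$threshold[i])) {
        expect_equal(roc$sensitivity[i], ss$sensitivity)
        expect_equal(roc$specificity[i], ss$specificity)
      }
    }
  }
})

test_that("the two AUC forms agree to 1e-12 and equal the all-pairs count", {
  sep <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 3),
                        edi = c(60, 65, 70, 30, 35, 40))
  expect_identical(edi_auc(sep), 1)
  for (seed in 1:10) {
    sim <- random_edi_cohort(25, 25, seed = seed)
    if (seed %% 2 == 0) sim$edi[1:5] <- sim$edi[6:10]  # ties
    mw <- edi_auc(sim, method = "mann_whitney")
    tz <- edi_auc(sim, method = "trapezoid")
    expect_lt(abs(mw - tz), 1e-12)
    expect_equal(mw, brute_auc(sim$edi[sim$group == "SGS"],
                               sim$edi[sim$group == "asthma"]),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms and ~0.5 under label permutation", {
  sim <- random_edi_cohort(20, 15, seed = 3)
  base <- edi_auc(sim)
  for (f in list(function(x) exp(x / 50), function(x) x^3,
                 function(x) 5 * x + 2, sqrt)) {
    transformed <- sim
    transformed$edi <- f(sim$edi)
    expect_equal(edi_auc(transformed), base, tolerance = 1e-12)
  }
  perm_aucs <- withr::with_seed(8, vapply(1:200, function(i) {
    shuffled <- sim
    shuffled$group <- sample(sim$group)
    edi_auc(shuffled)
  }, numeric(1)))
  expect_lt(abs(mean(perm_aucs) - 0.5), 0.03)
})

test_that("AUC intervals behave at the zero-variance limit and are seeded", {
  sep <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 4),
                        edi = c(61:64, 31:34))
  hm <- auc_ci(sep, method = "hanley_mcneil")
  expect_identical(c(hm$auc, hm$lower, hm$upper), c(1, 1, 1))

  sim <- random_edi_cohort(15, 12, seed = 2)
  b1 <- auc_ci(sim, method = "bootstrap", n_boot = 300, seed = 9)
  b2 <- auc_ci(sim, method = "bootstrap", n_boot = 300, seed = 9)
  expect_identical(b1, b2)
  expect_warning(
    auc_ci(tibble::tibble(group = rep(c("SGS", "asthma"), each = 5),
                          edi = rep(c(60, 40), each = 5)),
           method = "bootstrap", n_boot = 100, seed = 1),
    "degenerate"
  )
})

test_that("both AUC interval methods cover the closed-form value on a large calibrated cohort", {
  sim <- simulate_edi_cohort(study_group_specs(2000, 2000), seed = 31)
  truth <- study_closed_form_auc()
  hm <- auc_ci(sim, method = "hanley_mcneil")
  bs <- auc_ci(sim, method = "bootstrap", n_boot = 400, seed = 31)
  expect_true(hm$lower <= truth && truth <= hm$upper)
  expect_true(bs$lower <= truth && truth <= bs$upper)
})

test_that("cutoff selection maximizes Youden's J with ties broken low", {
  # separated groups with a gap: the optimum is the largest non-diseased
  # value, the lowest observed threshold achieving J = 1
  sep <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 3),
                        edi = c(60, 63, 69, 40, 42, 44))
  expect_identical(best_cutoff(sep), 44)

  # a genuine tie: J = 0.5 at thresholds 1 and 3, pick the lower
  tie <- tibble::tibble(group = c("SGS", "SGS", "asthma", "asthma"),
                        edi = c(2, 4, 1, 3))
  expect_identical(best_cutoff(tie), 1)

  # exhaustive-search oracle on random cohorts
  for (seed in 1:5) {
    sim <- random_edi_cohort(22, 18, seed = seed)
    js <- vapply(sort(unique(sim$edi)), function(t) {
      ss <- sensitivity_specificity(build_contingency(sim, t))
      ss$sensitivity + ss$specificity - 1
    }, numeric(1))
    want <- min(sort(unique(sim$edi))[js >= max(js) - 1e-12])
    expect_identical(best_cutoff(sim), want)

    grid <- seq(floor(min(sim$edi)), ceiling(max(sim$edi)))
    js_int <- vapply(grid, function(t) {
      tab <- build_contingency(sim, t)
      if (tab$tp + tab$fp == 0 || tab$fn + tab$tn == 0) return(-Inf)
      ss <- sensitivity_specificity(tab)
      ss$sensitivity + ss$specificity - 1
    }, numeric(1))
    want_int <- min(grid[js_int >= max(js_int) - 1e-12])
    expect_identical(best_cutoff(sim, integer_grid = TRUE), want_int)
  }
})

test_that("the median optimal integer cutoff over replicates brackets the published 48-50 region", {
  cuts <- vapply(1:500, function(s) {
    best_cutoff(simulate_edi_cohort(study_group_specs(), seed = 1000 + s),
                integer_grid = TRUE)
  }, numeric(1))
  expect_gte(median(cuts), 44)
  expect_lte(median(cuts), 52)
})

test_that("group comparison tests match enumeration oracles", {
  # identical samples: no group difference, p = 1
  same <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 3),
                         edi = rep(c(1, 2, 3), 2))
  expect_equal(compare_groups(same, edi)$p_value, 1, tolerance = 1e-9)

  # disjoint 3 vs 3: exact two-sided p = 2 / choose(6, 3) = 0.1
  disjoint <- tibble::tibble(group = rep(c("SGS", "asthma"), each = 3),
                             edi = c(1, 2, 3, 7, 8, 9))
  res <- compare_groups(disjoint, edi)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_match(res$method, "exact")

  # Fisher on an extreme 2x2 equals direct hypergeometric summation
  m <- matrix(c(1, 9, 9, 1), nrow = 2, byrow = TRUE)
  expect_equal(compare_groups(m, kind = "fisher_exact")$p_value,
               brute_fisher_p(m), tolerance = 1e-10)
  m2 <- matrix(c(39, 11, 21, 11), nrow = 2, byrow = TRUE)
  expect_equal(compare_groups(m2, kind = "fisher_exact")$p_value,
               brute_fisher_p(m2), tolerance = 1e-10)

  # binary cohort variable goes through the same Fisher path
  cohort <- tibble::tibble(
    group = c(rep("SGS", 10), rep("asthma", 10)),
    sex = c(rep("female", 1), rep("male", 9), rep("female", 9), rep("male", 1))
  )
  expect_equal(compare_groups(cohort, sex)$p_value, brute_fisher_p(m),
               tolerance = 1e-10)
  expect_error(compare_groups(tibble::tibble(group = "SGS", edi = 1), edi),
               "both groups")
})

test_that("compare_cohort maps the tests over the spirometry columns", {
  fixture <- compute_edi(make_table2_fixture())
  res <- compare_cohort(fixture, c("fev1_l", "pefr_ls", "edi"))
  expect_equal(res$variable, c("fev1_l", "pefr_ls", "edi"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  # the EDI separates the fixture groups decisively
  expect_lt(res$p_value[res$variable == "edi"], 1e-6)
})

test_that("the AUC agrees with an established independent implementation", {
  for (seed in c(2, 14)) {
    sim <- random_edi_cohort(30, 20, seed = seed)
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = sim$group, predictor = sim$edi,
      levels = c("asthma", "SGS"), direction = "<"
    )))
    expect_equal(edi_auc(sim), as.numeric(ref), tolerance = 1e-12)
  }
})
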