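#' Build the 2x2 screening contingency table
#'
#' Cross-tabulates condition (`"SGS"` = diseased, `"asthma"` =
#' non-diseased) against the screening decision at a given EDI cutoff
#' (positivity per [screen_positive()]):
#' `tp` = SGS & screen-positive, `fn` = SGS & screen-negative,
#' `fp` = asthma & screen-positive, `tn` = asthma & screen-negative.
#'
#' @param data A data frame with columns `group` and `edi` (both
#'   conditions must be present); build one with [compute_edi()] or
#'   [simulate_edi_cohort()].
#' @param cutoff Referral cutoff, EDI units.
#' @param strict Require EDI strictly greater than the cutoff for a
#'   positive screen? See [screen_positive()].
#' @return A one-row tibble with integer columns `tp`, `fn`, `fp`, `tn`
#'   and attributes `cutoff` and `strict`.
#' @examples
#' make_table2_fixture() |> compute_edi() |> build_contingency(cutoff = 48)
#' @export
build_contingency <- function(data, cutoff, strict = TRUE) {
  data <- check_labeled_edi(data)
  positive <- screen_positive(data$edi, cutoff = cutoff, strict = strict)
  diseased <- data$group == "SGS"
  out <- tibble::tibble(
    tp = sum(diseased & positive),
    fn = sum(diseased & !positive),
    fp = sum(!diseased & positive),
    tn = sum(!diseased & !positive)
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "strict") <- strict
  out
}

#' Sensitivity and specificity of a contingency table
#'
#' @param table A one-row data frame with columns `tp`, `fn`, `fp`, `tn`
#'   (see [build_contingency()]).
#' @return A one-row tibble with `sensitivity = tp / (tp + fn)` and
#'   `specificity = tn / (fp + tn)`.
#' @examples
#' sensitivity_specificity(tibble::tibble(tp = 44, fn = 6, fp = 5, tn = 27))
#' @export
sensitivity_specificity <- function(table) {
  table <- check_contingency(table)
  if (table$tp + table$fn == 0 || table$fp + table$tn == 0) {
    abort_validation("undefined metric: a margin of the contingency table is empty.")
  }
  tibble::tibble(
    sensitivity = table$tp / (table$tp + table$fn),
    specificity = table$tn / (table$fp + table$tn)
  )
}

check_contingency <- function(table) {
  if (!is.data.frame(table) || nrow(table) != 1L ||
      !all(c("tp", "fn", "fp", "tn") %in% names(table))) {
    abort_schema("`table` must be a one-row data frame with columns tp, fn, fp, tn.")
  }
  counts <- unlist(table[1, c("tp", "fn", "fp", "tn")])
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_validation("contingency counts must be non-negative integers.")
  }
  table
}

#' Binomial confidence interval for a proportion
#'
#' Two interval methods are offered:
#' * `clopper_pearson` (default) — the exact central interval from beta
#'   quantiles: lower = `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#'   upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Its
#'   actual coverage is at least the nominal level.
#' * `wilson` — the score interval, narrower and approximately calibrated.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A one-row tibble: `estimate`, `lower`, `upper`, `level`,
#'   `method`, all bounds clamped to \[0, 1\].
#' @examples
#' proportion_ci(44, 50)
#' proportion_ci(27, 32, method = "wilson")
#' @export
proportion_ci <- function(successes, n,
                          method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  check_level(level)
  check_number(n, "n", positive = TRUE)
  check_number(successes, "successes")
  if (successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    abort_validation("`successes` must be an integer in 0..n.")
  }
  alpha <- 1 - level
  est <- successes / n
  if (method == "clopper_pearson") {
    lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
    upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  } else {
    z <- qnorm(1 - alpha / 2)
    centre <- (est + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(est * (1 - est) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lower <- centre - half
    upper <- centre + half
  }
  tibble::tibble(
    estimate = est,
    lower = min(max(lower, 0), 1),
    upper = min(max(upper, 0), 1),
    level = level,
    method = method
  )
}

#' ROC curve of the EDI
#'
#' One candidate threshold per distinct observed EDI value, with
#' positivity defined as strictly greater than the threshold, plus a
#' `-Inf` threshold so both degenerate endpoints are present: `-Inf`
#' gives (sensitivity 1, specificity 0) and the largest observed value
#' gives (sensitivity 0, specificity 1). Sensitivity is non-increasing
#' and specificity non-decreasing in the threshold.
#'
#' @inheritParams build_contingency
#' @return A tibble of class `edi_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`, ordered by threshold, and attributes
#'   `n_pos`/`n_neg` (group sizes).
#' @examples
#' sim <- simulate_edi_cohort(seed = 7)
#' roc <- roc_points(sim)
#' head(roc)
#' @export
roc_points <- function(data) {
  data <- check_labeled_edi(data)
  pos <- sort(data$edi[data$group == "SGS"])
  neg <- sort(data$edi[data$group == "asthma"])
  thresholds <- c(-Inf, sort(unique(data$edi)))
  # findInterval on the sorted group values counts how many are <= t.
  out <- tibble::tibble(
    threshold = thresholds,
    sensitivity = 1 - findInterval(thresholds, pos) / length(pos),
    specificity = findInterval(thresholds, neg) / length(neg)
  )
  attr(out, "n_pos") <- length(pos)
  attr(out, "n_neg") <- length(neg)
  class(out) <- c("edi_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' The AUC is computed two ways that are algebraically identical and are
#' required to agree to 1e-12, as an internal correctness guard:
#' * trapezoidal integration of the ROC polygon from [roc_points()];
#' * the Mann-Whitney form — the proportion of (SGS, asthma) pairs with
#'   `EDI_SGS > EDI_asthma`, ties counted 1/2 — computed from midranks.
#'
#' The Mann-Whitney value is returned. The AUC is invariant under any
#' strictly increasing transformation of the EDI values.
#'
#' @inheritParams build_contingency
#' @param method Return the Mann-Whitney value after cross-checking both
#'   forms (`"both"`, default), or compute a single form without the
#'   guard (mainly for testing).
#' @return A number in \[0, 1\].
#' @examples
#' edi_auc(simulate_edi_cohort(seed = 7))
#' @export
edi_auc <- function(data, method = c("both", "mann_whitney", "trapezoid")) {
  method <- match.arg(method)
  data <- check_labeled_edi(data)
  mw <- if (method != "trapezoid") auc_mann_whitney(data) else NULL
  tz <- if (method != "mann_whitney") auc_trapezoid(data) else NULL
  if (method == "both" && abs(mw - tz) > 1e-12) {
    abort(glue::glue(
      "internal error: Mann-Whitney and trapezoid AUC disagree ",
      "({mw} vs {tz})."
    ), class = "ediscreen_error")
  }
  mw %||% tz
}

auc_mann_whitney <- function(data) {
  diseased <- data$group == "SGS"
  r <- rank(data$edi, ties.method = "average")
  n1 <- sum(diseased)
  n0 <- sum(!diseased)
  (sum(r[diseased]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

auc_trapezoid <- function(data) {
  roc <- roc_points(data)
  fpr <- 1 - roc$specificity  # decreasing in threshold order
  sens <- roc$sensitivity
  sum((fpr[-length(fpr)] - fpr[-1]) * (sens[-length(sens)] + sens[-1]) / 2)
}

#' Confidence interval for the AUC
#'
#' * `hanley_mcneil` (default) — the closed-form standard error of
#'   Hanley & McNeil with a normal interval, clamped to \[0, 1\]; under
#'   perfect separation the SE is 0 and the interval collapses to
#'   \[1, 1\].
#' * `bootstrap` — stratified percentile bootstrap: patients are resampled
#'   with replacement within each condition group, the AUC recomputed per
#'   resample, and the central `level` quantile range reported.
#'   Deterministic given `seed`.
#'
#' @inheritParams build_contingency
#' @param method `"hanley_mcneil"` or `"bootstrap"`.
#' @param level Confidence level, default 0.95.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble: `auc`, `lower`, `upper`, `level`, `method`.
#' @examples
#' sim <- simulate_edi_cohort(seed = 7)
#' auc_ci(sim)
#' auc_ci(sim, method = "bootstrap", n_boot = 500, seed = 1)
#' @export
auc_ci <- function(data, method = c("hanley_mcneil", "bootstrap"),
                   level = 0.95, n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  check_level(level)
  data <- check_labeled_edi(data)
  a <- edi_auc(data)
  n1 <- sum(data$group == "SGS")
  n0 <- sum(data$group == "asthma")
  if (method == "hanley_mcneil") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
                 (n1 * n0))
    z <- qnorm(1 - (1 - level) / 2)
    lower <- max(a - z * se, 0)
    upper <- min(a + z * se, 1)
  } else {
    check_number(n_boot, "n_boot", positive = TRUE)
    if (n_boot < 100) abort_validation("`n_boot` must be at least 100.")
    pos <- data$edi[data$group == "SGS"]
    neg <- data$edi[data$group == "asthma"]
    if (length(unique(pos)) == 1L || length(unique(neg)) == 1L) {
      warn("degenerate group (single distinct value): bootstrap interval may be unreliable.")
    }
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        resampled <- tibble::tibble(
          group = c(rep("SGS", n1), rep("asthma", n0)),
          edi = c(sample(pos, n1, replace = TRUE),
                  sample(neg, n0, replace = TRUE))
        )
        auc_mann_whitney(resampled)
      }, numeric(1))
    })
    qs <- unname(quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          type = 7))
    lower <- qs[1]
    upper <- qs[2]
  }
  tibble::tibble(auc = a, lower = lower, upper = upper,
                 level = level, method = method)
}

#' Optimal screening cutoff from a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the candidate
#' thresholds, breaking ties toward the lower threshold (favoring
#' sensitivity, the appropriate direction for a screening test). With
#' `integer_grid = TRUE` only integer cutoffs spanning the observed range
#' are evaluated; their operating points are looked up on the ROC step
#' function (positivity is "strictly greater", so an integer cutoff `c`
#' acts like the largest observed value not exceeding `c`).
#'
#' @param x A labeled EDI data frame (columns `group`, `edi`) or an
#'   `edi_roc` from [roc_points()].
#' @param criterion Cutoff criterion; only `"youden"` is implemented.
#' @param integer_grid Restrict candidates to integer cutoffs?
#' @return The selected cutoff (a single number).
#' @examples
#' fixture <- compute_edi(make_table2_fixture())
#' best_cutoff(fixture, integer_grid = TRUE)
#' @export
best_cutoff <- function(x, criterion = "youden", integer_grid = FALSE) {
  criterion <- match.arg(criterion, "youden")
  roc <- if (inherits(x, "edi_roc")) x else roc_points(x)
  finite <- dplyr::filter(tibble::as_tibble(roc), is.finite(.data$threshold))
  if (nrow(finite) < 2L) {
    abort_validation("degenerate ROC curve: need at least two distinct thresholds.")
  }
  if (integer_grid) {
    candidates <- seq(floor(min(finite$threshold)), ceiling(max(finite$threshold)))
    idx <- findInterval(candidates, finite$threshold)
    keep <- idx >= 1L
    candidates <- candidates[keep]
    idx <- idx[keep]
    j <- finite$sensitivity[idx] + finite$specificity[idx] - 1
  } else {
    candidates <- finite$threshold
    j <- finite$sensitivity + finite$specificity - 1
  }
  best <- j >= max(j) - 1e-12
  min(candidates[best])
}

#' Between-group comparison tests
#'
#' Tests a per-patient variable for a difference between the two condition
#' groups, the way demographic and spirometry variables are compared in a
#' cohort characteristics table.
#' * Continuous variables: two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'   via [stats::wilcox.test()] — exact enumeration when the combined
#'   sample size is at most 12 and there are no ties, otherwise the
#'   tie-corrected normal approximation (no continuity correction).
#' * Binary variables (or a 2x2 count matrix passed directly): Fisher's
#'   exact test via [stats::fisher.test()], two-sided by summing tables
#'   with probability at most that observed.
#'
#' @param data A data frame with a `group` column, or a 2x2 count matrix
#'   (then `kind` must be `"fisher_exact"`).
#' @param var For a data frame: the column to compare (unquoted).
#' @param kind `"mann_whitney"` or `"fisher_exact"`; inferred from the
#'   variable type when omitted (numeric -> Mann-Whitney, two-level
#'   discrete -> Fisher).
#' @return A one-row tibble: `variable`, `kind`, `statistic` (Mann-Whitney
#'   U, or `NA` for Fisher), `p_value`, `method`.
#' @examples
#' fixture <- compute_edi(make_table2_fixture())
#' compare_groups(fixture, fev1_l)
#' compare_groups(matrix(c(39, 11, 21, 11), nrow = 2), kind = "fisher_exact")
#' @export
compare_groups <- function(data, var = NULL, kind = NULL) {
  if (is.matrix(data)) {
    if (!is.null(kind) && kind != "fisher_exact") {
      abort_validation("a count matrix implies kind = 'fisher_exact'.")
    }
    if (!all(dim(data) == c(2L, 2L))) {
      abort_validation("Fisher's exact test needs a 2x2 count matrix.")
    }
    p <- fisher.test(data)$p.value
    return(tibble::tibble(variable = NA_character_, kind = "fisher_exact",
                          statistic = NA_real_, p_value = p,
                          method = "Fisher's exact test (two-sided)"))
  }
  if (!is.data.frame(data) || !"group" %in% names(data)) {
    abort_validation("`data` must be a data frame with a `group` column, or a 2x2 matrix.")
  }
  var_quo <- rlang::enquo(var)
  if (rlang::quo_is_null(var_quo)) {
    abort_validation("`var` is required when `data` is a data frame.")
  }
  values <- dplyr::pull(data, !!var_quo)
  var_name <- rlang::as_name(var_quo)
  groups <- normalize_group(data$group)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- groups[keep]
  a <- values[groups == "SGS"]
  b <- values[groups == "asthma"]
  if (length(a) == 0 || length(b) == 0) {
    abort_validation("both groups must have at least one non-missing value.")
  }
  if (is.null(kind)) {
    kind <- if (is.numeric(values)) "mann_whitney" else "fisher_exact"
  }
  kind <- match.arg(kind, c("mann_whitney", "fisher_exact"))
  if (kind == "mann_whitney") {
    if (!is.numeric(values)) abort_validation("Mann-Whitney requires a numeric variable.")
    ties <- anyDuplicated(values) > 0
    use_exact <- (length(a) + length(b)) <= 12 && !ties
    res <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided",
                  exact = use_exact, correct = FALSE)
    )
    tibble::tibble(
      variable = var_name, kind = kind,
      statistic = unname(res$statistic), p_value = res$p.value,
      method = if (use_exact) {
        "Mann-Whitney, exact enumeration"
      } else {
        "Mann-Whitney, tie-corrected normal approximation"
      }
    )
  } else {
    lev <- unique(values)
    if (length(lev) != 2L) {
      abort_validation("Fisher's exact test requires a two-level variable.")
    }
    counts <- table(factor(groups, levels = edi_groups),
                    factor(values, levels = lev))
    p <- fisher.test(counts)$p.value
    tibble::tibble(variable = var_name, kind = kind,
                   statistic = NA_real_, p_value = p,
                   method = "Fisher's exact test (two-sided)")
  }
}

#' Compare several cohort variables between groups
#'
#' Maps [compare_groups()] over a set of cohort columns, producing the
#' p-value column of a group-characteristics table.
#'
#' @param data A cohort data frame with a `group` column.
#' @param vars Character vector of column names to compare.
#' @return A tibble with one row per variable.
#' @examples
#' fixture <- compute_edi(make_table2_fixture())
#' compare_cohort(fixture, c("fev1_l", "pefr_ls", "edi"))
#' @export
compare_cohort <- function(data, vars = c("fev1_l", "pefr_ls", "fvc_l", "vc_l")) {
  vars <- intersect(vars, names(data))
  purrr::map_dfr(vars, function(v) {
    compare_groups(data, !!rlang::sym(v))
  })
}
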