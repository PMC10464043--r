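#' Full diagnostic-accuracy evaluation of the EDI
#'
#' Runs the complete evaluation on a labeled cohort: ROC curve, AUC with
#' confidence interval, the screening cutoff (fixed, or optimized with
#' [best_cutoff()] when `cutoff = NULL`), the 2x2 contingency table at
#' that cutoff, and sensitivity/specificity with binomial confidence
#' intervals.
#'
#' @param data A data frame with columns `group` and `edi`, or a cohort
#'   with `fev1_l`/`pefr_ls` from which the EDI is computed.
#' @param cutoff Fixed EDI cutoff; `NULL` (default) selects the Youden
#'   cutoff from the data. Note that an optimized cutoff is evaluated on
#'   the same data that chose it, so its operating point is optimistically
#'   biased.
#' @param strict Positivity rule at the cutoff, see [screen_positive()].
#' @param level Confidence level for all intervals.
#' @param ci_method Binomial interval method, see [proportion_ci()].
#' @param auc_ci_method AUC interval method, see [auc_ci()].
#' @param n_boot Bootstrap resamples when `auc_ci_method = "bootstrap"`.
#' @param integer_grid Restrict cutoff optimization to integer cutoffs?
#' @param seed Optional integer seed (used by the bootstrap).
#' @return An object of class `edi_accuracy`: a list with elements
#'   `cutoff`, `cutoff_source`, `strict`, `table`, `sensitivity`,
#'   `specificity`, `auc` (tibbles from the component functions), `roc`,
#'   `n_sgs`, `n_asthma`, `level`, `methods`, `seed`. Methods:
#'   [tidy()][generics::tidy], [glance()][generics::glance], `print()`,
#'   [ggplot2::autoplot()].
#' @examples
#' fit <- make_table2_fixture() |> compute_edi() |> evaluate_accuracy(cutoff = 48)
#' fit
#' glance(fit)
#' @export
evaluate_accuracy <- function(data, cutoff = NULL, strict = TRUE,
                              level = 0.95,
                              ci_method = c("clopper_pearson", "wilson"),
                              auc_ci_method = c("hanley_mcneil", "bootstrap"),
                              n_boot = 2000, integer_grid = FALSE,
                              seed = NULL) {
  ci_method <- match.arg(ci_method)
  auc_ci_method <- match.arg(auc_ci_method)
  check_level(level)
  if (is.data.frame(data) && !"edi" %in% names(data) &&
      all(c("fev1_l", "pefr_ls") %in% names(data))) {
    data <- compute_edi(data)
  }
  data <- check_labeled_edi(data)

  roc <- roc_points(data)
  cutoff_source <- if (is.null(cutoff)) {
    if (integer_grid) "optimized (Youden, integer grid)" else "optimized (Youden)"
  } else {
    "fixed"
  }
  if (is.null(cutoff)) {
    cutoff <- best_cutoff(roc, integer_grid = integer_grid)
  }
  tab <- build_contingency(data, cutoff = cutoff, strict = strict)
  sens_spec <- sensitivity_specificity(tab)
  sens_ci <- proportion_ci(tab$tp, tab$tp + tab$fn, method = ci_method, level = level)
  spec_ci <- proportion_ci(tab$tn, tab$fp + tab$tn, method = ci_method, level = level)
  auc_int <- auc_ci(data, method = auc_ci_method, level = level,
                    n_boot = n_boot, seed = seed)

  structure(
    list(
      cutoff = cutoff,
      cutoff_source = cutoff_source,
      strict = strict,
      table = tab,
      sensitivity = sens_ci,
      specificity = spec_ci,
      auc = auc_int,
      roc = roc,
      n_sgs = tab$tp + tab$fn,
      n_asthma = tab$fp + tab$tn,
      level = level,
      methods = list(ci_method = ci_method, auc_ci_method = auc_ci_method,
                     n_boot = if (auc_ci_method == "bootstrap") n_boot else NA_integer_),
      seed = seed
    ),
    class = "edi_accuracy"
  )
}

#' @export
tidy.edi_accuracy <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "specificity", "auc"),
    estimate = c(x$sensitivity$estimate, x$specificity$estimate, x$auc$auc),
    lower = c(x$sensitivity$lower, x$specificity$lower, x$auc$lower),
    upper = c(x$sensitivity$upper, x$specificity$upper, x$auc$upper),
    level = x$level,
    method = c(x$sensitivity$method, x$specificity$method, x$auc$method)
  )
}

#' @export
glance.edi_accuracy <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff,
    strict = x$strict,
    tp = x$table$tp, fn = x$table$fn, fp = x$table$fp, tn = x$table$tn,
    sensitivity = x$sensitivity$estimate,
    specificity = x$specificity$estimate,
    auc = x$auc$auc,
    auc_lower = x$auc$lower,
    auc_upper = x$auc$upper,
    n_sgs = x$n_sgs,
    n_asthma = x$n_asthma
  )
}

#' @export
print.edi_accuracy <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable accuracy report
#'
#' Formats an [evaluate_accuracy()] result as plain text: the 2x2
#' contingency table in its published layout (screening decision in rows,
#' condition in columns), percent metrics at 1 decimal place, the AUC at
#' 2 decimals, and the method provenance of every interval.
#'
#' @param report An `edi_accuracy` object.
#' @return A character vector of report lines (also the `print()` method
#'   of `edi_accuracy`).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "edi_accuracy"))
  tab <- report$table
  cmp <- if (report$strict) c(">", "<=") else c(">=", "<")
  pct <- function(p) sprintf("%.1f%%", 100 * p)
  ci_line <- function(label, ci) {
    glue::glue("{label}: {pct(ci$estimate)} ({round(100 * ci$level, 1)}% CI ",
               "{pct(ci$lower)}-{pct(ci$upper)}, {ci$method})")
  }
  rows <- rbind(
    c(glue::glue("EDI {cmp[1]} {report$cutoff}"), tab$tp, tab$fp, tab$tp + tab$fp),
    c(glue::glue("EDI {cmp[2]} {report$cutoff}"), tab$fn, tab$tn, tab$fn + tab$tn),
    c("total", report$n_sgs, report$n_asthma, report$n_sgs + report$n_asthma)
  )
  header <- c("", "SGS", "asthma", "total")
  widths <- pmax(nchar(header), apply(nchar(rows), 2, max))
  fmt_row <- function(r) paste(mapply(formatC, r, width = widths), collapse = "  ")
  c(
    "EDI diagnostic accuracy report",
    "==============================",
    glue::glue("Cutoff: EDI {cmp[1]} {format(report$cutoff)} ({report$cutoff_source})"),
    "",
    fmt_row(header),
    apply(rows, 1, fmt_row),
    "",
    ci_line("Sensitivity", report$sensitivity),
    ci_line("Specificity", report$specificity),
    glue::glue("AUC: {sprintf('%.2f', report$auc$auc)} ",
               "({round(100 * report$auc$level, 1)}% CI ",
               "{sprintf('%.2f', report$auc$lower)}-",
               "{sprintf('%.2f', report$auc$upper)}, {report$auc$method})"),
    glue::glue("Groups: {report$n_sgs} SGS, {report$n_asthma} asthma"),
    if (!is.null(report$seed)) glue::glue("Seed: {report$seed}") else character(0)
  )
}
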