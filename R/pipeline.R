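#' Configure an end-to-end EDI analysis run
#'
#' A run configuration names exactly one input source — a cohort CSV
#' (`input`) or a generator spec table (`specs`, see [group_spec()]) —
#' plus the cutoff policy and method choices. The configuration hash
#' (excluding the output directory) and the seed are embedded in every
#' output file so a run can be reproduced and outputs matched to the
#' configuration that made them.
#'
#' @param input Path to a cohort CSV (see [read_cohort()]), or `NULL`.
#' @param specs A group-spec tibble for [simulate_edi_cohort()], or
#'   `NULL`. Exactly one of `input`/`specs` must be given.
#' @param cutoff Fixed EDI cutoff, or `NULL` to optimize (Youden).
#' @param strict Positivity rule at the cutoff.
#' @param level Confidence level.
#' @param ci_method,auc_ci_method,n_boot,integer_grid Method choices, see
#'   [evaluate_accuracy()].
#' @param seed Integer seed used for simulation and bootstrap.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `edi_run_config`.
#' @export
edi_run_config <- function(input = NULL, specs = NULL, cutoff = NULL,
                           strict = TRUE, level = 0.95,
                           ci_method = "clopper_pearson",
                           auc_ci_method = "hanley_mcneil",
                           n_boot = 2000, integer_grid = FALSE,
                           seed = 1L, out_dir = tempfile("edi_run_")) {
  if (is.null(input) == is.null(specs)) {
    abort_validation("exactly one input source required: give `input` or `specs`.")
  }
  config <- list(
    input = input, specs = specs, cutoff = cutoff, strict = strict,
    level = level, ci_method = ci_method, auc_ci_method = auc_ci_method,
    n_boot = n_boot, integer_grid = integer_grid,
    seed = as.integer(seed), out_dir = out_dir
  )
  class(config) <- "edi_run_config"
  config
}

config_hash <- function(config) {
  # out_dir is excluded so re-running into a different directory
  # reproduces byte-identical reports.
  hash(config[setdiff(names(config), "out_dir")])
}

#' Run the full screening analysis pipeline
#'
#' Reads or simulates a cohort, scores the EDI, evaluates diagnostic
#' accuracy, and writes four files into `config$out_dir`:
#' * `report.json` — the machine-readable report (full precision; read it
#'   back with [read_edi_report()]);
#' * `report.txt` — the [render_report()] text;
#' * `roc_points.csv` — threshold, sensitivity, specificity;
#' * `edi_values.csv` — long-format `group, edi` values, ready for a
#'   violin plot.
#' Every file embeds the configuration hash and seed. The run is
#' deterministic given the configuration: the same config and seed produce
#' byte-identical `report.json` files.
#'
#' @param config An [edi_run_config()].
#' @param quiet Suppress progress messages?
#' @return The `edi_accuracy` result, invisibly, with the written file
#'   paths in attribute `files`.
#' @examples
#' \donttest{
#' cfg <- edi_run_config(specs = study_group_specs(), seed = 42)
#' res <- run_edi_pipeline(cfg)
#' glance(res)
#' }
#' @export
run_edi_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "edi_run_config")) {
    abort_validation("`config` must come from edi_run_config().")
  }
  say <- function(...) if (!quiet) inform(glue::glue(...))

  if (!is.null(config$input)) {
    say("reading cohort from {config$input}")
    cohort <- read_cohort(config$input)
    data <- compute_edi(cohort)
  } else {
    say("simulating cohort from {nrow(config$specs)} group spec(s), seed {config$seed}")
    data <- simulate_edi_cohort(config$specs, seed = config$seed)
  }
  if (nrow(data) == 0) {
    abort_validation("empty cohort: nothing to evaluate.")
  }
  say("evaluating {nrow(data)} records ({sum(data$group == 'SGS')} SGS, ",
      "{sum(data$group == 'asthma')} asthma)")

  report <- evaluate_accuracy(
    data,
    cutoff = config$cutoff, strict = config$strict, level = config$level,
    ci_method = config$ci_method, auc_ci_method = config$auc_ci_method,
    n_boot = config$n_boot, integer_grid = config$integer_grid,
    seed = config$seed
  )
  say("cutoff {format(report$cutoff)} ({report$cutoff_source}); ",
      "sensitivity {sprintf('%.1f%%', 100 * report$sensitivity$estimate)}, ",
      "specificity {sprintf('%.1f%%', 100 * report$specificity$estimate)}, ",
      "AUC {sprintf('%.3f', report$auc$auc)}")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- glue::glue("# config_hash={config_hash(config)} seed={config$seed}")
  files <- c(
    report = file.path(config$out_dir, "report.json"),
    text = file.path(config$out_dir, "report.txt"),
    roc = file.path(config$out_dir, "roc_points.csv"),
    edi = file.path(config$out_dir, "edi_values.csv")
  )
  write_edi_report(report, files[["report"]], config_hash = config_hash(config))
  writeLines(c(render_report(report), "",
               glue::glue("config_hash: {config_hash(config)}"),
               glue::glue("seed: {config$seed}")),
             files[["text"]])
  writeLines(stamp, files[["roc"]])
  readr::write_csv(tibble::as_tibble(report$roc), files[["roc"]],
                   append = TRUE, col_names = TRUE, progress = FALSE)
  writeLines(stamp, files[["edi"]])
  readr::write_csv(data[, c("group", "edi")], files[["edi"]],
                   append = TRUE, col_names = TRUE, progress = FALSE)
  say("wrote {length(files)} files to {config$out_dir}")

  attr(report, "files") <- files
  invisible(report)
}

#' Write and read the machine-readable accuracy report
#'
#' The machine-readable report is a JSON file holding every numeric field
#' of an `edi_accuracy` object at full precision, plus the configuration
#' hash and seed. `read_edi_report()` reconstructs an `edi_accuracy`
#' object (without the ROC table, which lives in its own CSV) so the
#' report round-trips losslessly.
#'
#' @param report An `edi_accuracy` object.
#' @param path File path.
#' @param config_hash Optional configuration hash to embed.
#' @return `write_edi_report()` returns `path` invisibly;
#'   `read_edi_report()` returns an `edi_accuracy` object.
#' @export
write_edi_report <- function(report, path, config_hash = NULL) {
  stopifnot(inherits(report, "edi_accuracy"))
  payload <- list(
    config_hash = config_hash,
    seed = report$seed,
    cutoff = report$cutoff,
    cutoff_source = report$cutoff_source,
    strict = report$strict,
    level = report$level,
    table = as.list(report$table[1, c("tp", "fn", "fp", "tn")]),
    sensitivity = as.list(report$sensitivity[1, ]),
    specificity = as.list(report$specificity[1, ]),
    auc = as.list(report$auc[1, ]),
    n_sgs = report$n_sgs,
    n_asthma = report$n_asthma,
    methods = report$methods
  )
  # 17 significant digits: the shortest precision at which every double
  # reads back bit-identically.
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_edi_report
#' @export
read_edi_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON does not distinguish 48 from 48.0, so coerce each field back to
  # the type evaluate_accuracy() produces.
  as_ci <- function(x) {
    out <- tibble::as_tibble(x)
    for (col in intersect(c("estimate", "lower", "upper", "level", "auc"),
                          names(out))) {
      out[[col]] <- as.double(out[[col]])
    }
    out
  }
  structure(
    list(
      cutoff = as.double(payload$cutoff),
      cutoff_source = payload$cutoff_source,
      strict = payload$strict,
      table = tibble::as_tibble(lapply(payload$table, as.integer)),
      sensitivity = as_ci(payload$sensitivity),
      specificity = as_ci(payload$specificity),
      auc = as_ci(payload$auc),
      roc = NULL,
      n_sgs = as.integer(payload$n_sgs),
      n_asthma = as.integer(payload$n_asthma),
      level = payload$level,
      methods = payload$methods,
      seed = payload$seed,
      config_hash = payload$config_hash
    ),
    class = "edi_accuracy"
  )
}
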