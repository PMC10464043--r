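# Shared validation helpers. All user-facing errors go through rlang::abort
# with a subclass so callers (and the pipeline driver) can branch on them.

abort_validation <- function(message, ...) {
  abort(message, class = c("ediscreen_validation_error", "ediscreen_error"), ...)
}

abort_schema <- function(message, ...) {
  abort(message, class = c("ediscreen_schema_error", "ediscreen_error"), ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation(glue::glue("`{name}` must be a single non-missing number."))
  }
  if (finite && !is.finite(x)) {
    abort_validation(glue::glue("`{name}` must be finite."))
  }
  if (positive && x <= 0) {
    abort_validation(glue::glue("`{name}` must be positive."))
  }
  invisible(x)
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    abort_validation("`level` must be a single number strictly between 0 and 1.")
  }
  invisible(level)
}

# Normalize condition labels case-insensitively onto the canonical pair.
# Returns a character vector or aborts naming the offending values.
normalize_group <- function(x) {
  lowered <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    lowered == "sgs" ~ "SGS",
    lowered == "asthma" ~ "asthma",
    .default = NA_character_
  )
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort_validation(glue::glue(
      "Unknown group label(s): {paste(shQuote(bad), collapse = ', ')}. ",
      "Accepted labels (case-insensitive): 'SGS', 'asthma'."
    ))
  }
  out
}

# Require a data frame with `group` and `edi` columns and both conditions
# present; used by every accuracy operation.
check_labeled_edi <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    abort_validation("`data` must be a data frame with columns `group` and `edi`.")
  }
  missing_cols <- setdiff(c("group", "edi"), names(data))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "`data` is missing required column(s): {paste(missing_cols, collapse = ', ')}."
    ))
  }
  data$group <- normalize_group(data$group)
  if (!all(edi_groups %in% data$group)) {
    abort_validation("both conditions required: need at least one 'SGS' and one 'asthma' record.")
  }
  if (!is.numeric(data$edi) || anyNA(data$edi)) {
    abort_validation("`edi` must be numeric with no missing values.")
  }
  data
}

# Seed scoping: every stochastic operation takes an optional integer seed and
# leaves the global RNG stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0) {
    abort_validation("`seed` must be a single non-negative integer.")
  }
  withr::with_seed(as.integer(seed), force(code))
}
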