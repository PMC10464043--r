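# Cohort table I/O. A cohort is an ordinary tibble, one row per patient,
# with a fixed schema so files are portable between tools:
#   required: patient_id (character), group ('SGS'/'asthma'),
#             fev1_l (liters), pefr_ls (liters/second)
#   optional: fvc_l, vc_l (liters), sex ('female'/'male'), age_years,
#             bmi (kg/m^2), etiology (free text)
# Units are fixed (liters, liters/second) because the EDI is defined on them.

cohort_required_cols <- c("patient_id", "group", "fev1_l", "pefr_ls")
cohort_optional_cols <- c("fvc_l", "vc_l", "sex", "age_years", "bmi", "etiology")

#' Validate a cohort table
#'
#' Checks the cohort schema and row-level invariants: required columns
#' present, unique patient ids, recognized group labels (normalized
#' case-insensitively to `"SGS"` / `"asthma"`), positive FEV1 and PEFR,
#' and FEV1 no greater than FVC where FVC is given. Optional columns that
#' are absent are added as `NA` so downstream code can rely on the full
#' schema.
#'
#' One row per patient is required; when a patient has repeated spirometry
#' tests, selecting which maneuver to keep is the caller's responsibility
#' upstream of this package.
#'
#' @param data A data frame in the cohort schema.
#' @return The validated cohort as a tibble with normalized group labels
#'   and all optional columns present.
#' @export
validate_cohort <- function(data) {
  if (!is.data.frame(data)) {
    abort_validation("a cohort must be a data frame.")
  }
  missing_cols <- setdiff(cohort_required_cols, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "cohort is missing required column(s): {paste(missing_cols, collapse = ', ')}."
    ))
  }
  data <- tibble::as_tibble(data)
  data$patient_id <- as.character(data$patient_id)
  if (anyNA(data$patient_id) || any(data$patient_id == "")) {
    abort_validation("`patient_id` must be non-missing and non-empty.")
  }
  if (anyDuplicated(data$patient_id)) {
    dup <- unique(data$patient_id[duplicated(data$patient_id)])
    abort_validation(glue::glue(
      "`patient_id` must be unique; duplicated: {paste(head(dup, 5), collapse = ', ')}."
    ))
  }
  data$group <- normalize_group(data$group)
  for (col in c("fev1_l", "pefr_ls")) {
    v <- data[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) <= 0)
    if (length(bad) > 0) {
      abort_validation(glue::glue(
        "`{col}` must be a positive number; invalid in row(s) ",
        "{paste(head(bad, 5), collapse = ', ')}."
      ))
    }
    data[[col]] <- as.numeric(v)
  }
  for (col in cohort_optional_cols) {
    if (!col %in% names(data)) {
      data[[col]] <- if (col %in% c("sex", "etiology")) NA_character_ else NA_real_
    }
  }
  bad_fvc <- which(!is.na(data$fvc_l) & data$fev1_l > data$fvc_l + 1e-12)
  if (length(bad_fvc) > 0) {
    abort_validation(glue::glue(
      "`fev1_l` exceeds `fvc_l` in row(s) {paste(head(bad_fvc, 5), collapse = ', ')}."
    ))
  }
  data[, c(cohort_required_cols, cohort_optional_cols)]
}

#' Read and write cohort tables
#'
#' Cohort files are UTF-8 comma-separated text with a header row and a
#' decimal point, in the schema described under [validate_cohort()].
#' `write_cohort()` writes doubles with the shortest representation that
#' reads back to the identical value, so
#' `read_cohort(write_cohort(cohort, path))` reproduces every field
#' exactly.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @examples
#' cohort <- make_table2_fixture()
#' path <- tempfile(fileext = ".csv")
#' write_cohort(cohort, path)
#' identical(read_cohort(path)$fev1_l, cohort$fev1_l)
#' @export
read_cohort <- function(path) {
  # Numeric fields are read as text and converted with as.numeric():
  # base R's strtod parse is correctly rounded, so values written at
  # shortest round-trip precision read back bit-identically.
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in intersect(c("fvc_l", "vc_l", "age_years", "bmi"), names(raw))) {
    bad <- which(!is.na(raw[[col]]) &
                   is.na(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad) > 0) {
      abort_validation(glue::glue(
        "`{col}` must be numeric; invalid in row(s) ",
        "{paste(head(bad, 5), collapse = ', ')}."
      ))
    }
    raw[[col]] <- as.numeric(raw[[col]])
  }
  missing_cols <- setdiff(cohort_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "cohort file {path} is missing required column(s): ",
      "{paste(missing_cols, collapse = ', ')}."
    ))
  }
  validate_cohort(raw)
}

#' @rdname read_cohort
#' @param cohort A cohort data frame (see [validate_cohort()]).
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "", progress = FALSE)
  invisible(path)
}
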