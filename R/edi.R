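#' Expiratory Disproportion Index
#'
#' The EDI is the ratio of FEV1 (liters) to PEFR (liters/second),
#' multiplied by 100. A fixed upper-airway obstruction caps peak flow
#' while leaving the volume expired over a whole second comparatively
#' intact, so PEFR falls more than FEV1 and the EDI rises; diffuse
#' lower-airway obstruction (asthma) reduces both roughly proportionally
#' and leaves the EDI unchanged. `edi_value()` is the bare vectorized
#' computation; `compute_edi()` is the data-frame verb that adds an `edi`
#' column to a cohort.
#'
#' No rounding is applied: the EDI carries full floating precision into
#' classification, and is rounded (2 decimals) only for display.
#'
#' @param fev1 Forced expiratory volume in 1 s, liters (positive).
#' @param pefr Peak expiratory flow rate, liters/second (positive).
#' @return `edi_value()`: a numeric vector, `100 * fev1 / pefr`.
#' @examples
#' edi_value(3.0, 3.0)   # 100
#' edi_value(1.2, 5.0)   # 24
#'
#' make_table2_fixture() |> compute_edi() |> head()
#' @export
edi_value <- function(fev1, pefr) {
  if (!is.numeric(fev1) || !is.numeric(pefr)) {
    abort_validation("`fev1` and `pefr` must be numeric.")
  }
  if (any(!is.finite(fev1)) || any(fev1 <= 0)) {
    abort_validation("FEV1 must be positive.")
  }
  if (any(!is.finite(pefr)) || any(pefr <= 0)) {
    abort_validation("PEFR must be positive.")
  }
  100 * fev1 / pefr
}

#' @rdname edi_value
#' @param data A data frame with columns `fev1_l` and `pefr_ls`.
#' @return `compute_edi()`: `data` as a tibble with an `edi` column added
#'   (recomputed if already present).
#' @export
compute_edi <- function(data) {
  if (!is.data.frame(data)) {
    abort_validation("`data` must be a data frame with columns `fev1_l` and `pefr_ls`.")
  }
  missing_cols <- setdiff(c("fev1_l", "pefr_ls"), names(data))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "`data` is missing required column(s): {paste(missing_cols, collapse = ', ')}."
    ))
  }
  dplyr::mutate(tibble::as_tibble(data), edi = edi_value(.data$fev1_l, .data$pefr_ls))
}

#' Screen an EDI value against a referral cutoff
#'
#' A screen-positive result flags possible upper-airway obstruction and
#' would trigger referral for laryngoscopy. With `strict = TRUE` (the
#' default) positivity requires the EDI to be strictly greater than the
#' cutoff, matching the "EDI > cutoff" referral rule; an EDI exactly equal
#' to the cutoff is screen-negative. `strict = FALSE` makes equality
#' positive, since the boundary case is formally unassigned in the
#' published rule.
#'
#' @param edi Numeric vector of EDI values.
#' @param cutoff Referral cutoff, EDI units (finite, positive).
#' @param strict Require strictly greater than the cutoff?
#' @return `screen_positive()`: a logical vector.
#' @examples
#' screen_positive(c(45.68, 67.10), cutoff = 48)  # FALSE TRUE
#' screen_positive(48, 48)                        # FALSE (strict)
#' screen_positive(48, 48, strict = FALSE)        # TRUE
#' @export
screen_positive <- function(edi, cutoff = 48, strict = TRUE) {
  check_number(cutoff, "cutoff", positive = TRUE)
  if (!is.numeric(edi) || anyNA(edi)) {
    abort_validation("`edi` must be numeric with no missing values.")
  }
  if (strict) edi > cutoff else edi >= cutoff
}

#' @rdname screen_positive
#' @param data A data frame with an `edi` column (add one with
#'   [compute_edi()]).
#' @return `classify_edi()`: `data` as a tibble with a logical
#'   `screen_positive` column added; the cutoff and rule are recorded in
#'   attributes `cutoff` and `strict`.
#' @export
classify_edi <- function(data, cutoff = 48, strict = TRUE) {
  if (!is.data.frame(data) || !"edi" %in% names(data)) {
    abort_schema("`data` must be a data frame with an `edi` column; see compute_edi().")
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    screen_positive = screen_positive(.data$edi, cutoff = cutoff, strict = strict)
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "strict") <- strict
  out
}
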