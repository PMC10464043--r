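#' Construct and validate a sampled expiratory flow-volume curve
#'
#' A flow-volume curve is the record of one forced-expiration maneuver:
#' sampled time points (seconds, starting at 0 at the start of forced
#' expiration), cumulative expired volume (liters, starting at 0), and
#' instantaneous expiratory flow (liters/second). Indices such as FEV1 and
#' PEFR are extracted from it with [extract_indices()].
#'
#' Validation enforces the maneuver invariants: time strictly increasing
#' from 0, volume non-decreasing from 0, non-negative flow, at least 3
#' samples, and (optionally) consistency of the flow channel with the
#' numerical derivative of volume with respect to time: on every sampling
#' interval the secant slope of volume must match the trapezoidal mean of
#' the flow endpoints within `flow_tol` times the peak flow. Raw
#' spirometer exports with mismatched channels fail loudly rather than
#' silently producing a wrong PEFR.
#'
#' @param time Numeric vector of sample times in seconds.
#' @param volume Numeric vector of cumulative expired volume in liters.
#' @param flow Numeric vector of instantaneous expiratory flow in L/s.
#' @param check_consistency Check flow against the volume derivative?
#' @param flow_tol Relative consistency tolerance, as a fraction of peak
#'   flow (default 0.05).
#' @return A tibble with columns `time`, `volume`, `flow` and class
#'   `fv_curve`.
#' @examples
#' t <- seq(0, 3, by = 0.01)
#' curve <- flow_volume_curve(t, 2 * t, rep(2, length(t)))
#' extract_indices(curve)
#' @seealso [extract_indices()], [simulate_flow_volume_curve()],
#'   [read_curve()]
#' @export
flow_volume_curve <- function(time, volume, flow,
                              check_consistency = TRUE,
                              flow_tol = 0.05) {
  if (length(time) != length(volume) || length(time) != length(flow)) {
    abort_validation("`time`, `volume` and `flow` must have equal length.")
  }
  if (length(time) < 3L) {
    abort_validation("a flow-volume curve needs at least 3 samples.")
  }
  if (anyNA(time) || anyNA(volume) || anyNA(flow)) {
    abort_validation("curve samples must not contain missing values.")
  }
  if (time[1] != 0) {
    abort_validation("`time` must start at 0 (start of forced expiration).")
  }
  if (any(diff(time) <= 0)) {
    abort_validation("`time` must be strictly increasing.")
  }
  if (volume[1] != 0) {
    abort_validation("`volume` must start at 0.")
  }
  if (any(diff(volume) < 0)) {
    abort_validation("`volume` must be non-decreasing.")
  }
  if (any(flow < 0)) {
    abort_validation("`flow` must be non-negative at every sample.")
  }
  curve <- tibble::tibble(time = as.double(time),
                          volume = as.double(volume),
                          flow = as.double(flow))
  if (check_consistency) {
    check_flow_consistency(curve, flow_tol)
  }
  class(curve) <- c("fv_curve", class(curve))
  curve
}

# Consistency of the flow channel with the numerical derivative of volume:
# on every sampling interval the secant slope (v[i+1] - v[i]) / (t[i+1] -
# t[i]) must match the trapezoidal mean of the flow endpoints. This is
# exact for any maneuver whose volume is piecewise quadratic (flow
# piecewise linear) between samples, including constant- and linear-flow
# curves, and O(h^2) otherwise.
check_flow_consistency <- function(curve, flow_tol) {
  n <- nrow(curve)
  slope <- diff(curve$volume) / diff(curve$time)
  mean_flow <- (curve$flow[-1L] + curve$flow[-n]) / 2
  peak <- max(curve$flow)
  if (peak <= 0) {
    abort_validation("`flow` must be positive somewhere on the maneuver.")
  }
  dev <- max(abs(slope - mean_flow))
  if (dev > flow_tol * peak) {
    abort_validation(glue::glue(
      "flow is inconsistent with the volume derivative: max deviation ",
      "{signif(dev, 4)} L/s exceeds {flow_tol * 100}% of peak flow ",
      "({signif(peak, 4)} L/s)."
    ))
  }
  invisible(curve)
}

as_fv_curve <- function(data, check_consistency = TRUE, flow_tol = 0.05) {
  if (inherits(data, "fv_curve")) return(data)
  missing_cols <- setdiff(c("time", "volume", "flow"), names(data))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "curve is missing required column(s): {paste(missing_cols, collapse = ', ')}."
    ))
  }
  flow_volume_curve(data$time, data$volume, data$flow,
                    check_consistency = check_consistency,
                    flow_tol = flow_tol)
}

#' Extract spirometry indices from a flow-volume curve
#'
#' Computes the three indices that enter the screening analysis:
#' * `fev1` — forced expiratory volume in the first second, the expired
#'   volume at t = 1 s obtained by linear interpolation of the volume
#'   samples (exact whenever volume is piecewise linear between samples);
#' * `pefr` — peak expiratory flow rate, the maximum of the flow samples;
#' * `fvc` — forced vital capacity, the final volume sample.
#'
#' No back-extrapolated time-zero correction is applied: t = 0 is taken as
#' the start of forced expiration as recorded.
#'
#' @param curve An `fv_curve` (see [flow_volume_curve()]) or a data frame
#'   with columns `time`, `volume`, `flow`.
#' @param check_consistency,flow_tol Validation options passed to
#'   [flow_volume_curve()] when `curve` is a plain data frame.
#' @return A one-row tibble with columns `fev1`, `pefr`, `fvc` (liters,
#'   L/s, liters).
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' curve <- flow_volume_curve(t, 4 * t - t^2 / 2, 4 - t)
#' extract_indices(curve) # fev1 = 3.5, pefr = 4, fvc = 8
#' @export
extract_indices <- function(curve, check_consistency = TRUE, flow_tol = 0.05) {
  curve <- as_fv_curve(curve, check_consistency = check_consistency,
                       flow_tol = flow_tol)
  duration <- curve$time[nrow(curve)]
  if (duration < 1) {
    abort_validation("curve too short for FEV1: maneuver duration must be at least 1 s.")
  }
  fev1 <- approx(curve$time, curve$volume, xout = 1, ties = "ordered")$y
  pefr <- max(curve$flow)
  fvc <- curve$volume[nrow(curve)]
  if (fev1 <= 0 || pefr <= 0) {
    abort_validation("degenerate maneuver: FEV1 and PEFR must be positive.")
  }
  tibble::tibble(fev1 = fev1, pefr = pefr, fvc = fvc)
}

#' Read or write a single-maneuver curve file
#'
#' Curve files are plain CSV with a header and columns `time_s`,
#' `volume_l`, `flow_ls`, one maneuver per file.
#'
#' @param path File path.
#' @param check_consistency,flow_tol Validation options, see
#'   [flow_volume_curve()].
#' @return `read_curve()` returns an `fv_curve`; `write_curve()` returns
#'   `path` invisibly.
#' @export
read_curve <- function(path, check_consistency = TRUE, flow_tol = 0.05) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  missing_cols <- setdiff(c("time_s", "volume_l", "flow_ls"), names(raw))
  if (length(missing_cols) > 0) {
    abort_schema(glue::glue(
      "curve file is missing required column(s): {paste(missing_cols, collapse = ', ')}."
    ))
  }
  flow_volume_curve(raw$time_s, raw$volume_l, raw$flow_ls,
                    check_consistency = check_consistency, flow_tol = flow_tol)
}

#' @rdname read_curve
#' @param curve An `fv_curve` or data frame with `time`, `volume`, `flow`.
#' @export
write_curve <- function(curve, path) {
  curve <- as_fv_curve(curve, check_consistency = FALSE)
  out <- tibble::tibble(time_s = curve$time, volume_l = curve$volume,
                        flow_ls = curve$flow)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
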