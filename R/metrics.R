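# Accuracy metrics for AGB estimation and the spectral-saturation
# diagnostic.

#' Regression accuracy metrics (R2, RMSE, nRMSE)
#'
#' Computes the three standard evaluation metrics with all denominators
#' taken over the measured series:
#' `R2 = 1 - sum((x - y)^2) / sum((x - mean(x))^2)`,
#' `RMSE = sqrt(mean((x - y)^2))` and `nRMSE = RMSE / mean(x) * 100`
#' (percent), where `x` is measured and `y` estimated.
#'
#' @param measured Numeric vector of measured values.
#' @param estimated Numeric vector of estimated values (same length).
#' @return Named list: `R2`, `RMSE`, `nRMSE`.
#' @examples
#' agb_metrics(c(1, 2, 3), c(2, 3, 4))  # RMSE 1, nRMSE 50
#' @export
agb_metrics <- function(measured, estimated) {
  if (length(measured) != length(estimated) || length(measured) < 2L) {
    stop("measured and estimated must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(measured)) || any(!is.finite(estimated))) {
    stop("metrics require finite inputs", call. = FALSE)
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("zero variance in measured values: R2 undefined",
                        call. = FALSE)
  sse <- sum((measured - estimated)^2)
  rmse <- sqrt(sse / length(measured))
  if (mean(measured) == 0) stop("mean of measured values is zero: nRMSE ",
                                "undefined", call. = FALSE)
  list(R2 = 1 - sse / ss_tot,
       RMSE = rmse,
       nRMSE = rmse / mean(measured) * 100)
}

#' Spectral-saturation diagnostic
#'
#' Mean signed residual (measured minus estimated) over the top fraction of
#' the measured distribution. A positive value means the model
#' under-predicts the largest observations — the signature of spectral
#' saturation, where index sensitivity flattens at high biomass.
#'
#' @param measured,estimated Numeric vectors of equal length.
#' @param top_fraction Fraction of rows (by measured value, descending) to
#'   average over; the selected tail must hold at least 3 points.
#' @return Mean signed residual in the tail (same units as `measured`).
#' @export
saturation_diagnostic <- function(measured, estimated, top_fraction = 0.2) {
  if (length(measured) != length(estimated)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  check_number(top_fraction, "top_fraction", lower = 1e-9, upper = 1)
  k <- ceiling(top_fraction * length(measured))
  if (k < 3L) stop("top fraction holds fewer than 3 points", call. = FALSE)
  idx <- order(measured, decreasing = TRUE)[seq_len(k)]
  mean(measured[idx] - estimated[idx])
}
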