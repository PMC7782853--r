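#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR = glucose (mg/dL) x insulin (uU/mL) / 405.
#'
#' @param glucose_mgdl fasting glucose in mg/dL (non-negative).
#' @param insulin_uUml fasting insulin in uU/mL (non-negative).
#' @return HOMA-IR index (vectorized).
#' @export
homa_ir <- function(glucose_mgdl, insulin_uUml) {
  if (any(glucose_mgdl < 0) || any(insulin_uUml < 0))
    stop("glucose and insulin must be non-negative")
  glucose_mgdl * insulin_uUml / 405
}

#' Homeostatic model assessment of beta-cell function (HOMA-B)
#'
#' HOMA-B = 360 x insulin (uU/mL) / (glucose (mg/dL) - 63), in percent.
#' Undefined for glucose <= 63 mg/dL (hypoglycemic range).
#'
#' @inheritParams homa_ir
#' @return HOMA-B in percent (vectorized).
#' @export
homa_b <- function(glucose_mgdl, insulin_uUml) {
  if (any(insulin_uUml < 0)) stop("insulin must be non-negative")
  if (any(glucose_mgdl <= 63))
    stop("HOMA-B undefined for glucose <= 63 mg/dL")
  360 * insulin_uUml / (glucose_mgdl - 63)
}

#' Area under the glucose tolerance test curve
#'
#' Trapezoidal area of blood glucose over the measured interval of an
#' intraperitoneal glucose tolerance test (default sampling at 0, 15, 30,
#' 60 and 120 min).
#'
#' @param glucose blood glucose (mg/dL) at each time point.
#' @param times_min measurement times in minutes, strictly increasing.
#' @return area in mg/dL x min.
#' @export
gtt_auc <- function(glucose, times_min = c(0, 15, 30, 60, 120)) {
  if (length(glucose) != length(times_min))
    stop("glucose and times_min must have the same length")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  pracma::trapz(times_min, glucose)
}
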