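#' Mono-exponential time-activity fit through two points
#'
#' With two post-therapy scans the time-activity curve is modelled as
#' `A(t) = A0 * exp(-lambda * t)` fitted exactly through the two samples:
#' `lambda = ln(a1 / a2) / (t2 - t1)`, `A0 = a1 * exp(lambda * t1)`.
#' Non-decaying pairs (a2 >= a1) are rejected as a non-physical effective
#' half-life.
#'
#' @param times_h two acquisition times (h).
#' @param activities_bq two measured activities (Bq).
#' @return An object of class `tac_fit` with `A0_bq`, `lambda_per_h`,
#'   `half_life_h` and the input samples.
#' @export
fit_monoexp_tac <- function(times_h, activities_bq) {
  if (length(times_h) != 2 || length(activities_bq) != 2)
    stop("exactly two time points are required")
  if (times_h[1] == times_h[2]) stop("time points must be distinct")
  if (any(activities_bq <= 0)) stop("activities must be positive")
  o <- order(times_h)
  t1 <- times_h[o[1]]; t2 <- times_h[o[2]]
  a1 <- activities_bq[o[1]]; a2 <- activities_bq[o[2]]
  if (a2 >= a1)
    stop("non-physical effective half-life: activity does not decay between scans")
  lambda <- log(a1 / a2) / (t2 - t1)
  A0 <- a1 * exp(lambda * t1)
  structure(list(A0_bq = A0, lambda_per_h = lambda,
                 half_life_h = log(2) / lambda,
                 times_h = c(t1, t2), activities_bq = c(a1, a2)),
            class = "tac_fit")
}

#' Time-integrated activity
#'
#' Integral of the fitted mono-exponential from 0 to infinity:
#' `TIA = A0 / lambda`, returned in Bq*s (lambda is per hour).
#'
#' @param fit a [fit_monoexp_tac()] result.
#' @return TIA in Bq*s.
#' @export
time_integrated_activity <- function(fit) {
  stopifnot(inherits(fit, "tac_fit"))
  if (fit$lambda_per_h <= 0) stop("lambda must be positive for a finite TIA")
  fit$A0_bq / fit$lambda_per_h * 3600
}

#' RBE-weighted absorbed dose (MIRD formalism)
#'
#' `dose = RBE * TIA * S`, with the S-value supplied as configuration (e.g.
#' a published whole-decay-chain value for the region mass); local energy
#' deposition of all daughters is assumed.
#'
#' @param tia_bq_s time-integrated activity (Bq*s).
#' @param s_value_gy_per_bq_s S-value (Gy per Bq*s).
#' @param rbe relative biological effectiveness (default 5).
#' @return RBE-weighted absorbed dose (Gy).
#' @export
absorbed_dose <- function(tia_bq_s, s_value_gy_per_bq_s, rbe = 5) {
  if (tia_bq_s < 0 || s_value_gy_per_bq_s < 0 || rbe < 0)
    stop("tia, s_value and rbe must be non-negative")
  rbe * tia_bq_s * s_value_gy_per_bq_s
}

#' Total activity in a region
#'
#' Sum of concentration times voxel volume over a mask, for a calibrated
#' image in Bq/ml.
#'
#' @param image_bq_ml calibrated `volume_image` (Bq/ml).
#' @param mask logical array.
#' @return activity (Bq).
#' @export
region_activity <- function(image_bq_ml, mask) {
  stopifnot(is_volume(image_bq_ml))
  if (!any(mask)) stop("empty region mask")
  sum(image_bq_ml$data[mask]) * voxel_volume_ml(image_bq_ml)
}

#' Assemble a dose record
#'
#' @param region region name.
#' @param window energy-window label.
#' @param fit a [fit_monoexp_tac()] result.
#' @param s_value_gy_per_bq_s S-value (Gy per Bq*s).
#' @param rbe relative biological effectiveness.
#' @return one-row data.frame with the TAC parameters, TIA, S-value, RBE and
#'   RBE-weighted dose.
#' @export
dose_record <- function(region, window, fit, s_value_gy_per_bq_s, rbe = 5) {
  tia <- time_integrated_activity(fit)
  data.frame(region = region, window = window,
             A1_bq = fit$activities_bq[1], A2_bq = fit$activities_bq[2],
             lambda_per_h = fit$lambda_per_h, tia_bq_s = tia,
             s_value_gy_per_bq_s = s_value_gy_per_bq_s, rbe = rbe,
             dose_gy = absorbed_dose(tia, s_value_gy_per_bq_s, rbe))
}
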