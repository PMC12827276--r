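#' Cortical surface irradiance from a bench power measurement
#'
#' Converts the optical power measured on the laboratory power meter to the
#' irradiance delivered at the cortical surface:
#' CSI = (P / DSF) * 4 BSF / (pi d^2),
#' where DSF is the detector scale factor (fraction of emitted power reaching
#' the meter), BSF the brain scale factor (fraction entering tissue) and d
#' the illuminated spot diameter on the cortical surface.
#'
#' @param measured_power_mW measured optical power, mW (>= 0).
#' @param dsf,bsf scale factors in (0, 1\].
#' @param d_mm spot diameter, mm (> 0). Defaults: 0.530 (acute, with
#'   cortical window) or 0.270 (chronic) via [spot_diameter_default()].
#' @return Cortical surface irradiance, mW mm^-2.
#' @export
csi_from_power <- function(measured_power_mW, dsf, bsf, d_mm) {
  if (!is.finite(dsf) || dsf <= 0 || dsf > 1) stop("DSF must lie in (0, 1]")
  if (!is.finite(bsf) || bsf <= 0 || bsf > 1) stop("BSF must lie in (0, 1]")
  if (!is.finite(d_mm) || d_mm <= 0) stop("spot diameter must be > 0")
  stopifnot(all(measured_power_mW >= 0))
  (measured_power_mW / dsf) * 4 * bsf / (pi * d_mm^2)
}

#' Default cortical spot diameters
#'
#' @param scene `"acute"` (with cortical window) or `"chronic"`.
#' @return Spot diameter, mm.
#' @export
spot_diameter_default <- function(scene = c("acute", "chronic")) {
  switch(match.arg(scene), acute = 0.530, chronic = 0.270)
}

#' Fit a current-to-irradiance curve for one micro-LED
#'
#' Least-squares second-order polynomial of cortical surface irradiance
#' against drive current, the per-LED regression used to normalise optical
#' output across the array despite fabrication variability.
#'
#' @param samples data.frame with columns `current_mA` and either `csi`
#'   (mW mm^-2) or `power_mW` (converted through `consts`).
#' @param consts optional list with `dsf`, `bsf`, `d_mm` to convert measured
#'   power into irradiance first.
#' @return Object of class `li_curve`: coefficients (c0, c1, c2), the fitted
#'   current range, and a `monotone` flag over that range.
#' @export
fit_li <- function(samples, consts = NULL) {
  if (nrow(samples) < 3)
    stop("at least 3 samples are required for a quadratic fit")
  x <- samples$current_mA
  y <- if ("csi" %in% names(samples)) samples$csi
       else csi_from_power(samples$power_mW, consts$dsf, consts$bsf, consts$d_mm)
  if (any(y < 0)) stop("irradiance samples must be >= 0")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  rng <- range(x)
  deriv_ends <- cf[2] + 2 * cf[3] * rng
  structure(list(coef = cf, range = rng,
                 monotone = all(deriv_ends >= -1e-9),
                 csi_max = max(cf[1] + cf[2] * rng[2] + cf[3] * rng[2]^2, 0)),
            class = "li_curve")
}

# evaluate a fitted L-I curve
predict_li <- function(curve, current_mA) {
  cf <- curve$coef
  cf[1] + cf[2] * current_mA + cf[3] * current_mA^2
}

#' Drive current needed for a target irradiance
#'
#' Inverts the fitted quadratic by root-finding on the fitted current range,
#' returning the smallest valid root.  LEDs whose fitted curve cannot reach
#' the target within the calibrated range are flagged as having insufficient
#' power (`NA` with attribute `reason`), mirroring the exclusion of
#' non-functional or under-powered LEDs.
#'
#' @param curve an `li_curve`.
#' @param target_csi desired cortical surface irradiance, mW mm^-2.
#' @return Drive current in mA, or `NA` (attribute `reason =
#'   "insufficient_power"`) when the target exceeds the fitted range.
#' @export
invert_for_current <- function(curve, target_csi) {
  stopifnot(inherits(curve, "li_curve"), target_csi >= 0)
  f <- function(I) predict_li(curve, I) - target_csi
  lo <- curve$range[1]; hi <- curve$range[2]
  if (f(hi) < 0 && f(lo) < 0)
    return(structure(NA_real_, reason = "insufficient_power"))
  # smallest root: scan subintervals for the first sign change
  grid <- seq(lo, hi, length.out = 64)
  fg <- f(grid)
  if (fg[1] >= 0) return(lo)
  i <- which(fg[-1] >= 0 & fg[-length(fg)] < 0)[1]
  if (is.na(i)) return(structure(NA_real_, reason = "insufficient_power"))
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
}

#' Infrared-camera count-to-temperature calibration
#'
#' Second-order polynomial regression of thermocouple temperature against
#' raw camera counts, fitted over a heating/cooling sweep.
#'
#' @param counts raw camera counts.
#' @param temperature_C thermocouple temperature, degrees C.
#' @return Object of class `ir_calibration` with coefficients, residual
#'   standard deviation, and a `predict` function counts -> degrees C.
#' @export
ir_calibration <- function(counts, temperature_C) {
  stopifnot(length(counts) == length(temperature_C))
  if (length(counts) < 3) stop("at least 3 paired samples are required")
  if (stats::sd(counts) == 0)
    stop("degenerate calibration: camera counts are constant")
  fit <- stats::lm(temperature_C ~ counts + I(counts^2))
  cf <- unname(stats::coef(fit))
  # exact input data makes summary.lm warn about a perfect fit
  sm <- suppressWarnings(summary(fit))
  structure(list(coef = cf,
                 sigma = sm$sigma,
                 se = unname(sm$coefficients[, "Std. Error"]),
                 predict = function(x) cf[1] + cf[2] * x + cf[3] * x^2),
            class = "ir_calibration")
}

#' Equivalent in-vivo time of an accelerated soak test
#'
#' Polymer ageing at an elevated bath temperature is mapped to equivalent
#' time at body temperature with the rate-doubling convention
#' factor = base^((T_test - T_ref) / interval); base 2 per 10 degrees C is
#' the common polymer-testing choice and both are configurable.  A
#' measured/assumed acceleration factor can be supplied directly instead.
#'
#' @param duration_h test duration, hours (>= 0).
#' @param t_test_C bath temperature, degrees C.
#' @param t_ref_C reference (body) temperature, degrees C.
#' @param base,interval_C rate-doubling base and temperature interval.
#' @param factor optional explicit acceleration factor overriding the
#'   temperature rule.
#' @return Equivalent duration at `t_ref_C`, hours.
#' @export
accelerated_equivalent_time <- function(duration_h, t_test_C, t_ref_C = 37,
                                        base = 2, interval_C = 10,
                                        factor = NULL) {
  stopifnot(all(duration_h >= 0))
  if (is.null(factor)) {
    stopifnot(base > 0, interval_C > 0)
    factor <- base^((t_test_C - t_ref_C) / interval_C)
  }
  duration_h * factor
}
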