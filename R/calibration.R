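# Calibration models between sensor measurements (x) and reference
# measurements (y): linear y = slope*x + intercept for the heights and the
# projected leaf area, power y = a*x^b + c for total leaf area and volume
# (leaf occlusion makes those saturate as plants grow).  The shipped
# default coefficients were fitted to a 63-plant lettuce reference data
# set and are carried as configuration, not re-derived here.

#' Default calibration models
#'
#' Sensor-to-reference maps for each growth measurement (heights and areas
#' in cm / cm^2, volume in cm^3), plus volume-to-fresh-weight and
#' volume-to-dry-weight biomass models (g).  All were fitted on a lettuce
#' reference data set; treat them as appropriate only for comparable
#' plants and capture setups.
#'
#' @return Named list of [CalibrationModel-class] objects.
#' @examples
#' cal <- defaultCalibrations()
#' applyCalibration(1.252, cal$projectedLeafArea, "inverse")  # 0
#' @export
defaultCalibrations <- function() {
  list(
    relativeHeight = calibrationModel("linear",
      c(slope = 1.002, intercept = -0.7111)),
    absoluteHeightSoil = calibrationModel("linear",
      c(slope = 1.021, intercept = -0.5781)),
    absoluteHeightBottom = calibrationModel("linear",
      c(slope = 0.9409, intercept = 0.2327)),
    totalLeafArea = calibrationModel("power",
      c(a = 44.17, b = 0.4321, c = -268.8)),
    projectedLeafArea = calibrationModel("linear",
      c(slope = 0.788, intercept = 1.252)),
    volume = calibrationModel("power",
      c(a = 4.726, b = 0.5121, c = -3.911)),
    freshWeightFromVolume = calibrationModel("power",
      c(a = 0.1949, b = 1.492, c = 0)),
    dryWeightFromVolume = calibrationModel("power",
      c(a = 0.006076, b = 1.669, c = 0)))
}

#' Apply a calibration model
#'
#' Forward maps a sensor measurement x to the reference scale
#' (`y = slope*x + intercept` or `y = a*x^b + c`); inverse solves the same
#' relation algebraically for x given y, e.g. `x = (y - 1.252) / 0.788`
#' for the projected-area model.
#'
#' @param value input value (x for forward, y for inverse).
#' @param model a [CalibrationModel-class].
#' @param direction `"forward"` (default) or `"inverse"`.
#' @return The mapped value.
#' @export
applyCalibration <- function(value, model, direction = c("forward",
                                                         "inverse")) {
  direction <- match.arg(direction)
  co <- model@coefficients
  if (model@kind == "linear") {
    if (direction == "forward") return(co[["slope"]] * value +
                                         co[["intercept"]])
    if (abs(co[["slope"]]) < 1e-300) stop("linear model is not invertible")
    return((value - co[["intercept"]]) / co[["slope"]])
  }
  if (direction == "forward") return(co[["a"]] * value^co[["b"]] + co[["c"]])
  base <- (value - co[["c"]]) / co[["a"]]
  if (any(base <= 0)) stop("inverse power calibration undefined: (y - c)/a <= 0")
  base^(1 / co[["b"]])
}

#' Fit a calibration model to (x, y) pairs
#'
#' Linear models by ordinary least squares; power models `y = a*x^b + c`
#' by nonlinear least squares initialized from a linear fit in log-log
#' space.
#'
#' @param x,y numeric vectors of sensor and reference measurements; at
#'   least 3 pairs for linear, 4 for power.
#' @param kind `"linear"` or `"power"`.
#' @return A fitted [CalibrationModel-class].
#' @export
fitCalibration <- function(x, y, kind = c("linear", "power")) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  if (kind == "linear") {
    if (length(x) < 3L) stop("linear calibration needs at least 3 pairs")
    fit <- stats::lm(y ~ x)
    return(calibrationModel("linear",
      c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))))
  }
  if (length(x) < 4L) stop("power calibration needs at least 4 pairs")
  if (any(x <= 0)) stop("power calibration requires x > 0")
  # log-log linear initialization with a shift estimate from min(y)
  c0 <- min(y) - 1e-6 - diff(range(y)) * 0.01
  ll <- stats::lm(log(pmax(y - c0, 1e-12)) ~ log(x))
  start <- list(a = exp(unname(coef(ll)[1])), b = unname(coef(ll)[2]),
                c = c0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b + c, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("power calibration did not converge: ",
                             conditionMessage(e)))
  co <- coef(fit)
  calibrationModel("power", c(a = unname(co["a"]), b = unname(co["b"]),
                              c = unname(co["c"])))
}
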