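#' @include AllClasses.R
NULL

#' Simple linear calibration of an RBC spectral parameter against paO2
#'
#' Ordinary least squares of the RBC chemical shift (ppm) or linewidth
#' (Hz) on arterial oxygen partial pressure (mmHg), the per-animal
#' calibration underlying paO2 mapping. With the porcine group means
#' (181.74 mmHg, 208.80 ppm) and (386.13 mmHg, 206.81 ppm) the shift
#' calibration slope is -0.0097 ppm/mmHg (printed as -0.01) and the
#' linewidth slope 0.044 Hz/mmHg (printed as 0.04).
#'
#' @param pao2 numeric paO2 values (mmHg), n >= 3, not constant
#' @param y RBC chemical shift (ppm) or linewidth (Hz)
#' @param response "shift" or "linewidth" (annotation only)
#' @return a \linkS4class{LinearShiftModel}
#' @export
fitSlr <- function(pao2, y, response = c("shift", "linewidth")) {
  response <- match.arg(response)
  stopifnot(length(pao2) == length(y))
  if (length(pao2) < 3) stop("need at least 3 calibration points")
  if (stats::sd(pao2) == 0) stop("paO2 is constant: rank-deficient design")
  fit <- stats::lm(y ~ pao2)
  sm <- summary(fit)
  new("LinearShiftModel",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r2 = sm$r.squared, pSlope = sm$coefficients[2, 4],
      n = length(pao2), response = response)
}

#' Multiple linear paO2 model with shift-linewidth interaction
#'
#' paO2 regressed on RBC chemical shift, RBC linewidth and their product:
#' paO2 = b0 + b1*cs + b2*lw + b3*cs*lw, with per-coefficient two-sided
#' t-test p-values (df = n - 4) and R^2. Voxel-wise inversion always uses
#' these unrounded coefficients; coefficients rounded for display are far
#' too coarse for prediction because the interaction term multiplies large
#' cs*lw products.
#'
#' @param cs RBC chemical shift (ppm)
#' @param lw RBC linewidth (Hz)
#' @param pao2 paO2 (mmHg)
#' @return a \linkS4class{PaO2MlrModel}
#' @export
fitMlr <- function(cs, lw, pao2) {
  n <- length(pao2)
  stopifnot(length(cs) == n, length(lw) == n)
  if (n < 5) stop("need at least 5 points for the interaction model")
  X <- cbind(1, cs, lw, cs * lw)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    bad <- c("intercept", "cs", "lw", "cs:lw")[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(pao2 ~ cs * lw)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  names(cf) <- c("intercept", "cs", "lw", "cs:lw")
  p <- sm$coefficients[, 4]
  names(p) <- names(cf)
  new("PaO2MlrModel", coef = cf, p = p, r2 = sm$r.squared, n = as.integer(n))
}

#' Logarithmic calibration of RBC chemical shift against paO2
#'
#' cs = a * ln(paO2) + b by least squares in the log-transformed
#' predictor; over the 180-390 mmHg span of the two studied oxygen levels
#' it is nearly indistinguishable from the linear calibration, but it
#' captures the curvature seen when lower inspired-oxygen data are added.
#'
#' @param pao2 paO2 values (mmHg), all positive, n >= 3
#' @param cs RBC chemical shift (ppm)
#' @return a \linkS4class{LogShiftModel}
#' @export
fitLogModel <- function(pao2, cs) {
  if (any(pao2 <= 0)) stop("paO2 must be positive for the log model")
  if (length(pao2) < 3) stop("need at least 3 points")
  fit <- stats::lm(cs ~ log(pao2))
  sm <- summary(fit)
  new("LogShiftModel", a = unname(stats::coef(fit)[2]),
      b = unname(stats::coef(fit)[1]), r2 = sm$r.squared,
      n = length(pao2))
}

#' Evaluate a fitted model in the forward direction
#'
#' For a \linkS4class{LinearShiftModel}: predicted shift/linewidth at
#' given paO2. For a \linkS4class{LogShiftModel}: a*ln(paO2) + b.
#'
#' @param model a fitted calibration model
#' @param pao2 paO2 values (mmHg)
#' @return predicted spectral parameter
#' @export
predictShift <- function(model, pao2) {
  if (is(model, "LinearShiftModel"))
    return(model@slope * pao2 + model@intercept)
  if (is(model, "LogShiftModel"))
    return(model@a * log(pao2) + model@b)
  stop("unsupported model class: ", class(model))
}

#' Voxel-wise paO2 prediction maps
#'
#' Inverts a fitted calibration over the masked voxels of a
#' \linkS4class{QuantMaps}. For a simple linear shift (or linewidth)
#' calibration the inversion is algebraic: paO2 = (value - intercept) /
#' slope, identical to re-deriving the published inverse equations with
#' unrounded coefficients. For the multiple linear model the fitted
#' coefficient vector is evaluated on the RBC shift and linewidth maps:
#' paO2 = b0 + b1*cs + b2*lw + b3*cs*lw. For a logarithmic calibration
#' paO2 = exp((cs - b)/a). Voxels outside the mask are NA.
#'
#' @param qm a \linkS4class{QuantMaps}
#' @param model a \linkS4class{LinearShiftModel}, \linkS4class{PaO2MlrModel}
#'   or \linkS4class{LogShiftModel}
#' @return numeric 3D paO2 map (mmHg)
#' @export
predictPao2 <- function(qm, model) {
  cs <- qm@maps$cs_rbc
  lw <- qm@maps$lw_rbc
  if (is(model, "LinearShiftModel")) {
    if (model@slope == 0) stop("zero slope: calibration not invertible")
    src <- if (model@response == "shift") cs else lw
    out <- (src - model@intercept) / model@slope
  } else if (is(model, "PaO2MlrModel")) {
    b <- model@coef
    out <- b[["intercept"]] + b[["cs"]] * cs + b[["lw"]] * lw +
      b[["cs:lw"]] * cs * lw
  } else if (is(model, "LogShiftModel")) {
    if (model@a == 0) stop("zero slope: calibration not invertible")
    out <- exp((cs - model@b) / model@a)
  } else {
    stop("unsupported model class: ", class(model))
  }
  out[!qm@mask] <- NA_real_
  out
}

#' Exponential chemical-shift versus sO2 model
#'
#' Constructor and evaluator for delta(sO2) = alpha*exp(beta*sO2) +
#' delta0. The built-in human whole-blood parameterization is alpha =
#' 9.3e-4 ppm, beta = 8.62, delta0 = 20.4 ppm (shift difference
#' increasing with saturation); porcine data decrease with saturation and
#' are fit with \code{\link{fitExpShiftModel}}.
#'
#' @param alpha,beta,delta0 model parameters
#' @param direction "increasing" or "decreasing"
#' @return an \linkS4class{OxShiftExpModel}
#' @export
expShiftModel <- function(alpha = 9.3e-4, beta = 8.62, delta0 = 20.4,
                          direction = "increasing") {
  new("OxShiftExpModel", alpha = alpha, beta = beta, delta0 = delta0,
      direction = direction)
}

#' @rdname expShiftModel
#' @param so2 hemoglobin oxygen saturation, in [0, 1.1]
#' @param model an \linkS4class{OxShiftExpModel}
#' @return predicted shift (ppm)
#' @export
evalExpShiftModel <- function(so2, model = expShiftModel()) {
  if (any(so2 < 0 | so2 > 1.1))
    stop("sO2 outside the model domain [0, 1.1]")
  model@alpha * exp(model@beta * so2) + model@delta0
}

#' Fit the exponential shift model to sO2 data
#'
#' Nonlinear least squares for delta = alpha*exp(beta*sO2) + delta0; the
#' direction tag is set from the sign of the fitted slope at sO2 = 1.
#'
#' @param so2 saturation values
#' @param shift shift (or shift-difference) values (ppm)
#' @param start optional named start list (alpha, beta, delta0)
#' @return an \linkS4class{OxShiftExpModel}
#' @export
fitExpShiftModel <- function(so2, shift, start = NULL) {
  if (is.null(start)) {
    rng <- range(shift)
    incr <- stats::cor(so2, shift) >= 0
    start <- list(alpha = if (incr) 1e-3 else -1e-3,
                  beta = 8, delta0 = if (incr) rng[1] else rng[2])
  }
  fit <- stats::nls(shift ~ alpha * exp(beta * so2) + delta0,
                    start = start,
                    control = stats::nls.control(maxiter = 1000,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  slope1 <- cf[["alpha"]] * cf[["beta"]] * exp(cf[["beta"]])
  new("OxShiftExpModel", alpha = cf[["alpha"]], beta = cf[["beta"]],
      delta0 = cf[["delta0"]],
      direction = if (slope1 >= 0) "increasing" else "decreasing")
}

#' Species oxygen-hemoglobin dissociation curves
#'
#' Hill-type parameterizations with literature-sourced defaults: human
#' P50 26.8 mmHg with Hill coefficient 2.7 (Severinghaus-type standard
#' curve); porcine P50 33.0 mmHg with Hill coefficient 2.8 (porcine blood
#' has a right-shifted curve). Above about 150 mmHg the two curves are
#' practically identical (both saturated), which is why the two studied
#' oxygen levels probe the flat part of either curve.
#'
#' @param species "human" or "porcine", or "custom" with explicit values
#' @param p50 half-saturation paO2 (mmHg), for species = "custom"
#' @param hill Hill coefficient, for species = "custom"
#' @param citation provenance string for custom curves
#' @return an \linkS4class{OdcModel}
#' @export
odcModel <- function(species = c("porcine", "human", "custom"),
                     p50 = NULL, hill = NULL, citation = NULL) {
  species <- match.arg(species)
  if (species == "human") {
    new("OdcModel", species = "human", p50 = 26.8, hill = 2.7,
        citation = "standard adult human ODC (Severinghaus-type Hill fit)")
  } else if (species == "porcine") {
    new("OdcModel", species = "porcine", p50 = 33.0, hill = 2.8,
        citation = "porcine whole-blood ODC, right-shifted Hill fit")
  } else {
    stopifnot(!is.null(p50), !is.null(hill))
    new("OdcModel", species = "custom", p50 = p50, hill = hill,
        citation = if (is.null(citation)) "user-supplied" else citation)
  }
}

#' Oxygen-hemoglobin dissociation curve
#'
#' Hill function sO2 = paO2^n / (paO2^n + P50^n): monotone increasing,
#' 0.5 at P50, bounded in [0, 1).
#'
#' @param pao2 paO2 values (mmHg), >= 0
#' @param model an \linkS4class{OdcModel}
#' @return sO2 fractions in [0, 1)
#' @export
odc <- function(pao2, model = odcModel("porcine")) {
  stopifnot(all(pao2 >= 0))
  x <- pao2^model@hill
  x / (x + model@p50^model@hill)
}
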