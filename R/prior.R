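#' @include AllClasses.R acquisition.R
NULL

#' Default prior knowledge for the three-peak dissolved-phase model
#'
#' Initial values at the FiO2-conditional whole-lung means of
#' \code{\link{xeDefaults}} with the package's default bounds: chemical
#' shift within +/- 5 ppm of its initial value, linewidth 1-50 Hz for the
#' gas peak and 5-300 Hz for the dissolved peaks, amplitudes bounded below
#' by zero, Lorentzian line shapes for gas and RBC and a Voigt membrane
#' line (Gaussian component bounded 5-200 Hz). Phases are tied to a single
#' shared zero-order term.
#'
#' @param fio2 inspired oxygen fraction with built-in defaults (0.40, 1.00)
#' @param csWindowPpm half-width of the chemical-shift bounds (ppm)
#' @param sharedPhase single shared zero-order phase (default TRUE)
#' @return a \linkS4class{PriorKnowledge}
#' @export
defaultPrior <- function(fio2 = 0.40, csWindowPpm = 5, sharedPhase = TRUE) {
  d <- xeDefaults(fio2)
  cs0 <- unname(d$cs)
  lw0 <- c(d$lw[["gas"]], d$lwLMembrane, d$lw[["rbc"]])
  peaks <- data.frame(
    peak = PEAKS,
    lineshape = c("lorentzian", "voigt", "lorentzian"),
    cs0 = cs0, csMin = cs0 - csWindowPpm, csMax = cs0 + csWindowPpm,
    lw0 = lw0,
    lwMin = c(1, 5, 5), lwMax = c(50, 300, 300),
    lwG0 = c(0, d$lwGMembrane, 0),
    lwGMin = c(0, 5, 0), lwGMax = c(0, 200, 0),
    amp0 = c(1, 1, 1))
  new("PriorKnowledge", peaks = peaks, sharedPhase = sharedPhase,
      optimized = FALSE, warningFlag = FALSE)
}

#' Optimize prior starting values on the mean FID
#'
#' Fits the three-peak model to the average FID (normally the mean over all
#' acquired or voxel FIDs) and replaces the prior's initial amplitudes,
#' chemical shifts and linewidths by the fitted values; bounds are left
#' unchanged. If the fit does not converge, or explains less than 20\% of
#' the signal energy (a pure-noise average), the original prior is
#' returned with its warning flag set.
#'
#' @param meanFid complex vector, the averaged FID
#' @param prior a \linkS4class{PriorKnowledge}
#' @param acq an \linkS4class{XeAcquisition}
#' @return an updated \linkS4class{PriorKnowledge}
#' @export
optimizePrior <- function(meanFid, prior, acq) {
  fit <- fitFidCore(meanFid, prior, acq)
  energyExplained <- 1 - fit$residual^2 / sum(Mod(meanFid)^2)
  if (!fit$converged || !is.finite(energyExplained) ||
      energyExplained < 0.2) {
    prior@warningFlag <- TRUE
    return(prior)
  }
  p <- prior@peaks
  p$amp0 <- fit$amp
  p$cs0 <- pmin(pmax(fit$cs, p$csMin), p$csMax)
  p$lw0 <- pmin(pmax(fit$lw, p$lwMin), p$lwMax)
  p$lwG0[p$lineshape == "voigt"] <- fit$lwG
  prior@peaks <- p
  prior@optimized <- TRUE
  prior@warningFlag <- FALSE
  prior
}
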