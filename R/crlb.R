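#' @include fit.R
NULL

#' Cramer-Rao lower bounds for a voxel fit
#'
#' Inverse Fisher information of the time-domain model at the fitted
#' parameters under complex white noise. For a complex Gaussian likelihood
#' with per-component noise SD sigma the information matrix is
#' Re(J^H J) / sigma^2 with J the complex Jacobian of the model FID, and
#' the bounds are the square roots of the diagonal of its inverse —
#' absolute SDs per parameter. A numerically singular information matrix
#' yields infinite bounds with the \code{singular} flag set.
#'
#' Bounds scale linearly in the noise SD and vanish as it goes to zero.
#'
#' @param fit the \code{core} fit object from \code{\link{fitVoxel}} (or a
#'   \code{fitFidCore} result)
#' @param acq an \linkS4class{XeAcquisition}
#' @param noise a noise estimate from \code{\link{estimateNoise}} (its
#'   \code{sdTime} component is the time-domain SD used here), or a single
#'   number taken directly as the time-domain SD
#' @return list with per-peak numeric vectors \code{amp}, \code{cs} (ppm),
#'   \code{lw} (Hz), \code{phase} (rad), plus \code{singular}
#' @export
computeCrlb <- function(fit, acq, noise) {
  if (is.data.frame(fit)) fit <- attr(fit, "core")
  sdTime <- if (is.list(noise)) noise$sdTime else noise
  lay <- fit$lay
  if (sdTime == 0) {
    z <- rep(0, lay$nPk)
    return(list(amp = z, cs = z, lw = z, phase = z, singular = FALSE))
  }
  t <- (seq_len(acq@nSpectral) - 1) / acq@bandwidth
  m <- fitModelEval(fit$par, lay, t, acq@refFrequency, jacobian = TRUE)
  J <- m$J
  info <- Re(Conj(t(J)) %*% J) / sdTime^2
  nPk <- lay$nPk
  inv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(inv)) {
    infv <- rep(Inf, nPk)
    return(list(amp = infv, cs = infv, lw = infv, phase = infv,
                singular = TRUE))
  }
  sds <- sqrt(pmax(diag(inv), 0))
  phaseSd <- if (lay$nPhi == 1L) rep(sds[lay$iPhi], nPk) else sds[lay$iPhi]
  list(amp = sds[lay$iAmp],
       cs = sds[lay$iCs],        # parameterized in ppm directly
       lw = sds[lay$iLw],
       phase = phaseSd,
       singular = FALSE)
}
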