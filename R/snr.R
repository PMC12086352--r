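#' @include fit.R
NULL

#' Estimate spectral noise in a signal-free window
#'
#' Noise is measured far from the three xenon resonances, by default in
#' the -250 to -150 ppm window, as the standard deviation of the real part
#' of the voxel spectra over all voxels and window bins. The equivalent
#' time-domain SD (used by the Cramer-Rao bounds) follows from the
#' orthonormal zero-filled transform: sdTime = sd / sqrt(nSpectral /
#' nSpectralZf).
#'
#' @param simg a \linkS4class{SpectralImage} in the spectral domain
#' @param window ppm interval (length 2) that must not overlap any peak
#' @param peakPpm resonance positions used for the overlap guard
#' @return list with \code{sd} (spectral, real part), \code{sdTime},
#'   \code{window}
#' @export
estimateNoise <- function(simg, window = c(-250, -150),
                          peakPpm = c(0, 197, 208)) {
  window <- sort(window)
  guard <- 25  # ppm half-width of the peak passbands
  if (any(peakPpm + guard > window[1] & peakPpm - guard < window[2]))
    stop("noise window overlaps a peak passband")
  ppm <- simg@ppm
  sel <- ppm >= window[1] & ppm <= window[2]
  if (!any(sel)) stop("noise window outside the spectral range")
  vals <- Re(simg@data[, , , sel, drop = FALSE])
  sd <- stats::sd(as.vector(vals))
  acq <- simg@acq
  list(sd = sd, sdTime = sd / sqrt(acq@nSpectral / acq@nSpectralZf),
       window = window)
}

#' Per-peak signal-to-noise ratio
#'
#' SNR is the fitted amplitude divided by the spectral noise SD. By
#' default the volume-level definition is used: the mean fitted amplitude
#' over the analysis voxels divided by the noise SD. With
#' \code{perVoxel = TRUE} a per-voxel SNR map per peak is returned
#' instead.
#'
#' @param fit a \linkS4class{VoxelFitVolume}
#' @param noise result of \code{\link{estimateNoise}} (its \code{sd} is
#'   the denominator); zero noise yields infinite SNR
#' @param mask optional logical volume restricting the voxels used
#' @param perVoxel return per-voxel maps instead of volume means
#' @return named numeric of length 3, or a list of 3D maps
#' @export
computeSnr <- function(fit, noise, mask = NULL, perVoxel = FALSE) {
  sel <- fit@fitted
  if (!is.null(mask)) sel <- sel & mask
  if (perVoxel) {
    out <- lapply(seq_along(PEAKS), function(k) {
      m <- fit@amp[, , , k] / noise$sd
      m[!sel] <- NA_real_
      m
    })
    names(out) <- PEAKS
    return(out)
  }
  vapply(seq_along(PEAKS), function(k)
    mean(fit@amp[, , , k][sel], na.rm = TRUE) / noise$sd,
    numeric(1)) |> stats::setNames(PEAKS)
}
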