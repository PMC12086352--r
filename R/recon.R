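#' @include trajectory.R
NULL

#' Reconstruct sampled k-space into a spatial-spectral image
#'
#' Grids the sampled FIDs onto the Cartesian matrix (unsampled locations
#' stay zero), zero-pads spatially by the configured factor, applies an
#' inverse 3D Fourier transform per time point, then zero-fills each voxel
#' FID to the spectral target and Fourier transforms it to a spectrum with
#' the calibrated ppm axis attached.
#'
#' Transforms are orthonormal; the spatially zero-padded image is rescaled
#' by sqrt(padded/native grid size) so voxel amplitudes keep the scale of
#' the native grid (with full sampling and no padding the reconstruction
#' exactly inverts \code{\link{simulateAcquisition}}).
#'
#' @param ksp a \linkS4class{KSpaceMRSI}
#' @param acq an \linkS4class{XeAcquisition}; defaults to the one stored in
#'   \code{ksp}
#' @param spectralTransform return spectra (TRUE, default) or keep the
#'   voxel-domain FIDs in the fourth dimension (FALSE)
#' @return a \linkS4class{SpectralImage}
#' @export
reconstructMRSI <- function(ksp, acq = acquisition(ksp),
                            spectralTransform = TRUE) {
  m <- acq@matrixSize
  loc <- ksp@locations
  if (anyDuplicated(loc)) stop("duplicate k-space locations")
  lo <- -(m %/% 2L); hi <- m - m %/% 2L - 1L
  for (d in 1:3)
    if (any(loc[, d] < lo[d] | loc[, d] > hi[d]))
      stop("k-space location outside the acquisition matrix")
  K <- ksp@fids
  nS <- ncol(K)
  if (nS != acq@nSpectral)
    stop("FID length does not match acquired spectral samples")
  mp <- m * acq@spatialZf
  # centered k indices map to the same (cyclic) array positions on the
  # padded grid, which places the pad at high spatial frequencies
  idx <- cbind(centeredToArray(loc[, 1], mp[1]),
               centeredToArray(loc[, 2], mp[2]),
               centeredToArray(loc[, 3], mp[3]))
  flat <- (idx[, 3] - 1L) * mp[1] * mp[2] + (idx[, 2] - 1L) * mp[1] + idx[, 1]
  vox <- array(0i, c(mp, nS))
  grid <- array(0i, mp)
  for (s in seq_len(nS)) {
    grid[] <- 0i
    grid[flat] <- K[, s]
    vox[, , , s] <- fft(grid, inverse = TRUE) / sqrt(prod(mp)) *
      sqrt(prod(mp) / prod(m))
  }
  if (spectralTransform) {
    nZf <- acq@nSpectralZf
    spec <- array(0i, c(mp, nZf))
    vmat <- matrix(vox, ncol = nS)
    padded <- cbind(vmat, matrix(0i, nrow(vmat), nZf - nS))
    # orthonormal FFT along the spectral axis, fftshifted so the ppm axis
    # of spectralAxis() (DC at bin nZf/2+1) applies
    sp <- t(stats::mvfft(t(padded))) / sqrt(nZf)
    shift <- c((nZf %/% 2L + 1L):nZf, 1L:(nZf %/% 2L))
    sp <- sp[, shift, drop = FALSE]
    spec[] <- sp
    out <- spec
  } else {
    out <- vox
  }
  new("SpectralImage", data = out,
      ppm = if (spectralTransform) spectralAxis(acq)
            else as.numeric(seq_len(dim(out)[4])),  # FID domain: bin index
      voxelSize = voxelSize(acq), acq = acq)
}
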