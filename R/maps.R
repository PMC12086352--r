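#' @include snr.R
NULL

#' Flip-angle and T2* amplitude correction
#'
#' Corrects fitted amplitudes for the differing dissolved/gas excitation
#' flip angles and for T2* decay between excitation and the acquisition
#' window: corrected = amplitude * exp(TE / T2*) / sin(flip), with the gas
#' peak using the gas flip angle and the dissolved peaks the dissolved
#' flip angle. TE and T2* are in ms.
#'
#' @param amp numeric per-peak amplitudes (vector gas/membrane/rbc, or a
#'   4D amplitude array with peaks in the fourth dimension)
#' @param acq an \linkS4class{XeAcquisition}
#' @param t2star numeric(3) per-compartment T2* in ms
#' @return corrected amplitudes, same shape as \code{amp}
#' @examples
#' correctAmplitudes(c(1, 1, 1), XeAcquisition(te = 0),
#'                   t2star = c(14.1, 4.75, 3.98))
#' @export
correctAmplitudes <- function(amp, acq, t2star) {
  if (any(t2star <= 0)) stop("T2* must be positive")
  flips <- c(acq@flipGas, acq@flipDissolved, acq@flipDissolved)
  fac <- exp(acq@te / t2star) / sin(flips * pi / 180)
  if (is.null(dim(amp))) {
    amp * fac
  } else {
    sweep(amp, 4, fac, `*`)
  }
}

#' Gas-signal analysis mask
#'
#' Voxels whose fitted gas amplitude is at least \code{factor} times the
#' mean gas amplitude, the mean being taken over voxels with a converged
#' fit (the field-of-view background would bias a full-volume mean
#' downward). A factor of 0 keeps every voxel with positive gas signal.
#'
#' The mask is monotone in the factor: raising it never adds voxels.
#'
#' @param fit a \linkS4class{VoxelFitVolume}
#' @param factor threshold multiplier (default 0.6)
#' @return logical 3D array
#' @export
buildAnalysisMask <- function(fit, factor = 0.6) {
  gas <- fit@amp[, , , 1]
  base <- fit@fitted & fit@converged
  if (!any(base)) stop("no converged fits to build a mask from")
  meanGas <- mean(gas[base], na.rm = TRUE)
  mask <- array(FALSE, dim(gas))
  if (factor == 0) {
    mask[base] <- gas[base] > 0
  } else {
    mask[base] <- gas[base] >= factor * meanGas
  }
  mask
}

#' Build quantitative gas-exchange maps from voxel fits
#'
#' Computes, inside the analysis mask: flip/T2*-corrected amplitude ratio
#' maps (M:Gas, RBC:Gas, RBC:M), per-peak chemical-shift and linewidth
#' maps, the RBC - membrane chemical-shift difference map, and per-peak
#' SNR. Voxels with a zero corrected gas (or membrane) amplitude are
#' flagged NaN in the affected ratio and excluded from summaries; all
#' maps are NA outside the mask.
#'
#' @param fit a \linkS4class{VoxelFitVolume}
#' @param mask logical volume from \code{\link{buildAnalysisMask}}
#' @param t2star numeric(3) per-compartment T2* (ms) for the correction
#' @param noise optional noise estimate for the SNR slot
#' @param fio2 inspired-oxygen fraction recorded in the object
#' @return a \linkS4class{QuantMaps}
#' @export
makeQuantMaps <- function(fit, mask, t2star, noise = NULL,
                          fio2 = NA_real_) {
  acq <- fit@acq
  ampC <- correctAmplitudes(fit@amp, acq, t2star)
  g <- ampC[, , , 1]; m <- ampC[, , , 2]; r <- ampC[, , , 3]
  div <- function(num, den) {
    out <- num / den
    out[den == 0] <- NaN
    out
  }
  mapList <- list(
    m_gas = div(m, g), rbc_gas = div(r, g), rbc_m = div(r, m),
    cs_gas = fit@cs[, , , 1], cs_membrane = fit@cs[, , , 2],
    cs_rbc = fit@cs[, , , 3],
    lw_gas = fit@lw[, , , 1], lw_membrane = fit@lw[, , , 2],
    lw_rbc = fit@lw[, , , 3],
    cs_rbc_m_diff = fit@cs[, , , 3] - fit@cs[, , , 2],
    amp_gas = ampC[, , , 1], amp_membrane = ampC[, , , 2],
    amp_rbc = ampC[, , , 3])
  mapList <- lapply(mapList, function(x) { x[!mask] <- NA_real_; x })
  snr <- if (is.null(noise)) {
    stats::setNames(rep(NA_real_, 3), PEAKS)
  } else {
    computeSnr(fit, noise, mask = mask)
  }
  new("QuantMaps", maps = mapList, mask = mask, snr = snr,
      voxelSize = voxelSize(acq), fio2 = fio2)
}

#' Whole-volume summary of quantitative maps
#'
#' Mean, SD and voxel count per metric over the mask (non-finite voxels
#' excluded). For the three amplitude-ratio metrics a volume-level ratio
#' computed as the ratio of masked mean corrected amplitudes is also
#' reported (column \code{ratio_of_means}); at low RBC SNR it is the less
#' biased whole-lung statistic (see the methods vignette) and is NA for
#' non-ratio metrics.
#'
#' @param qm a \linkS4class{QuantMaps}
#' @param mask optional logical volume overriding the stored mask
#' @return data.frame with columns metric, mean, sd, n_voxels,
#'   ratio_of_means
#' @export
summarizeMaps <- function(qm, mask = NULL) {
  if (is.null(mask)) mask <- qm@mask
  mm <- qm@maps
  num <- list(m_gas = c("amp_membrane", "amp_gas"),
              rbc_gas = c("amp_rbc", "amp_gas"),
              rbc_m = c("amp_rbc", "amp_membrane"))
  rows <- lapply(names(mm), function(nm) {
    v <- mm[[nm]][mask]
    v <- v[is.finite(v)]
    rom <- NA_real_
    if (nm %in% names(num)) {
      a <- mm[[num[[nm]][1]]][mask]; b <- mm[[num[[nm]][2]]][mask]
      ok <- is.finite(a) & is.finite(b)
      if (any(ok) && sum(b[ok]) != 0) rom <- mean(a[ok]) / mean(b[ok])
    }
    data.frame(metric = nm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_voxels = length(v), ratio_of_means = rom)
  })
  do.call(rbind, rows)
}
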