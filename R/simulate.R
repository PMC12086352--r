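#' @include phantom.R
NULL

# Gaussian time-domain decay coefficient for a Gaussian FWHM lwG (Hz):
# exp(-g * t^2) with g = (pi*lwG)^2 / (4 log 2)
gaussDecayCoef <- function(lwG) (pi * lwG)^2 / (4 * log(2))

#' Simulate a single free-induction decay
#'
#' Time-domain three-compartment (or arbitrary) signal model: each peak
#' contributes amp * sin(flip) * exp(-TE/T2*) * exp(i*phase) *
#' exp(i*2*pi*f*t) * decay(t), where f is the chemical shift converted to
#' Hz by the reference frequency, decay is exponential at rate pi*lw for
#' Lorentzian peaks and additionally Gaussian for the Voigt membrane peak.
#' Complex white noise of standard deviation \code{noiseSd} (per real
#' component, per sample) is added when requested.
#'
#' @param peaks data.frame with columns amp, cs (ppm), lw (Hz), and
#'   optionally lwG (Hz, Gaussian FWHM component; 0 = Lorentzian), phase
#'   (rad), compartment ("gas"/"membrane"/"rbc"), t2star (ms)
#' @param acq an \linkS4class{XeAcquisition}
#' @param nSamples number of complex samples (default: acquired samples)
#' @param noiseSd noise standard deviation per real component (>= 0)
#' @param seed integer seed for the noise draw
#' @param applyExcitation multiply by sin(flip) and exp(-TE/T2*); set FALSE
#'   when \code{amp} is already an observed (raw) amplitude
#' @return complex vector of length \code{nSamples}
#' @examples
#' acq <- XeAcquisition()
#' fid <- simulateFid(data.frame(amp = 1, cs = 206.81, lw = 80), acq,
#'                    applyExcitation = FALSE)
#' @export
simulateFid <- function(peaks, acq, nSamples = acq@nSpectral,
                        noiseSd = 0, seed = NULL,
                        applyExcitation = TRUE) {
  stopifnot(nSamples >= 1)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (acq@bandwidth <= 0) stop("bandwidth must be positive")
  t <- (seq_len(nSamples) - 1) / acq@bandwidth
  sig <- complex(nSamples)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    a <- p$amp
    if (applyExcitation) {
      comp <- if (!is.null(p$compartment)) p$compartment else "rbc"
      flip <- if (identical(comp, "gas")) acq@flipGas else acq@flipDissolved
      a <- a * sin(flip * pi / 180)
      if (!is.null(p$t2star) && is.finite(p$t2star))
        a <- a * exp(-acq@te / p$t2star)
    }
    ph <- if (is.null(p$phase)) 0 else p$phase
    lwG <- if (is.null(p$lwG) || is.na(p$lwG)) 0 else p$lwG
    f <- ppmToHz(p$cs, acq)
    env <- exp(-pi * p$lw * t - gaussDecayCoef(lwG) * t^2)
    sig <- sig + a * exp(1i * (ph + 2 * pi * f * t)) * env
  }
  if (noiseSd > 0) {
    if (!is.null(seed)) {
      rng <- localRNG(seed)
      sig <- sig + rng(function()
        complex(real = stats::rnorm(nSamples, 0, noiseSd),
                imaginary = stats::rnorm(nSamples, 0, noiseSd)))
    } else {
      sig <- sig + complex(real = stats::rnorm(nSamples, 0, noiseSd),
                           imaginary = stats::rnorm(nSamples, 0, noiseSd))
    }
  }
  sig
}

# noiseless per-voxel FID array (nx, ny, nz, nSamples) for a phantom
phantomFidArray <- function(phantom, acq, nSamples = acq@nSpectral) {
  grid <- dim(phantom@lungMask)
  t <- (seq_len(nSamples) - 1) / acq@bandwidth
  out <- array(0i, c(grid, nSamples))
  flips <- c(acq@flipGas, acq@flipDissolved, acq@flipDissolved)
  for (k in 1:3) {
    sel <- which(phantom@amp[, , , k] > 0)
    if (!length(sel)) next
    a <- phantom@amp[, , , k][sel] * sin(flips[k] * pi / 180) *
      exp(-acq@te / phantom@t2star[k])
    f <- ppmToHz(phantom@cs[, , , k][sel], acq)
    lwv <- phantom@lw[, , , k][sel]
    ph <- phantom@phase[, , , k][sel]
    z <- 2i * pi * f - pi * lwv
    E <- exp(outer(z, t))                       # nvox x nSamples
    if (k == 2L) {
      g <- gaussDecayCoef(phantom@lwG[sel])
      E <- E * exp(outer(-g, t^2))
    }
    E <- (a * exp(1i * ph)) * E
    # accumulate into the flattened spatial index
    for (s in seq_len(nSamples))
      out[sel + (s - 1L) * prod(grid)] <-
        out[sel + (s - 1L) * prod(grid)] + E[, s]
  }
  out
}

#' Simulate the spherical-sampled MRSI acquisition
#'
#' For every sampled k-space location the stored FID is the orthonormal 3D
#' discrete Fourier transform, at that location, of the phantom's noiseless
#' per-voxel FIDs, plus independent complex white noise.
#'
#' @param phantom a \linkS4class{PhantomTruth}
#' @param acq an \linkS4class{XeAcquisition}
#' @param pattern a \linkS4class{SamplingPattern}, or "full" for complete
#'   Cartesian sampling
#' @param noiseSd k-space noise SD per real component (see
#'   \code{\link{calibrateNoiseSd}})
#' @param seed integer seed for the noise draw
#' @return a \linkS4class{KSpaceMRSI}
#' @export
simulateAcquisition <- function(phantom, acq, pattern = "full",
                                noiseSd = 0, seed = NULL) {
  grid <- dim(phantom@lungMask)
  stopifnot(identical(as.integer(grid), acq@matrixSize))
  if (identical(pattern, "full")) {
    loc <- as.matrix(expand.grid(kx = centeredIndex(grid[1]),
                                 ky = centeredIndex(grid[2]),
                                 kz = centeredIndex(grid[3])))
    pattern <- new("SamplingPattern", locations = loc,
                   matrixSize = as.integer(grid), ordering = "center-out",
                   boundaryRule = "full")
  }
  loc <- pattern@locations
  if (nrow(loc) == 0L) stop("empty sampling pattern")
  vf <- phantomFidArray(phantom, acq)
  nS <- acq@nSpectral
  idx <- cbind(centeredToArray(loc[, 1], grid[1]),
               centeredToArray(loc[, 2], grid[2]),
               centeredToArray(loc[, 3], grid[3]))
  flat <- (idx[, 3] - 1L) * grid[1] * grid[2] +
    (idx[, 2] - 1L) * grid[1] + idx[, 1]
  K <- matrix(0i, nrow(loc), nS)
  scale <- sqrt(prod(grid))
  for (s in seq_len(nS)) {
    ks <- fft(vf[, , , s]) / scale     # orthonormal forward 3D DFT
    K[, s] <- ks[flat]
  }
  if (noiseSd > 0) {
    drawNoise <- function()
      matrix(complex(real = stats::rnorm(length(K), 0, noiseSd),
                     imaginary = stats::rnorm(length(K), 0, noiseSd)),
             nrow(K), ncol(K))
    K <- K + if (is.null(seed)) drawNoise() else localRNG(seed)(drawNoise)
  }
  new("KSpaceMRSI", locations = loc, fids = K, acq = acq)
}

#' Calibrate k-space noise to a target RBC spectral SNR
#'
#' Computes the k-space noise SD that makes the reconstructed-voxel
#' spectral-domain RBC SNR (fitted amplitude over the SD of the real part
#' of the spectrum in a signal-free window) equal \code{snrRbc} for the
#' mean lung RBC raw amplitude of the phantom. Propagation: k-space noise
#' sd_k becomes voxel time-domain noise sd_k * sqrt(nSampled/nGrid) under
#' the orthonormal reconstruction, and spectral noise
#' sd_t * sqrt(nSpectral/nSpectralZf) after zero-filled orthonormal FFT.
#'
#' @param phantom a \linkS4class{PhantomTruth}
#' @param acq an \linkS4class{XeAcquisition}
#' @param pattern the \linkS4class{SamplingPattern} to be simulated
#' @param snrRbc target RBC SNR (default: the phantom FiO2 default)
#' @return k-space noise SD per real component
#' @export
calibrateNoiseSd <- function(phantom, acq, pattern,
                             snrRbc = xeDefaults(phantom@fio2)$snr[["rbc"]]) {
  rbcRaw <- mean(phantom@amp[, , , 3][phantom@lungMask]) *
    sin(acq@flipDissolved * pi / 180) * exp(-acq@te / phantom@t2star[3])
  sdSpec <- rbcRaw / snrRbc
  sdVox <- sdSpec / sqrt(acq@nSpectral / acq@nSpectralZf)
  nSampled <- if (identical(pattern, "full")) prod(acq@matrixSize)
              else nrow(pattern@locations)
  sdVox / sqrt(nSampled / prod(acq@matrixSize))
}

#' Simulate per-animal arterial blood-gas records
#'
#' Draws animal-level blood-gas and oximetry values from normal
#' distributions with the means and SDs of the porcine study conditions
#' (paO2 181.74 +/- 11.22 mmHg at 40\% and 386.13 +/- 31.65 mmHg at 100\%
#' inspired oxygen, plus pH, pCO2, hematocrit and hemoglobin); sO2 is
#' derived from the drawn paO2 through the porcine oxygen-hemoglobin
#' dissociation curve.
#'
#' @param nAnimals number of animals (>= 1)
#' @param fio2Levels inspired-oxygen fractions; 0.40 and 1.00 have
#'   built-in distributions
#' @param seed integer seed
#' @param sdScale multiplier on every SD (0 = deterministic means)
#' @return data.frame with columns animal, fio2, pao2_mmHg, pco2_mmHg, ph,
#'   so2, hct, hb_mmol_l
#' @export
simulateBloodGas <- function(nAnimals, fio2Levels = c(0.40, 1.00),
                             seed = 1L, sdScale = 1) {
  stopifnot(nAnimals >= 1)
  base <- list(
    "0.4" = list(pao2 = c(181.74, 11.22), pco2 = c(44.03, 1.58),
                 ph = c(7.49, 0.01), hct = c(0.3013, 0.0345),
                 hb = c(6.10, 0.70)),
    "1" = list(pao2 = c(386.13, 31.65), pco2 = c(42.90, 3.15),
               ph = c(7.49, 0.02), hct = c(0.2930, 0.0301),
               hb = c(5.93, 0.63)))
  rng <- localRNG(seed)
  porcine <- odcModel("porcine")
  rows <- list()
  for (fio2 in fio2Levels) {
    key <- as.character(fio2)
    if (!key %in% names(base))
      stop("no built-in blood-gas distribution for FiO2 = ", fio2)
    b <- base[[key]]
    draw <- function(ms) rng(stats::rnorm, nAnimals, ms[1], ms[2] * sdScale)
    pao2 <- draw(b$pao2)
    rows[[key]] <- data.frame(
      animal = seq_len(nAnimals), fio2 = fio2,
      pao2_mmHg = pao2, pco2_mmHg = draw(b$pco2), ph = draw(b$ph),
      so2 = odc(pao2, porcine), hct = draw(b$hct), hb_mmol_l = draw(b$hb))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a ventilation image with a focal defect
#'
#' Builds a ventilation volume proportional to the phantom's gas amplitude
#' with a small noise floor, then suppresses the signal in a contiguous
#' defect region grown around a random lung voxel so that a target
#' fraction of the lung is below the 10\%-of-maximum segmentation
#' threshold. The default defect fraction is drawn from the per-FiO2
#' ventilation-defect-percentage distribution of the study conditions
#' (6.90 +/- 3.90\% at 40\% oxygen, 5.02 +/- 4.34\% at 100\%, truncated
#' at zero).
#'
#' @param phantom a \linkS4class{PhantomTruth}
#' @param seed integer seed
#' @param defectFrac defect fraction of lung voxels in [0, 1); NULL draws
#'   it from the FiO2 default distribution
#' @param noiseRel noise floor relative to the maximum signal
#' @return list: \code{vent} (numeric volume), \code{defectMask},
#'   \code{defectFrac}
#' @export
simulateVentilation <- function(phantom, seed = 1L, defectFrac = NULL,
                                noiseRel = 0.02) {
  rng <- localRNG(seed)
  if (is.null(defectFrac)) {
    d <- xeDefaults(phantom@fio2)
    defectFrac <- max(0, rng(stats::rnorm, 1, d$vdpMean, d$vdpSd) / 100)
  }
  gas <- phantom@amp[, , , 1]
  mask <- phantom@lungMask
  nDefect <- round(defectFrac * sum(mask))
  defect <- array(FALSE, dim(mask))
  if (nDefect > 0) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- idx[rng(sample.int, nrow(idx), 1L), ]
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 +
      (idx[, 3] - ctr[3])^2
    sel <- order(d2)[seq_len(min(nDefect, nrow(idx)))]
    defect[idx[sel, , drop = FALSE]] <- TRUE
  }
  vent <- gas
  vent[defect] <- vent[defect] * 0.02
  mx <- max(vent)
  vent <- vent + array(abs(rng(stats::rnorm, length(vent), 0,
                               noiseRel * mx)), dim(vent))
  list(vent = vent, defectMask = defect,
       defectFrac = if (nDefect > 0) sum(defect) / sum(mask) else 0)
}

#' Simulate lobe-level regional metric data with configurable effects
#'
#' Generates animal-by-lobe-by-oxygen mean values for a set of metrics with
#' additive region effects, oxygen effects and region-by-oxygen
#' interactions on top of animal-level random offsets and residual noise.
#' The default effect pattern mirrors the regional two-way ANOVA findings
#' in healthy porcine lungs: region effects on dissolved-phase ratios,
#' chemical shifts and linewidths; oxygen effects on RBC shift, RBC
#' linewidth and RBC:M; interactions on M:Gas, RBC:Gas, membrane shift and
#' RBC linewidth; and no effects at all on perfusion-like metrics.
#'
#' All values are in units of the residual noise SD, so an effect size of
#' 2 means lobe means are spread over about 2 SDs.
#'
#' @param nAnimals animals per group (paired across oxygen levels)
#' @param metrics data.frame with columns metric, region, oxygen,
#'   interaction (effect magnitudes; 0 = absent); default pattern as above
#' @param seed integer seed
#' @return data.frame with columns animal, fio2, lobe, metric, value
#' @export
simulateRegionalData <- function(nAnimals = 4,
                                 metrics = regionalEffectDefaults(),
                                 seed = 1L) {
  rng <- localRNG(seed)
  lobes <- c("R1", "R2", "R3", "R4", "L1", "L2")
  fio2 <- c(0.40, 1.00)
  out <- list()
  for (i in seq_len(nrow(metrics))) {
    m <- metrics[i, ]
    regionEff <- m$region * seq(-1, 1, length.out = 6)
    oxyEff <- m$oxygen * c(-0.5, 0.5)
    interEff <- m$interaction *
      outer(seq(-0.5, 0.5, length.out = 6), c(-1, 1))
    animalEff <- rng(stats::rnorm, nAnimals, 0, 0.5)
    g <- expand.grid(animal = seq_len(nAnimals), lobe = seq_along(lobes),
                     oxy = seq_along(fio2))
    val <- regionEff[g$lobe] + oxyEff[g$oxy] +
      interEff[cbind(g$lobe, g$oxy)] + animalEff[g$animal] +
      rng(stats::rnorm, nrow(g), 0, 1)
    out[[i]] <- data.frame(animal = g$animal, fio2 = fio2[g$oxy],
                           lobe = lobes[g$lobe], metric = m$metric,
                           value = val)
  }
  do.call(rbind, out)
}

#' Default regional effect pattern
#'
#' @return data.frame of per-metric effect magnitudes used by
#'   \code{\link{simulateRegionalData}}
#' @export
regionalEffectDefaults <- function() {
  data.frame(
    metric = c("m_gas", "rbc_gas", "rbc_m", "cs_gas", "cs_membrane",
               "cs_rbc", "lw_gas", "lw_membrane", "lw_rbc",
               "mtt", "pf", "vd", "fom"),
    region = c(3, 3, 2, 3, 3, 2, 0, 3, 3, 0, 0, 0, 0),
    oxygen = c(0, 0, 2, 1.5, 0, 2, 0, 0, 1.8, 0, 0, 0, 0),
    interaction = c(3.5, 3.5, 0, 0, 3.5, 0, 0, 0, 3.5, 0, 0, 0, 0))
}
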