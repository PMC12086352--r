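#' @include AllGenerics.R
NULL

PEAKS <- c("gas", "membrane", "rbc")

#' Acquisition protocol for dissolved-phase 129Xe MRSI
#'
#' Holds the geometry and timing of the 3D Cartesian MRSI protocol: matrix
#' size, field of view, spectral sampling and zero-filling, bandwidth,
#' repetition/echo time, the dual flip angles of the spectrally selective
#' excitation (dissolved-phase vs. gas-phase passband), the dummy-scan
#' saturation block, the spectrometer reference frequency used for the
#' ppm scale, and the spatial zero-fill factor of the reconstruction.
#'
#' @slot matrixSize integer(3), acquisition matrix (x, y, z)
#' @slot fov numeric(3), field of view in cm
#' @slot nSpectral integer, spectral samples acquired per FID
#' @slot nSpectralZf integer, spectral samples after zero-filling
#' @slot bandwidth numeric, spectral bandwidth in Hz
#' @slot tr numeric, repetition time in ms
#' @slot te numeric, echo time in ms
#' @slot flipDissolved numeric, dissolved-phase flip angle in degrees
#' @slot flipGas numeric, gas-phase flip angle in degrees
#' @slot nDummy integer, number of saturating dummy scans
#' @slot dummyFlip numeric, dummy-scan flip angle in degrees
#' @slot refFrequency numeric, 129Xe reference frequency in MHz (ppm scale)
#' @slot spatialZf integer, spatial zero-fill factor of the reconstruction
#' @export
setClass("XeAcquisition", representation(
  matrixSize = "integer", fov = "numeric",
  nSpectral = "integer", nSpectralZf = "integer",
  bandwidth = "numeric", tr = "numeric", te = "numeric",
  flipDissolved = "numeric", flipGas = "numeric",
  nDummy = "integer", dummyFlip = "numeric",
  refFrequency = "numeric", spatialZf = "integer"))

setValidity("XeAcquisition", function(object) {
  msg <- character()
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 1L))
    msg <- c(msg, "matrixSize must be 3 positive integers")
  if (length(object@fov) != 3L || any(object@fov <= 0))
    msg <- c(msg, "fov must be 3 positive values (cm)")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be positive")
  if (object@nSpectral < 1L) msg <- c(msg, "nSpectral must be >= 1")
  if (object@nSpectralZf < object@nSpectral)
    msg <- c(msg, "spectral zero-fill length must be >= acquired samples")
  if (any(c(object@tr, object@te) < 0)) msg <- c(msg, "tr/te must be >= 0")
  if (object@refFrequency <= 0) msg <- c(msg, "refFrequency must be positive")
  if (object@spatialZf < 1L) msg <- c(msg, "spatialZf must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Cartesian spherical sampling pattern
#'
#' Ordered list of centered integer k-space indices sampled by the
#' center-out spherical trajectory, together with the boundary rule that
#' defines which lattice points belong to the inscribed ellipsoid.
#'
#' @slot locations integer matrix (n x 3) of centered k-space indices
#' @slot matrixSize integer(3) acquisition matrix
#' @slot ordering character, "center-out"
#' @slot boundaryRule character, ellipsoid membership rule
#' @export
setClass("SamplingPattern", representation(
  locations = "matrix", matrixSize = "integer",
  ordering = "character", boundaryRule = "character"))

setValidity("SamplingPattern", function(object) {
  loc <- object@locations
  m <- object@matrixSize
  if (ncol(loc) != 3L) return("locations must have 3 columns")
  if (anyDuplicated(loc)) return("duplicate k-space locations")
  lo <- -(m %/% 2L); hi <- m - m %/% 2L - 1L
  for (d in 1:3)
    if (any(loc[, d] < lo[d] | loc[, d] > hi[d]))
      return("k-space index outside the matrix")
  TRUE
})

#' Sampled k-space MRSI data
#'
#' One complex FID per sampled Cartesian k-space location.
#'
#' @slot locations integer matrix (n x 3) of centered k-space indices
#' @slot fids complex matrix (n x nSpectral)
#' @slot acq the \linkS4class{XeAcquisition} the data were sampled under
#' @export
setClass("KSpaceMRSI", representation(
  locations = "matrix", fids = "matrix", acq = "XeAcquisition"))

setValidity("KSpaceMRSI", function(object) {
  if (nrow(object@locations) != nrow(object@fids))
    return("one FID per location required")
  if (ncol(object@fids) != object@acq@nSpectral)
    return("FID length must equal acquired spectral samples")
  if (!is.complex(object@fids)) return("fids must be complex")
  TRUE
})

#' Reconstructed spatial-spectral image
#'
#' Complex 4D array (three spatial axes and one spectral axis) with a
#' calibrated ppm axis, as produced by \code{\link{reconstructMRSI}}.
#'
#' @slot data complex 4D array (x, y, z, frequency)
#' @slot ppm numeric chemical-shift axis (ppm, gas-referenced)
#' @slot voxelSize numeric(3), reconstructed voxel size in mm
#' @slot acq the source \linkS4class{XeAcquisition}
#' @export
setClass("SpectralImage", representation(
  data = "array", ppm = "numeric", voxelSize = "numeric",
  acq = "XeAcquisition"))

setValidity("SpectralImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (length(object@ppm) != d[4L])
    return("ppm axis length must equal the spectral dimension")
  if (is.unsorted(object@ppm) && is.unsorted(rev(object@ppm)))
    return("ppm axis must be monotone")
  TRUE
})

#' Ground-truth synthetic lung phantom
#'
#' Per-voxel spectral parameters for the three xenon compartments (gas,
#' membrane, RBC) on the acquisition grid, plus lung mask, lobe atlas and
#' the physiological scalars of the simulated animal.
#'
#' Arrays \code{amp}, \code{cs}, \code{lw}, \code{phase} are 4D with the
#' fourth dimension indexing the peaks gas/membrane/rbc; \code{lwG} is the
#' Gaussian FWHM component of the membrane Voigt line.
#'
#' @slot amp numeric 4D array, time-domain signal amplitudes (a.u.)
#' @slot cs numeric 4D array, chemical shifts (ppm, gas-referenced)
#' @slot lw numeric 4D array, Lorentzian FWHM (Hz)
#' @slot lwG numeric 3D array, membrane Gaussian FWHM component (Hz)
#' @slot phase numeric 4D array, per-peak phase (rad)
#' @slot lungMask logical 3D array
#' @slot lobes integer 3D array, lobe labels (0 outside lung)
#' @slot lobeLabels character, label names (R1, R2, R3, R4, L1, L2)
#' @slot t2star numeric(3), per-compartment T2* (ms) for amplitude correction
#' @slot fio2 numeric, inspired oxygen fraction
#' @slot paO2 numeric, arterial oxygen partial pressure (mmHg)
#' @slot sO2 numeric, hemoglobin oxygen saturation (fraction)
#' @export
setClass("PhantomTruth", representation(
  amp = "array", cs = "array", lw = "array", lwG = "array",
  phase = "array", lungMask = "array", lobes = "array",
  lobeLabels = "character", t2star = "numeric",
  fio2 = "numeric", paO2 = "numeric", sO2 = "numeric"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (any(object@amp < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (any(object@lw[object@amp > 0] <= 0))
    msg <- c(msg, "linewidths must be > 0 where signal exists")
  if (any(object@lobes[!object@lungMask] != 0L))
    msg <- c(msg, "lobe labels outside the lung mask")
  dis <- object@amp[, , , 2:3, drop = FALSE]
  out <- !object@lungMask
  if (any(dis[c(out, out)] != 0))
    msg <- c(msg, "dissolved-phase amplitude outside the lung mask")
  if (length(msg)) msg else TRUE
})

#' Prior knowledge for the three-peak spectral model
#'
#' Initial values and bounds for the chemical shift, linewidth and amplitude
#' of the gas, membrane and RBC peaks, plus line-shape assignments
#' (Lorentzian for gas and RBC, Voigt for membrane by default). Phases are
#' tied to a single shared zero-order term unless \code{sharedPhase} is
#' FALSE, in which case each peak carries its own phase.
#'
#' @slot peaks data.frame, one row per peak with columns peak, lineshape,
#'   cs0, csMin, csMax, lw0, lwMin, lwMax, lwG0, lwGMin, lwGMax, amp0
#' @slot sharedPhase logical, single zero-order phase shared by all peaks
#' @slot optimized logical, whether \code{\link{optimizePrior}} has been run
#' @slot warningFlag logical, set when prior optimization failed
#' @export
setClass("PriorKnowledge", representation(
  peaks = "data.frame", sharedPhase = "logical",
  optimized = "logical", warningFlag = "logical"))

setValidity("PriorKnowledge", function(object) {
  p <- object@peaks
  need <- c("peak", "lineshape", "cs0", "csMin", "csMax", "lw0", "lwMin",
            "lwMax", "lwG0", "lwGMin", "lwGMax", "amp0")
  if (!all(need %in% names(p))) return("missing prior-knowledge columns")
  if (!all(p$lineshape %in% c("lorentzian", "voigt")))
    return("lineshape must be 'lorentzian' or 'voigt'")
  if (any(p$cs0 < p$csMin | p$cs0 > p$csMax))
    return("initial chemical shift outside its bounds")
  if (any(p$lw0 < p$lwMin | p$lw0 > p$lwMax))
    return("initial linewidth outside its bounds")
  if (any(p$amp0 < 0)) return("initial amplitudes must be >= 0")
  TRUE
})

#' Per-voxel spectral fit results over a volume
#'
#' Parameter, uncertainty and bookkeeping arrays for the AMARES-style fit of
#' every analysed voxel. 4D arrays carry one plane per peak (gas, membrane,
#' rbc); voxels that were not fit (below the signal screen) hold NA.
#'
#' @slot amp,cs,lw,phase numeric 4D arrays of fitted peak parameters
#' @slot lwG numeric 3D array, fitted membrane Gaussian FWHM (Hz)
#' @slot crlbAmp,crlbCs,crlbLw numeric 4D arrays of Cramer-Rao lower bounds
#' @slot phase0 numeric 3D array, zero-order phase (rad)
#' @slot delay numeric 3D array, first-order phase as a dead-time delay (s)
#' @slot residual numeric 3D array, residual norm
#' @slot converged logical 3D array
#' @slot fitted logical 3D array, whether the voxel was fit at all
#' @slot acq the \linkS4class{XeAcquisition}
#' @slot prior the \linkS4class{PriorKnowledge} used
#' @slot noiseSd numeric, estimated spectral noise SD (a.u.)
#' @export
setClass("VoxelFitVolume", representation(
  amp = "array", cs = "array", lw = "array", phase = "array",
  lwG = "array", crlbAmp = "array", crlbCs = "array", crlbLw = "array",
  phase0 = "array", delay = "array", residual = "array",
  converged = "array", fitted = "array",
  acq = "XeAcquisition", prior = "PriorKnowledge", noiseSd = "numeric"))

#' Quantitative gas-exchange maps
#'
#' Masked 3D maps derived from corrected voxel fits: compartment amplitude
#' ratios (M:Gas, RBC:Gas, RBC:M), per-peak chemical shift and linewidth,
#' and the RBC - membrane chemical-shift difference, plus per-peak SNR.
#'
#' @slot maps named list of numeric 3D arrays
#' @slot mask logical 3D array, analysis mask
#' @slot snr named numeric, volume-level per-peak SNR
#' @slot voxelSize numeric(3) in mm
#' @slot fio2 numeric, inspired oxygen fraction (NA if unknown)
#' @export
setClass("QuantMaps", representation(
  maps = "list", mask = "array", snr = "numeric",
  voxelSize = "numeric", fio2 = "numeric"))

setValidity("QuantMaps", function(object) {
  d <- dim(object@mask)
  ok <- vapply(object@maps, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) return("all maps must share the mask geometry")
  TRUE
})

#' Simple linear calibration between paO2 and an RBC spectral parameter
#'
#' Ordinary least-squares calibration of the RBC chemical shift (ppm) or
#' linewidth (Hz) against arterial oxygen partial pressure (mmHg).
#'
#' @slot slope,intercept numeric regression coefficients
#' @slot r2 numeric coefficient of determination
#' @slot pSlope numeric two-sided p-value of the slope
#' @slot n integer number of calibration points
#' @slot response character, "shift" or "linewidth"
#' @export
setClass("LinearShiftModel", representation(
  slope = "numeric", intercept = "numeric", r2 = "numeric",
  pSlope = "numeric", n = "integer", response = "character"))

#' Multiple linear paO2 model with shift-linewidth interaction
#'
#' paO2 regressed on RBC chemical shift, RBC linewidth and their product.
#'
#' @slot coef named numeric(4): intercept, cs, lw, cs:lw (mmHg-scaled)
#' @slot p named numeric(4), per-coefficient two-sided p-values
#' @slot r2 numeric
#' @slot n integer
#' @export
setClass("PaO2MlrModel", representation(
  coef = "numeric", p = "numeric", r2 = "numeric", n = "integer"))

#' Logarithmic paO2 calibration
#'
#' RBC chemical shift modelled as a + b is reversed: cs = a*ln(paO2) + b.
#'
#' @slot a,b numeric coefficients
#' @slot r2 numeric
#' @slot n integer
#' @export
setClass("LogShiftModel", representation(
  a = "numeric", b = "numeric", r2 = "numeric", n = "integer"))

#' Exponential chemical-shift versus oxygen-saturation model
#'
#' delta(sO2) = alpha * exp(beta * sO2) + delta0, the in-vitro whole-blood
#' relationship between the RBC-membrane shift difference and hemoglobin
#' oxygen saturation. The human curve increases with sO2; the porcine RBC
#' shift decreases, tracked by the direction tag.
#'
#' @slot alpha numeric (ppm)
#' @slot beta numeric (dimensionless growth factor)
#' @slot delta0 numeric (ppm)
#' @slot direction character, "increasing" (human) or "decreasing" (porcine)
#' @export
setClass("OxShiftExpModel", representation(
  alpha = "numeric", beta = "numeric", delta0 = "numeric",
  direction = "character"))

#' Hill-type oxygen-hemoglobin dissociation curve
#'
#' sO2 = paO2^n / (paO2^n + P50^n) with species-specific P50 and Hill
#' coefficient.
#'
#' @slot species character
#' @slot p50 numeric, paO2 at half saturation (mmHg)
#' @slot hill numeric, Hill coefficient
#' @slot citation character, source of the parameter values
#' @export
setClass("OdcModel", representation(
  species = "character", p50 = "numeric", hill = "numeric",
  citation = "character"))

setValidity("OdcModel", function(object) {
  if (object@p50 <= 0 || object@hill <= 0)
    return("P50 and Hill coefficient must be positive")
  TRUE
})

## ---- accessors ----

#' @rdname kLocations
#' @export
setMethod("kLocations", "SamplingPattern", function(object) object@locations)

#' @rdname kLocations
#' @export
setMethod("kLocations", "KSpaceMRSI", function(object) object@locations)

#' @rdname fids
#' @export
setMethod("fids", "KSpaceMRSI", function(object) object@fids)

#' @rdname acquisition
#' @export
setMethod("acquisition", "KSpaceMRSI", function(object) object@acq)

#' @rdname acquisition
#' @export
setMethod("acquisition", "SpectralImage", function(object) object@acq)

#' @rdname acquisition
#' @export
setMethod("acquisition", "VoxelFitVolume", function(object) object@acq)

#' @rdname ppmAxis
#' @export
setMethod("ppmAxis", "SpectralImage", function(object) object@ppm)

#' @rdname imageData
#' @export
setMethod("imageData", "SpectralImage", function(object) object@data)

#' @rdname maps
#' @export
setMethod("maps", "QuantMaps", function(object) object@maps)

#' @rdname analysisMask
#' @export
setMethod("analysisMask", "QuantMaps", function(object) object@mask)

#' @rdname analysisMask
#' @export
setMethod("analysisMask", "PhantomTruth",
          function(object) object@lungMask)

#' @rdname peakTable
#' @export
setMethod("peakTable", "PriorKnowledge", function(object) object@peaks)

#' @rdname modelCoef
#' @export
setMethod("modelCoef", "LinearShiftModel", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' @rdname modelCoef
#' @export
setMethod("modelCoef", "PaO2MlrModel", function(object, ...) object@coef)

#' @rdname modelCoef
#' @export
setMethod("modelCoef", "LogShiftModel", function(object, ...)
  c(a = object@a, b = object@b))

## ---- show methods ----

setMethod("show", "XeAcquisition", function(object) {
  cat("XeAcquisition:",
      paste(object@matrixSize, collapse = " x "), "matrix,",
      paste(object@fov, collapse = " x "), "cm FOV\n")
  cat(sprintf("  %d spectral samples (zero-filled to %d) @ %.0f Hz, %.2f MHz ref\n",
              object@nSpectral, object@nSpectralZf, object@bandwidth,
              object@refFrequency))
  cat(sprintf("  TR %.1f ms, TE %.2f ms, flips %.1f/%.2f deg (dissolved/gas)\n",
              object@tr, object@te, object@flipDissolved, object@flipGas))
})

setMethod("show", "SamplingPattern", function(object) {
  cat(sprintf("SamplingPattern: %d locations on %s (%s, %s)\n",
              nrow(object@locations),
              paste(object@matrixSize, collapse = "x"),
              object@ordering, object@boundaryRule))
})

setMethod("show", "KSpaceMRSI", function(object) {
  cat(sprintf("KSpaceMRSI: %d FIDs x %d samples\n",
              nrow(object@fids), ncol(object@fids)))
})

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralImage: %d x %d x %d voxels x %d spectral bins (%.2f..%.2f ppm)\n",
              d[1], d[2], d[3], d[4], min(object@ppm), max(object@ppm)))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %s grid, FiO2 %.2f, %d lung voxels, paO2 %.1f mmHg\n",
              paste(dim(object@lungMask), collapse = "x"), object@fio2,
              sum(object@lungMask), object@paO2))
})

setMethod("show", "PriorKnowledge", function(object) {
  cat("PriorKnowledge", if (object@optimized) "(optimized)" else "", "\n")
  print(object@peaks[, c("peak", "lineshape", "cs0", "lw0", "amp0")])
})

setMethod("show", "VoxelFitVolume", function(object) {
  cat(sprintf("VoxelFitVolume: %s grid, %d voxels fit (%d converged)\n",
              paste(dim(object@fitted), collapse = "x"),
              sum(object@fitted), sum(object@converged, na.rm = TRUE)))
})

setMethod("show", "QuantMaps", function(object) {
  cat(sprintf("QuantMaps: %s grid, %d masked voxels\n  maps: %s\n",
              paste(dim(object@mask), collapse = "x"), sum(object@mask),
              paste(names(object@maps), collapse = ", ")))
})

setMethod("show", "LinearShiftModel", function(object) {
  cat(sprintf("LinearShiftModel (%s): y = %.5g * paO2 + %.5g  (R2 %.3f, p %.3g, n %d)\n",
              object@response, object@slope, object@intercept, object@r2,
              object@pSlope, object@n))
})

setMethod("show", "PaO2MlrModel", function(object) {
  cat("PaO2MlrModel: paO2 ~ cs + lw + cs:lw\n")
  print(round(object@coef, 4))
  cat(sprintf("  R2 %.4f, n %d\n", object@r2, object@n))
})

setMethod("show", "OxShiftExpModel", function(object) {
  cat(sprintf("OxShiftExpModel (%s): delta = %.3g * exp(%.3g * sO2) + %.4g ppm\n",
              object@direction, object@alpha, object@beta, object@delta0))
})

setMethod("show", "OdcModel", function(object) {
  cat(sprintf("OdcModel (%s): P50 %.1f mmHg, Hill %.2f [%s]\n",
              object@species, object@p50, object@hill, object@citation))
})
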