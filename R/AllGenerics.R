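#' @import methods
NULL

#' Sampled k-space locations
#'
#' Accessor for the ordered list of centered integer k-space indices of a
#' \linkS4class{SamplingPattern} or \linkS4class{KSpaceMRSI} object.
#'
#' @param object a \linkS4class{SamplingPattern} or \linkS4class{KSpaceMRSI}
#' @return integer matrix with one row per sampled location (columns kx, ky, kz)
#' @export
setGeneric("kLocations", function(object) standardGeneric("kLocations"))

#' Free-induction-decay matrix
#'
#' @param object a \linkS4class{KSpaceMRSI}
#' @return complex matrix, one row per sampled k-space location
#' @export
setGeneric("fids", function(object) standardGeneric("fids"))

#' Acquisition settings attached to an object
#'
#' @param object an object carrying a \linkS4class{XeAcquisition}
#' @return the \linkS4class{XeAcquisition}
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' Chemical-shift axis of a reconstructed spectral image
#'
#' @param object a \linkS4class{SpectralImage}
#' @return numeric vector of ppm values, one per spectral bin
#' @export
setGeneric("ppmAxis", function(object) standardGeneric("ppmAxis"))

#' Raw array data
#'
#' @param object a \linkS4class{SpectralImage}
#' @return the complex 4D (x, y, z, frequency) array
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' Named list of quantitative 3D maps
#'
#' @param object a \linkS4class{QuantMaps}
#' @return named list of numeric 3D arrays
#' @export
setGeneric("maps", function(object) standardGeneric("maps"))

#' Analysis mask
#'
#' @param object a \linkS4class{QuantMaps} or \linkS4class{PhantomTruth}
#' @return logical 3D array
#' @export
setGeneric("analysisMask", function(object) standardGeneric("analysisMask"))

#' Per-peak prior-knowledge table
#'
#' @param object a \linkS4class{PriorKnowledge}
#' @return data.frame with one row per spectral peak
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' Model coefficients
#'
#' @param object a fitted model object from this package
#' @param ... unused
#' @return named numeric vector of coefficients
#' @export
setGeneric("modelCoef", function(object, ...) standardGeneric("modelCoef"))
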