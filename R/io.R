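#' @include regional.R oxygen.R
NULL

#' Write / read a 3D volume as NIfTI
#'
#' Volumes are written in RAS orientation with the voxel size recorded in
#' the header; logical and integer volumes round-trip through the nearest
#' integer. Non-finite voxels serialize as NaN.
#'
#' @param vol numeric/integer/logical 3D array
#' @param path output .nii or .nii.gz path
#' @param voxelSize numeric(3) voxel edge lengths in mm
#' @return \code{path}, invisibly
#' @export
writeVolume <- function(vol, path, voxelSize = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @return for \code{readVolume}: the array with a "voxelSize" attribute
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxelSize") <- RNifti::pixdim(img)[1:3]
  out
}

#' Blood-gas table I/O
#'
#' CSV with header animal,fio2,pao2_mmHg,pco2_mmHg,ph,so2,hct,hb_mmol_l.
#'
#' @param bg data.frame as produced by \code{\link{simulateBloodGas}}
#' @param path CSV path
#' @return the path (write) or the data.frame (read)
#' @export
writeBloodGas <- function(bg, path) {
  need <- c("animal", "fio2", "pao2_mmHg", "pco2_mmHg", "ph", "so2",
            "hct", "hb_mmol_l")
  stopifnot(all(need %in% names(bg)))
  utils::write.csv(bg[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBloodGas
#' @export
readBloodGas <- function(path) {
  bg <- utils::read.csv(path)
  need <- c("animal", "fio2", "pao2_mmHg", "so2")
  if (!all(need %in% names(bg)))
    stop("malformed blood-gas table: missing column(s) ",
         paste(setdiff(need, names(bg)), collapse = ", "))
  bg
}

acqToList <- function(acq) {
  list(matrixSize = acq@matrixSize, fov = acq@fov,
       nSpectral = acq@nSpectral, nSpectralZf = acq@nSpectralZf,
       bandwidth = acq@bandwidth, tr = acq@tr, te = acq@te,
       flipDissolved = acq@flipDissolved, flipGas = acq@flipGas,
       nDummy = acq@nDummy, dummyFlip = acq@dummyFlip,
       refFrequency = acq@refFrequency, spatialZf = acq@spatialZf)
}

listToAcq <- function(x) {
  do.call(XeAcquisition, x[intersect(names(x), names(formals(XeAcquisition)))])
}

#' Acquisition configuration I/O (JSON)
#'
#' @param acq an \linkS4class{XeAcquisition}
#' @param path JSON path
#' @return path (write) / \linkS4class{XeAcquisition} (read)
#' @export
writeAcquisition <- function(acq, path) {
  jsonlite::write_json(acqToList(acq), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeAcquisition
#' @export
readAcquisition <- function(path) {
  listToAcq(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' k-space MRSI container I/O
#'
#' A \linkS4class{KSpaceMRSI} is stored as a self-describing directory:
#' \code{locations.csv} (centered integer indices, one row per excitation,
#' in acquisition order), \code{fids_re.csv} / \code{fids_im.csv} (real
#' and imaginary FID samples, one row per excitation) and
#' \code{meta.json} holding the acquisition attributes and the index
#' convention.
#'
#' @param ksp a \linkS4class{KSpaceMRSI}
#' @param dir directory to create/fill
#' @return dir (write) / \linkS4class{KSpaceMRSI} (read)
#' @export
writeKSpace <- function(ksp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  loc <- as.data.frame(ksp@locations)
  names(loc) <- c("kx", "ky", "kz")
  utils::write.csv(loc, file.path(dir, "locations.csv"), row.names = FALSE)
  utils::write.table(Re(ksp@fids), file.path(dir, "fids_re.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(ksp@fids), file.path(dir, "fids_im.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- c(acqToList(ksp@acq),
            list(indexConvention = "centered; DC at 0; even axes -N/2..N/2-1",
                 nLocations = nrow(ksp@locations)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname writeKSpace
#' @export
readKSpace <- function(dir) {
  files <- file.path(dir, c("locations.csv", "fids_re.csv", "fids_im.csv",
                            "meta.json"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("malformed k-space container, missing: ",
         paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  loc <- as.matrix(utils::read.csv(files[1]))
  re <- as.matrix(utils::read.csv(files[2], header = FALSE))
  im <- as.matrix(utils::read.csv(files[3], header = FALSE))
  if (!identical(dim(re), dim(im)) || nrow(re) != nrow(loc))
    stop("malformed k-space container: inconsistent dimensions at ", dir)
  if (!is.null(meta$nLocations) && meta$nLocations != nrow(loc))
    stop("malformed k-space container: location count mismatch (meta says ",
         meta$nLocations, ", file has ", nrow(loc), ")")
  fids <- matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
  dimnames(loc) <- list(NULL, c("kx", "ky", "kz"))
  new("KSpaceMRSI", locations = loc, fids = fids, acq = listToAcq(meta))
}

#' Prior-knowledge I/O (JSON)
#'
#' Open-format serialization of a \linkS4class{PriorKnowledge}: the
#' per-peak table plus the phase-sharing flag.
#'
#' @param prior a \linkS4class{PriorKnowledge}
#' @param path JSON path
#' @return path (write) / \linkS4class{PriorKnowledge} (read)
#' @export
writePrior <- function(prior, path) {
  jsonlite::write_json(list(peaks = prior@peaks,
                            sharedPhase = prior@sharedPhase,
                            optimized = prior@optimized),
                       path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writePrior
#' @export
readPrior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$peaks)) stop("malformed prior file: no 'peaks' table in ", path)
  new("PriorKnowledge", peaks = as.data.frame(x$peaks),
      sharedPhase = isTRUE(x$sharedPhase),
      optimized = isTRUE(x$optimized), warningFlag = FALSE)
}

#' Oxygenation-model I/O (JSON)
#'
#' Serializes any of the oxygenation model classes with their class name,
#' coefficients and fit statistics.
#'
#' @param model a model object
#' @param path JSON path
#' @return path (write) / the model (read)
#' @export
writeModel <- function(model, path) {
  sl <- attributes(model)
  sl$class <- NULL
  out <- list(class = as.character(class(model)), slots = sl)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$class)) stop("malformed model file: ", path)
  sl <- x$slots
  cls <- x$class
  proto <- getSlots(cls)
  args <- lapply(names(proto), function(nm) {
    v <- sl[[nm]]
    if (proto[nm] == "integer") as.integer(v) else v
  })
  names(args) <- names(proto)
  do.call(new, c(list(cls), args))
}

#' Phantom truth I/O
#'
#' One NIfTI per parameter map (amplitude, shift, linewidth per peak, the
#' lung mask and lobe atlas) plus a JSON sidecar with the scalar
#' metadata.
#'
#' @param phantom a \linkS4class{PhantomTruth}
#' @param dir output directory
#' @param acq acquisition used for the voxel size in the headers
#' @return dir (write) / \linkS4class{PhantomTruth} (read)
#' @export
writePhantom <- function(phantom, dir, acq = XeAcquisition(spatialZf = 1L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- 10 * acq@fov / acq@matrixSize
  for (k in 1:3) {
    pk <- PEAKS[k]
    writeVolume(phantom@amp[, , , k], file.path(dir, paste0("amp_", pk, ".nii.gz")), vs)
    writeVolume(phantom@cs[, , , k], file.path(dir, paste0("cs_", pk, ".nii.gz")), vs)
    writeVolume(phantom@lw[, , , k], file.path(dir, paste0("lw_", pk, ".nii.gz")), vs)
    writeVolume(phantom@phase[, , , k], file.path(dir, paste0("phase_", pk, ".nii.gz")), vs)
  }
  writeVolume(phantom@lwG, file.path(dir, "lwG_membrane.nii.gz"), vs)
  writeVolume(phantom@lungMask, file.path(dir, "lung_mask.nii.gz"), vs)
  writeVolume(phantom@lobes, file.path(dir, "lobes.nii.gz"), vs)
  jsonlite::write_json(
    list(lobeLabels = phantom@lobeLabels, t2star = phantom@t2star,
         fio2 = phantom@fio2, paO2 = phantom@paO2, sO2 = phantom@sO2),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE)
  invisible(dir)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  rd <- function(nm) readVolume(file.path(dir, paste0(nm, ".nii.gz")))
  mask <- rd("lung_mask")
  grid <- dim(mask)
  arr4 <- function(stem) {
    a <- array(0, c(grid, 3))
    for (k in 1:3) a[, , , k] <- rd(paste0(stem, "_", PEAKS[k]))
    a
  }
  new("PhantomTruth", amp = arr4("amp"), cs = arr4("cs"), lw = arr4("lw"),
      lwG = rd("lwG_membrane"), phase = arr4("phase"),
      lungMask = array(mask > 0.5, grid),
      lobes = array(as.integer(round(rd("lobes"))), grid),
      lobeLabels = meta$lobeLabels, t2star = meta$t2star,
      fio2 = meta$fio2, paO2 = meta$paO2, sO2 = meta$sO2)
}

#' Quantitative-map volume I/O
#'
#' One NIfTI per map plus the mask and a JSON sidecar (SNR, FiO2, voxel
#' size). Flagged voxels serialize as NaN.
#'
#' @param qm a \linkS4class{QuantMaps}
#' @param dir output directory
#' @return dir (write) / \linkS4class{QuantMaps} (read)
#' @export
writeQuantMaps <- function(qm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(qm@maps))
    writeVolume(qm@maps[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                qm@voxelSize)
  writeVolume(qm@mask, file.path(dir, "mask.nii.gz"), qm@voxelSize)
  snrOut <- as.list(ifelse(is.finite(qm@snr), qm@snr, NA_real_))
  jsonlite::write_json(list(maps = names(qm@maps), snr = snrOut,
                            fio2 = qm@fio2, voxelSize = qm@voxelSize),
                       file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeQuantMaps
#' @export
readQuantMaps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"),
                              simplifyVector = TRUE)
  mask <- readVolume(file.path(dir, "mask.nii.gz"))
  mapList <- lapply(meta$maps, function(nm)
    readVolume(file.path(dir, paste0(nm, ".nii.gz"))))
  names(mapList) <- meta$maps
  snrIn <- vapply(meta$snr, function(x)
    if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x),
    numeric(1))
  new("QuantMaps", maps = mapList,
      mask = array(mask > 0.5, dim(mask)),
      snr = snrIn, voxelSize = meta$voxelSize,
      fio2 = if (is.null(meta$fio2)) NA_real_ else meta$fio2)
}
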