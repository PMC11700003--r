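# Generics and accessors.  Slot access from user code should go through
# these rather than `@`.

#' Grid geometry accessors
#'
#' @param x an object with a voxel grid (phantom, dose components, tally).
#' @return `phantomDims` an integer(3) vector, `voxelSize` the cubic voxel
#'   side in cm, `gridOrigin` the world coordinate of the grid corner.
#' @export
setGeneric("phantomDims", function(x) standardGeneric("phantomDims"))
#' @rdname phantomDims
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname phantomDims
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

for (cl in c("VoxelPhantom", "DoseComponents", "KermaTally", "PrimaryField")) {
  setMethod("phantomDims", cl, function(x) x@dims)
  setMethod("voxelSize", cl, function(x) x@voxelSize)
  setMethod("gridOrigin", cl, function(x) x@origin)
}

#' Extract a generation-resolved dose or kerma grid
#'
#' @param x a [DoseComponents-class] or [KermaTally-class] object.
#' @param gen one of `"prim"`, `"1sc"`, `"msc"`, `"tot"`.
#' @return a numeric 3D array in MeV/g per emitted photon (history).
#' @export
setGeneric("doseComponent", function(x, gen = "tot") standardGeneric("doseComponent"))

#' @rdname doseComponent
#' @export
setMethod("doseComponent", "DoseComponents", function(x, gen = "tot") {
  switch(match.arg(gen, c("tot", "prim", "1sc", "msc")),
    tot = x@tot, prim = x@prim, "1sc" = x@onesc, msc = x@msc)
})

#' @rdname doseComponent
#' @export
setMethod("doseComponent", "KermaTally", function(x, gen = "tot") {
  gen <- match.arg(gen, c("tot", "prim", "1sc", "msc"))
  # divide then add column-wise so the class components add to the total
  # bit-exactly
  m <- if (gen == "tot")
    x@kerma[, 1] / x@nHistories + x@kerma[, 2] / x@nHistories +
      x@kerma[, 3] / x@nHistories
  else x@kerma[, match(gen, c("prim", "1sc", "msc"))] / x@nHistories
  array(m, dim = x@dims)
})

#' Medium names of a phantom
#' @param x a [VoxelPhantom-class].
#' @export
setGeneric("mediaNames", function(x) standardGeneric("mediaNames"))
#' @rdname mediaNames
#' @export
setMethod("mediaNames", "VoxelPhantom",
  function(x) vapply(x@media, function(m) m@name, character(1)))

#' Logical mask of the box heterogeneity voxels
#'
#' Returns the strictly interior heterogeneity voxels (all voxels whose
#' volume lies inside the box; box faces coincide with voxel boundaries).
#'
#' @param x a [VoxelPhantom-class] built by [buildCase()].
#' @return logical 3D array, or an error for a homogeneous phantom.
#' @export
setGeneric("boxMask", function(x) standardGeneric("boxMask"))
#' @rdname boxMask
#' @export
setMethod("boxMask", "VoxelPhantom", function(x) {
  if (length(x@box) == 0L) stop("phantom has no box heterogeneity")
  ctr <- voxelCenters(x)
  m <- array(FALSE, dim = x@dims)
  m[ctr$x > x@box$lo[1] & ctr$x < x@box$hi[1],
    ctr$y > x@box$lo[2] & ctr$y < x@box$hi[2],
    ctr$z > x@box$lo[3] & ctr$z < x@box$hi[3]] <- TRUE
  m
})

setMethod("show", "VoxelPhantom", function(object) {
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels of %.3g cm (%.3g cm side)\n",
    object@dims[1], object@dims[2], object@dims[3], object@voxelSize,
    object@dims[1] * object@voxelSize))
  cat("  media: ", paste(mediaNames(object), collapse = ", "), "\n", sep = "")
  if (length(object@box))
    cat(sprintf("  box heterogeneity: %s, x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f] cm\n",
      object@box$medium, object@box$lo[1], object@box$hi[1],
      object@box$lo[2], object@box$hi[2], object@box$lo[3], object@box$hi[3]))
  cat(sprintf("  source at (%.3g, %.3g, %.3g) cm\n",
    object@source[1], object@source[2], object@source[3]))
})

setMethod("show", "Medium", function(object) {
  cat(sprintf("Medium '%s': rho = %.4g g/cm^3; %s\n", object@name,
    object@density, paste(sprintf("%s(%.1f)", names(object@composition),
      100 * object@composition), collapse = " ")))
})

setMethod("show", "PhotonSpectrum", function(object) {
  cat(sprintf("PhotonSpectrum: %d lines/bins, %.4g - %.4g MeV, mean %.4g MeV\n",
    length(object@energy), min(object@energy), max(object@energy),
    sum(object@energy * object@weight)))
})

setMethod("show", "DoseComponents", function(object) {
  cat(sprintf("DoseComponents (%s msc transport): %d x %d x %d voxels\n",
    object@mode, object@dims[1], object@dims[2], object@dims[3]))
  if (!is.null(object@meta$energySums))
    for (g in names(object@meta$energySums))
      cat(sprintf("  %-4s integral dose*mass = %.5g MeV/photon\n", g,
        object@meta$energySums[[g]]))
})

setMethod("show", "KermaTally", function(object) {
  cat(sprintf("KermaTally: %d x %d x %d voxels, %.3g histories (%s)\n",
    object@dims[1], object@dims[2], object@dims[3], object@nHistories,
    if (isTRUE(object@meta$forcing)) "forced" else "analog"))
})

setMethod("show", "KernelFit", function(object) {
  tot <- kernelFraction(object)
  cat(sprintf("KernelFit (%s): %d polar cones, deposited fraction %.4f\n",
    object@generation, nrow(object@params), tot))
})

setMethod("show", "KernelTally", function(object) {
  cat(sprintf("KernelTally (%s): %d x %d (r x cone) bins, deposited %.4f of released\n",
    object@generation, nrow(object@energy), ncol(object@energy),
    sum(object@energy)))
})
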