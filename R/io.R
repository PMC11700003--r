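# Volume and configuration I/O.

#' Write / read a dose or density volume
#'
#' Volumes are stored as NIfTI with the voxel size in the header (world
#' offsets are kept in the run configuration, not the volume).
#'
#' @param x 3D numeric array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param voxelSize cubic voxel side in cm.
#' @return the path (write) or a 3D array with a `voxelSize` attribute
#'   (read).
#' @export
writeVolume <- function(x, path, voxelSize) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep(voxelSize, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxelSize") <- RNifti::pixdim(img)[1]
  out
}

#' Write all generation components of an engine or MC result
#'
#' One volume per component (`prim`, `1sc`, `msc`, `tot`) plus a YAML
#' sidecar with provenance metadata.
#'
#' @param x a [DoseComponents-class] or [KermaTally-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return the sidecar path, invisibly.
#' @export
writeDoseComponents <- function(x, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in c("prim", "1sc", "msc", "tot"))
    writeVolume(doseComponent(x, g),
      file.path(dir, sprintf("%s_%s.nii.gz", prefix, g)), voxelSize(x))
  meta <- if (is(x, "DoseComponents"))
    c(list(kind = "engine", mode = x@mode), x@meta["nDirs1sc"],
      x@meta["nDirsMsc"])
  else list(kind = "mc", nHistories = x@nHistories, seed = x@meta$seed,
    forcing = x@meta$forcing,
    counters = as.list(x@counters))
  meta$dims <- as.integer(phantomDims(x))
  meta$voxelSize <- voxelSize(x)
  meta$origin <- gridOrigin(x)
  side <- file.path(dir, paste0(prefix, "_meta.yaml"))
  yaml::write_yaml(meta, side)
  invisible(side)
}

#' Write / read a phantom
#'
#' Medium-index and density volumes plus a YAML sidecar holding geometry,
#' the media library reference and the box description.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param dir output directory; prefix file name prefix.
#' @param prefix file name prefix.
#' @return `readPhantom` returns a [VoxelPhantom-class].
#' @export
writePhantom <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(array(phantom@medium, phantom@dims),
    file.path(dir, paste0(prefix, "_medium.nii.gz")), phantom@voxelSize)
  writeVolume(array(phantom@density, phantom@dims),
    file.path(dir, paste0(prefix, "_density.nii.gz")), phantom@voxelSize)
  writeMediaLibrary(phantom@media,
    file.path(dir, paste0(prefix, "_media.txt")))
  yaml::write_yaml(list(dims = as.integer(phantom@dims),
    voxelSize = phantom@voxelSize, origin = phantom@origin,
    source = phantom@source, media = mediaNames(phantom),
    box = phantom@box), file.path(dir, paste0(prefix, "_meta.yaml")))
  invisible(dir)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir, prefix = "phantom") {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
  med <- readVolume(file.path(dir, paste0(prefix, "_medium.nii.gz")))
  dens <- readVolume(file.path(dir, paste0(prefix, "_density.nii.gz")))
  media <- readMediaLibrary(file.path(dir, paste0(prefix, "_media.txt")))
  box <- meta$box
  if (length(box)) box <- list(medium = box$medium,
    lo = as.numeric(unlist(box$lo)), hi = as.numeric(unlist(box$hi)))
  else box <- list()
  voxelPhantom(meta$dims, meta$voxelSize, as.numeric(unlist(meta$origin)),
    as.integer(round(med)), media[unlist(meta$media)], density = as.numeric(dens),
    source = as.numeric(unlist(meta$source)), box = box)
}

#' Read / write a run configuration
#'
#' Plain YAML mapping of the [RunConfig-class] fields.
#'
#' @param path YAML file path.
#' @param config a [RunConfig-class] (for writing).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (nm in names(y)) {
    if (!nm %in% slotNames("RunConfig"))
      stop("unknown configuration key '", nm, "'")
    cur <- slot(cfg, nm)
    slot(cfg, nm) <- if (is.integer(cur)) as.integer(y[[nm]])
      else if (is.numeric(cur)) as.numeric(y[[nm]])
      else if (is.logical(cur)) as.logical(y[[nm]])
      else as.character(y[[nm]])
  }
  validObject(cfg)
  cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  vals <- lapply(slotNames("RunConfig"), function(s) slot(config, s))
  names(vals) <- slotNames("RunConfig")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Construct a run configuration
#'
#' @param ... named [RunConfig-class] fields overriding the desk-scale
#'   defaults (0.2 cm voxels, 16.2 cm subphantom, 320/72 directions, 2e6
#'   forced histories).
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(...) {
  args <- list(...)
  cfg <- new("RunConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames("RunConfig"))
      stop("unknown configuration key '", nm, "'")
    cur <- slot(cfg, nm)
    slot(cfg, nm) <- if (is.integer(cur)) as.integer(args[[nm]])
      else args[[nm]]
  }
  validObject(cfg)
  cfg
}
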