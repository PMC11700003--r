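# Voxel phantoms: constructors, the three benchmark cases and geometric
# ray-tracing utilities.

#' Construct a voxel phantom
#'
#' @param dims integer(3) voxel counts.
#' @param voxelSize cubic voxel side in cm.
#' @param origin world coordinate of the grid corner (cm).
#' @param medium integer vector of 1-based medium indices (length
#'   `prod(dims)`).
#' @param media list of [Medium-class] objects.
#' @param density optional per-voxel densities; defaults to each voxel's
#'   medium density.
#' @param source point-source position (cm), default the world origin.
#' @param box optional heterogeneity descriptor list (`medium`, `lo`, `hi`).
#' @return a [VoxelPhantom-class].
#' @export
voxelPhantom <- function(dims, voxelSize, origin, medium, media,
                         density = NULL, source = c(0, 0, 0), box = list()) {
  dims <- as.integer(dims)
  medium <- as.integer(unname(medium))
  if (is.null(density)) {
    dens <- vapply(media, function(m) m@density, numeric(1))
    density <- dens[medium]
  }
  density <- as.numeric(unname(density))
  new("VoxelPhantom", dims = dims, voxelSize = voxelSize,
    origin = as.numeric(origin), medium = medium, density = density,
    media = media, source = as.numeric(source), box = box)
}

#' Per-axis voxel center coordinates
#'
#' @param phantom a [VoxelPhantom-class].
#' @return list with per-axis numeric vectors `x`, `y`, `z` (cm).
#' @export
voxelCenters <- function(phantom) {
  v <- phantom@voxelSize
  lapply(setNames(1:3, c("x", "y", "z")), function(a)
    phantom@origin[a] + (seq_len(phantom@dims[a]) - 0.5) * v)
}

#' Homogeneous water phantom
#'
#' Cubic water phantom with the source at the center of the central voxel.
#'
#' @param voxelSize cubic voxel side (cm).
#' @param side phantom side length (cm); `side/voxelSize` must be an odd
#'   integer so the source voxel is centered.
#' @return a [VoxelPhantom-class].
#' @export
waterPhantom <- function(voxelSize = 0.1, side = 30.1) {
  n <- .gridCount(side, voxelSize)
  media <- mediaLibrary()
  voxelPhantom(rep(n, 3), voxelSize, rep(-n * voxelSize / 2, 3),
    rep(1L, n^3), media[c("water")])
}

.gridCount <- function(side, voxelSize) {
  n <- side / voxelSize
  if (abs(n - round(n)) > 1e-9)
    stop("side must be an integer multiple of voxelSize")
  n <- as.integer(round(n))
  if (n %% 2L == 0L)
    stop("side/voxelSize must be odd so the source sits at the center of ",
         "the central voxel")
  n
}

# box face coordinates for a heterogeneity of 2.1 x 2.1 x 3.1 cm^3 centered
# at (a, 0, 0)
.caseBox <- function(a) list(lo = c(a - 1.05, -1.05, -1.55),
                             hi = c(a + 1.05, 1.05, 1.55))

#' Build a benchmark heterogeneity case
#'
#' A cubic water phantom (default 30.1 cm side) with a box-shaped
#' heterogeneity of 2.1 x 2.1 x 3.1 cm^3 (long axis along z) centered on the
#' +x axis: Case A is cortical bone centered 6 cm from the source, Case B
#' cortical bone at 3 cm, Case C air at 3 cm.  All box faces must coincide
#' with voxel boundaries so that no voxel straddles a media boundary; with
#' the default 0.1 cm voxels this holds exactly.  For coarser grids where
#' the canonical faces fall inside voxels, `snapBox = TRUE` snaps each face
#' to the nearest voxel boundary (used by the desk-scale profile).
#'
#' @param caseId `"A"`, `"B"` or `"C"`.
#' @param voxelSize cubic voxel side (cm).
#' @param side phantom side (cm); `side/voxelSize` must be an odd integer.
#' @param snapBox snap box faces to the nearest voxel boundaries instead of
#'   failing when they would intersect voxel interiors.
#' @return a [VoxelPhantom-class].
#' @examples
#' ph <- buildCase("A", voxelSize = 0.1)
#' sum(boxMask(ph))  # 21 * 21 * 31 voxels inside the heterogeneity
#' @export
buildCase <- function(caseId = c("A", "B", "C"), voxelSize = 0.1,
                      side = 30.1, snapBox = FALSE) {
  caseId <- match.arg(caseId)
  n <- .gridCount(side, voxelSize)
  origin <- rep(-n * voxelSize / 2, 3)
  a <- if (caseId == "A") 6 else 3
  boxMedium <- if (caseId == "C") "air" else "cortical_bone"
  box <- .caseBox(a)
  snap <- function(x) origin[1] + round((x - origin[1]) / voxelSize) * voxelSize
  for (f in c("lo", "hi")) {
    onGrid <- abs((box[[f]] - origin) / voxelSize -
                  round((box[[f]] - origin) / voxelSize)) < 1e-9
    if (!all(onGrid)) {
      if (!snapBox)
        stop("box faces at ", paste(signif(box[[f]][!onGrid], 4),
          collapse = ", "), " cm do not lie on voxel boundaries for ",
          "voxelSize = ", voxelSize, " cm; no voxel may intersect a media ",
          "boundary (use snapBox = TRUE to snap faces to the grid)")
      box[[f]] <- snap(box[[f]])
    }
  }
  media <- mediaLibrary()[c("water", boxMedium)]
  medium <- rep(1L, n^3)
  ph <- voxelPhantom(rep(n, 3), voxelSize, origin, medium, media,
    box = c(list(medium = boxMedium), box))
  inBox <- boxMask(ph)
  ph@medium[inBox] <- 2L
  dens <- vapply(media, function(m) m@density, numeric(1))
  ph@density <- unname(dens[ph@medium])
  validObject(ph)
  ph
}

#' Index of the voxel containing a point
#' @param phantom a [VoxelPhantom-class]; point numeric(3) in cm.
#' @return 1-based linear voxel index.
#' @export
voxelIndex <- function(phantom, point) {
  ijk <- floor((point - phantom@origin) / phantom@voxelSize)
  ijk <- pmin(pmax(ijk, 0), phantom@dims - 1L)
  as.integer(1 + ijk[1] + phantom@dims[1] * (ijk[2] + phantom@dims[2] * ijk[3]))
}

#' Radiological path between two points
#'
#' Optical depth along the straight segment from `p0` to `p1`: the sum over
#' traversed voxels of geometric length times the local linear attenuation
#' coefficient, using exact incremental grid crossing.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param p0,p1 numeric(3) end points in cm (inside or on the grid).
#' @param energy photon energy in MeV used to evaluate the per-voxel linear
#'   attenuation `(mu/rho)(E, medium) * rho`; alternatively supply `muLinear`.
#' @param muLinear optional per-medium linear attenuation coefficients
#'   (cm^-1) at the nominal medium densities, overriding `energy`.
#' @return optical depth (dimensionless).
#' @export
radiologicalPath <- function(phantom, p0, p1, energy = NULL,
                             muLinear = NULL) {
  if (sum((as.numeric(p1) - as.numeric(p0))^2) == 0) return(0)
  if (is.null(muLinear)) {
    if (is.null(energy)) stop("supply either energy or muLinear")
    muMass <- vapply(phantom@media, function(m)
      mediumCoefficients(m, energy)$muRho, numeric(1))
  } else {
    muMass <- muLinear / vapply(phantom@media, function(m) m@density,
      numeric(1))
  }
  muVox <- muMass[phantom@medium] * phantom@density
  cpp_radiological_path(phantom@dims, phantom@voxelSize, phantom@origin,
    muVox, as.numeric(p0), as.numeric(p1))
}
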