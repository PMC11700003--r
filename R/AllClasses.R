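# S4 classes for the dose engine.  Grids are stored as numeric 3D arrays in
# x-fastest order; world coordinates are in cm with the source at the origin.

#' Discrete photon spectrum
#'
#' A set of photon energies with associated relative emission or fluence
#' probabilities.  Weights are normalized to unit sum on construction.
#'
#' @slot energy numeric, photon energies in MeV (ascending).
#' @slot weight numeric, non-negative normalized weights.
#' @export
setClass("PhotonSpectrum",
  representation(energy = "numeric", weight = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) != length(object@weight))
      msg <- c(msg, "energy and weight lengths differ")
    if (length(object@energy) == 0L) msg <- c(msg, "empty spectrum")
    if (any(object@weight < 0)) msg <- c(msg, "negative spectrum weights")
    if (abs(sum(object@weight) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
    if (any(object@energy < 1e-3 - 1e-12) || any(object@energy > 1.5 + 1e-12))
      msg <- c(msg, "energies outside the tabulated 1 keV - 1.5 MeV range")
    if (is.unsorted(object@energy, strictly = FALSE))
      msg <- c(msg, "energies must be ascending")
    if (length(msg)) msg else TRUE
  })

#' Homogeneous medium with photon interaction coefficients
#'
#' Elemental composition by mass together with mixture-rule mass attenuation
#' and mass energy-absorption coefficients on the package energy grid, and
#' per-process fractions of the total cross section.
#'
#' @slot name character medium name.
#' @slot composition named numeric, element mass fractions (sum 1).
#' @slot density numeric, g/cm^3.
#' @slot energy numeric energy grid (MeV, ascending).
#' @slot muRho numeric mass attenuation coefficient (cm^2/g) per grid energy.
#' @slot muenRho numeric mass energy-absorption coefficient (cm^2/g).
#' @slot processFractions matrix with columns photoelectric/incoherent/coherent,
#'   rows matching the energy grid; each row sums to 1.
#' @export
setClass("Medium",
  representation(name = "character", composition = "numeric",
    density = "numeric", energy = "numeric", muRho = "numeric",
    muenRho = "numeric", processFractions = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@density <= 0) msg <- c(msg, "density must be positive")
    if (abs(sum(object@composition) - 1) > 1e-4)
      msg <- c(msg, "mass fractions must sum to 1 within 1e-4")
    if (is.unsorted(object@energy, strictly = TRUE))
      msg <- c(msg, "energy grid must be strictly increasing")
    if (any(object@muRho <= 0) || any(object@muenRho <= 0))
      msg <- c(msg, "coefficients must be positive")
    if (any(object@muenRho > object@muRho * (1 + 1e-12)))
      msg <- c(msg, "muen/rho must not exceed mu/rho")
    if (nrow(object@processFractions) != length(object@energy))
      msg <- c(msg, "processFractions rows must match energy grid")
    else if (max(abs(rowSums(object@processFractions) - 1)) > 1e-9)
      msg <- c(msg, "process fractions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Voxelized phantom
#'
#' Uniform cubic voxel grid of medium indices and mass densities.  The
#' benchmark phantoms place the point source at the center of the central
#' voxel.
#'
#' @slot dims integer(3) voxel counts (nx, ny, nz).
#' @slot voxelSize numeric, cubic voxel side (cm).
#' @slot origin numeric(3), world coordinate of the grid corner (cm); voxel
#'   (i, j, k) spans `origin + (c(i,j,k) - 1) * voxelSize` (half-open).
#' @slot medium integer vector (length prod(dims)), 1-based index into media.
#' @slot density numeric vector, voxel mass densities (g/cm^3).
#' @slot media list of [Medium-class] objects.
#' @slot source numeric(3) point-source position (cm).
#' @slot box list describing the box heterogeneity (`medium`, `lo`, `hi`) or
#'   empty for a homogeneous phantom.
#' @export
setClass("VoxelPhantom",
  representation(dims = "integer", voxelSize = "numeric", origin = "numeric",
    medium = "integer", density = "numeric", media = "list",
    source = "numeric", box = "list"),
  validity = function(object) {
    msg <- character()
    nv <- prod(object@dims)
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be positive")
    if (length(object@medium) != nv || length(object@density) != nv)
      msg <- c(msg, "medium/density length must equal prod(dims)")
    if (length(object@media) == 0L ||
        any(object@medium < 1L) || any(object@medium > length(object@media)))
      msg <- c(msg, "medium indices outside media list")
    if (any(object@density <= 0)) msg <- c(msg, "densities must be positive")
    if (length(msg)) msg else TRUE
  })

#' Transport line lattice for one direction
#'
#' The set of parallel transport lines tiling the grid for a single cone
#' direction, as ordered voxel steps.  Each voxel of the grid is crossed by
#' exactly one line of the lattice and every step has the direction's
#' constant step length, so the summed step length per voxel equals the
#' per-direction total step length `dlMax` by construction.
#'
#' @slot direction numeric(3) unit vector.
#' @slot dlMax numeric, total step length per voxel for this direction (cm).
#' @slot steps data.frame with columns `line` (line id), `order` (step index
#'   along the line), `voxel` (1-based voxel index) and `dl` (step length, cm).
#' @export
setClass("TransportLineLattice",
  representation(direction = "numeric", dlMax = "numeric",
    steps = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
      msg <- c(msg, "direction must be a unit vector")
    if (length(msg)) msg else TRUE
  })

#' Forced-interaction kernel tally
#'
#' Energy deposited per unit released scatter energy, binned in radius and
#' polar angle relative to the incident photon direction, for one scatter
#' generation, together with the derived scatter spectrum and energy
#' bookkeeping counters.
#'
#' @slot generation `"1sc"` or `"msc"`.
#' @slot rEdges numeric radial bin edges (cm).
#' @slot coneCos numeric polar-angle bin edges as cos(theta), descending from
#'   1 (forward) to -1 (backward).
#' @slot energy matrix (nr x ncones) of deposited energy fractions.
#' @slot spectrum [PhotonSpectrum-class] of the emerging scatter generation.
#' @slot escapeCone numeric per-cone energy fraction whose deposition site
#'   lies beyond the tally radius (booked by direction so the fitted kernel
#'   can conserve each cone's total share).
#' @slot counters named numeric: released, deposited, escaped, continued,
#'   cutoff (MeV totals over the run).
#' @slot nHistories numeric, seed numeric.
#' @export
setClass("KernelTally",
  representation(generation = "character", rEdges = "numeric",
    coneCos = "numeric", energy = "matrix", escapeCone = "numeric",
    spectrum = "PhotonSpectrum",
    counters = "numeric", nHistories = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@generation %in% c("1sc", "msc"))
      msg <- c(msg, "generation must be '1sc' or 'msc'")
    if (any(object@energy < 0)) msg <- c(msg, "negative tally entries")
    if (sum(object@energy) > 1 + 1e-9)
      msg <- c(msg, "tally total exceeds released energy")
    if (length(msg)) msg else TRUE
  })

#' Fitted collapsed-cone kernel
#'
#' Per polar-cone bi-exponential kernel parameters: the radial energy density
#' per steradian is `C * exp(-c*r) + F * exp(-f*r)`.  The angular integral
#' `sum(coneSolidAngle * (C/c + F/f))` is the fraction of released energy the
#' kernel deposits.
#'
#' @slot generation `"1sc"` or `"msc"`.
#' @slot coneCos numeric cone edges as cos(theta) (length ncones + 1).
#' @slot params matrix (ncones x 4) with columns C, c, F, f; C and F are per
#'   steradian per cm, c and f in cm^-1.
#' @slot coneSolidAngle numeric cone solid angles (sr), summing to 4*pi.
#' @slot rms numeric per-cone fit RMS in log space.
#' @export
setClass("KernelFit",
  representation(generation = "character", coneCos = "numeric",
    params = "matrix", coneSolidAngle = "numeric", rms = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- object@params
    if (ncol(p) != 4L) msg <- c(msg, "params must have columns C, c, F, f")
    if (any(p[, 2] <= 0) || any(p[, 4] <= 0))
      msg <- c(msg, "attenuation parameters c and f must be positive")
    if (any(p[, c(1, 3)] < 0)) msg <- c(msg, "magnitudes C and F must be >= 0")
    if (abs(sum(object@coneSolidAngle) - 4 * pi) > 1e-9)
      msg <- c(msg, "cone solid angles must sum to 4*pi")
    if (length(msg)) msg else TRUE
  })

#' Primary photon field
#'
#' Compact representation of the primary energy fluence: per-voxel
#' density-weighted path lengths through each medium from the source to the
#' voxel center, the source-voxel distance, and the emission spectrum.  The
#' energy fluence for spectral line i at a voxel is
#' `w_i E_i exp(-sum_m (mu/rho)_m(E_i) * pathRho[, m]) / (4 pi d^2)`.
#'
#' @slot dims integer(3); voxelSize numeric; origin numeric(3).
#' @slot pathRho matrix (nvox x nmedia) of rho-weighted path lengths (g/cm^2).
#' @slot dist numeric source-to-voxel-center distances (cm).
#' @slot sourceVoxel integer index of the voxel containing the source.
#' @slot spectrum [PhotonSpectrum-class].
#' @export
setClass("PrimaryField",
  representation(dims = "integer", voxelSize = "numeric", origin = "numeric",
    pathRho = "matrix", dist = "numeric", sourceVoxel = "integer",
    spectrum = "PhotonSpectrum"))

#' Generation-resolved dose components
#'
#' Co-registered dose grids for the primary, first-scatter and
#' multiple-scatter generations; the total is their bit-level sum.
#'
#' @slot dims integer(3); voxelSize numeric; origin numeric(3).
#' @slot prim,onesc,msc,tot numeric 3D arrays (MeV/g per emitted photon).
#' @slot mode `"original"` or `"corrected"` multiple-scatter transport mode.
#' @slot meta list of provenance (direction counts, kernel id, balances).
#' @export
setClass("DoseComponents",
  representation(dims = "integer", voxelSize = "numeric", origin = "numeric",
    prim = "array", onesc = "array", msc = "array", tot = "array",
    mode = "character", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("original", "corrected"))
      msg <- c(msg, "mode must be 'original' or 'corrected'")
    if (!identical(object@tot, object@prim + object@onesc + object@msc))
      msg <- c(msg, "tot must be the exact sum of the components")
    if (any(object@prim < 0) || any(object@onesc < 0) || any(object@msc < 0))
      msg <- c(msg, "negative dose")
    if (length(msg)) msg else TRUE
  })

#' Monte Carlo collision-kerma tally
#'
#' Per-voxel, per-generation-class collision kerma with history-by-history
#' Type A uncertainties.  Classes are prim (bkn = 0), 1sc (bkn = 1) and msc
#' (bkn >= 2).
#'
#' @slot dims integer(3); voxelSize numeric; origin numeric(3).
#' @slot kerma matrix (nvox x 3), columns prim/1sc/msc: raw per-history
#'   score sums (MeV/g); divide by `nHistories` for the mean, or use
#'   [doseComponent()].
#' @slot sumsq matrix (nvox x 3) of per-history squared sums (for Type A).
#' @slot nHistories numeric.
#' @slot regions list of per-region history statistics (sum and sumsq per
#'   class) for region masks registered at run time.
#' @slot counters named numeric energy bookkeeping (emitted, absorbed,
#'   escaped, cutoff, rrLost).
#' @slot meta list (seed, forcing, spectrum id).
#' @export
setClass("KermaTally",
  representation(dims = "integer", voxelSize = "numeric", origin = "numeric",
    kerma = "matrix", sumsq = "matrix", nHistories = "numeric",
    regions = "list", counters = "numeric", meta = "list"),
  validity = function(object) {
    if (ncol(object@kerma) != 3L) return("kerma must have 3 generation columns")
    TRUE
  })

#' Engine run configuration
#'
#' Validated configuration for a full engine and/or Monte Carlo run.
#'
#' @slot caseId character ("A", "B", "C" or "water").
#' @slot voxelSize,side numeric phantom discretization (cm).
#' @slot nDirs1sc,nDirsMsc integer transport direction counts.
#' @slot mscMode character, "original", "corrected" or "both".
#' @slot nHistories numeric MC histories; seed numeric; forcing logical.
#' @slot kernelFile,spectrumFile character fixture paths ("" = packaged).
#' @slot outputDir character.
#' @export
setClass("RunConfig",
  representation(caseId = "character", voxelSize = "numeric",
    side = "numeric", nDirs1sc = "integer", nDirsMsc = "integer",
    mscMode = "character", nHistories = "numeric", seed = "numeric",
    forcing = "logical", kernelFile = "character",
    spectrumFile = "character", outputDir = "character"),
  prototype(caseId = "A", voxelSize = 0.25, side = 30.25, nDirs1sc = 320L,
    nDirsMsc = 72L, mscMode = "both", nHistories = 2e6, seed = 1,
    forcing = TRUE, kernelFile = "", spectrumFile = "", outputDir = "."),
  validity = function(object) {
    msg <- character()
    if (!object@caseId %in% c("A", "B", "C", "water"))
      msg <- c(msg, "caseId must be one of A, B, C, water")
    if (!object@mscMode %in% c("original", "corrected", "both"))
      msg <- c(msg, "mscMode must be original, corrected or both")
    if (object@voxelSize <= 0 || object@side <= 0)
      msg <- c(msg, "voxelSize and side must be positive")
    if (object@nDirs1sc < 1L || object@nDirsMsc < 1L)
      msg <- c(msg, "direction counts must be >= 1")
    if (object@nHistories < 1) msg <- c(msg, "nHistories must be >= 1")
    if (length(msg)) msg else TRUE
  })
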