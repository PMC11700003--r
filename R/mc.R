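# Generation-resolved Monte Carlo reference with scatter-generation
# bookkeeping and collision-kerma scoring.

#' Scatter-generation bookkeeping number for interaction products
#'
#' Bookkeeping rules: a photon leaving the source is primary (bkn 0); a
#' photon produced in a photon interaction (Compton, Rayleigh) or in a
#' secondary-particle interaction (e.g. bremsstrahlung) gets the parent's
#' bkn plus one; secondary charged particles keep the parent's bkn.
#' Whether elastic (Rayleigh) scattering increments the counter is
#' configurable since it does not degrade the energy; the default applies
#' the literal rule and increments.
#'
#' @param parent parent particle's bkn (ignored for `event = "source"`).
#' @param event one of `"source"`, `"compton"`, `"rayleigh"`,
#'   `"bremsstrahlung"`, `"charged"`.
#' @param rayleighIncrements should Rayleigh scattering increment the bkn?
#' @return integer bkn of the product particle.
#' @export
assignBkn <- function(parent = NULL,
                      event = c("source", "compton", "rayleigh",
                                "bremsstrahlung", "charged"),
                      rayleighIncrements = TRUE) {
  event <- match.arg(event)
  if (event == "source") return(0L)
  if (is.null(parent) || parent < 0L) stop("parent bkn must be known")
  parent <- as.integer(parent)
  switch(event,
    compton = parent + 1L,
    bremsstrahlung = parent + 1L,
    rayleigh = if (rayleighIncrements) parent + 1L else parent,
    charged = parent)
}

#' Run the Monte Carlo reference
#'
#' Photon-only random walk in the phantom with per-voxel ray-traced free
#' paths, free-electron Klein-Nishina Compton sampling, photoelectric
#' absorption, optional Thomson-sampled coherent scattering, and a 1 keV
#' photon cutoff.  Collision kerma (the dose surrogate with electron
#' transport disabled) is scored per voxel and per generation class
#' (prim/1sc/msc) by a track-length estimator; with `forcing = TRUE` the
#' expected-value estimator integrates the attenuated fluence over the full
#' ray, collisions are forced to occur inside the phantom by weight
#' splitting, photoelectric absorption is replaced by survival weighting
#' and low-weight photons undergo Russian roulette.  Type A uncertainties
#' use history-by-history statistics.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spectrum emission [PhotonSpectrum-class].
#' @param nHistories number of primary photon histories.
#' @param seed RNG seed (fixed seed gives bit-identical tallies).
#' @param forcing enable interaction forcing / expected-value scoring.
#' @param regions optional named list of logical masks; per-history sums
#'   over each region are tracked exactly for region-mean uncertainties.
#' @param rayleigh include coherent scattering.
#' @param bknRayleigh should Rayleigh scattering increment the bookkeeping
#'   number (see [assignBkn()]).
#' @param voxelVariance track per-voxel history-by-history variance grids
#'   (disable for large production runs; region uncertainties registered via
#'   `regions` remain exact either way).
#' @param specShell optional radial shell `c(r1, r2)` in cm: when given, the
#'   energy-fluence spectrum of photons colliding inside the shell is
#'   tallied per generation class (collision-density estimator, weights
#'   `w E / mu`) and returned in `meta$spectra`.
#' @return a [KermaTally-class].
#' @export
runMC <- function(phantom, spectrum = irSpectrum(), nHistories = 1e5,
                  seed = 1, forcing = TRUE, regions = list(),
                  rayleigh = TRUE, bknRayleigh = TRUE, specShell = NULL,
                  voxelVariance = TRUE) {
  if (nHistories < 1) stop("nHistories must be >= 1")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("invalid seed")
  nv <- prod(phantom@dims)
  regionLab <- integer(0)
  if (length(regions)) {
    regionLab <- integer(nv)
    for (i in seq_along(regions)) {
      m <- as.logical(regions[[i]])
      if (length(m) != nv) stop("region mask length mismatch")
      if (any(regionLab[m] != 0L)) stop("region masks must be disjoint")
      regionLab[m] <- i
    }
  }
  edges <- if (is.null(specShell)) numeric(0) else .specOutEdges()
  res <- cpp_run_mc(phantom@dims, phantom@voxelSize, phantom@origin,
    phantom@medium - 1L, phantom@density, phantom@source,
    spectrum@energy, spectrum@weight, as.integer(nHistories), seed,
    forcing, .physPack(phantom@media), regionLab,
    length(regions), rayleigh, bknRayleigh,
    if (is.null(specShell)) numeric(0) else as.numeric(specShell), edges,
    voxelVariance)
  regStats <- list()
  if (length(regions)) {
    cls <- c("prim", "1sc", "msc", "tot")
    for (i in seq_along(regions))
      regStats[[names(regions)[i]]] <- list(
        sum = setNames(res$regions$sum[i, ], cls),
        sumsq = setNames(res$regions$sumsq[i, ], cls),
        nVoxels = sum(regions[[i]]))
  }
  colnames(res$kerma) <- colnames(res$sumsq) <- c("prim", "1sc", "msc")
  spectra <- NULL
  if (!is.null(specShell)) {
    ctr <- sqrt(edges[-length(edges)] * edges[-1])
    spectra <- lapply(setNames(1:3, c("prim", "1sc", "msc")), function(i) {
      keep <- res$specFl[, i] > 0
      if (!any(keep)) return(NULL)
      sp <- photonSpectrum(ctr[keep], res$specFl[keep, i])
      attr(sp, "halfWidth") <- (diff(edges) / 2)[keep]
      sp
    })
  }
  new("KermaTally", dims = phantom@dims, voxelSize = phantom@voxelSize,
    origin = phantom@origin, kerma = res$kerma, sumsq = res$sumsq,
    nHistories = res$nhist, regions = regStats, counters = res$counters,
    meta = list(seed = seed, forcing = forcing, rayleigh = rayleigh,
      bknRayleigh = bknRayleigh, spectra = spectra, specShell = specShell,
      voxelVariance = voxelVariance))
}

#' Merge independent Monte Carlo tallies
#'
#' Combines tallies of the same phantom run with different seeds; raw score
#' sums add, so merging is associative up to floating-point rounding.
#'
#' @param ... two or more [KermaTally-class] objects.
#' @return the combined [KermaTally-class].
#' @export
mergeTallies <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && is.list(ts[[1]]) && !is(ts[[1]], "KermaTally"))
    ts <- ts[[1]]
  out <- ts[[1]]
  for (t in ts[-1]) {
    stopifnot(identical(out@dims, t@dims))
    out@kerma <- out@kerma + t@kerma
    out@sumsq <- out@sumsq + t@sumsq
    out@nHistories <- out@nHistories + t@nHistories
    out@counters <- out@counters + t@counters
    for (nm in names(out@regions)) {
      out@regions[[nm]]$sum <- out@regions[[nm]]$sum + t@regions[[nm]]$sum
      out@regions[[nm]]$sumsq <-
        out@regions[[nm]]$sumsq + t@regions[[nm]]$sumsq
    }
  }
  out
}

#' Mean kerma of a tally over a region
#'
#' @param tally a [KermaTally-class].
#' @param mask logical voxel mask.
#' @param gen generation class (`"prim"`, `"1sc"`, `"msc"`, `"tot"`).
#' @return mean kerma per history (MeV/g).
#' @export
mcRegionMean <- function(tally, mask, gen = "tot") {
  mean(doseComponent(tally, gen)[mask])
}

#' Type A uncertainty of a region-mean dose
#'
#' History-by-history estimator at coverage factor k = 2.  For a region
#' registered at run time (by name) the exact per-history region sums are
#' used, which correctly accounts for correlations between voxels scored by
#' the same history.  For an arbitrary mask the per-voxel variances are
#' combined ignoring such correlations, which underestimates the region
#' uncertainty; a single-voxel mask is exact.
#'
#' @param tally a [KermaTally-class].
#' @param region a region name registered in [runMC()], or a logical mask.
#' @param gen generation class (`"prim"`, `"1sc"`, `"msc"`, `"tot"`).
#' @return relative Type A uncertainty (k = 2) of the region-mean kerma.
#' @export
mcUncertainty <- function(tally, region, gen = "tot") {
  N <- tally@nHistories
  if (is.character(region)) {
    st <- tally@regions[[region]]
    if (is.null(st)) stop("region '", region, "' was not registered")
    m <- st$sum[[gen]] / N
    varm <- (st$sumsq[[gen]] / N - m^2) / (N - 1)
    return(2 * sqrt(max(0, varm)) / abs(m) * 1)
  }
  mask <- as.logical(region)
  idx <- which(mask)
  cls <- if (gen == "tot") 1:3 else match(gen, c("prim", "1sc", "msc"))
  s <- rowSums(tally@kerma[idx, cls, drop = FALSE])
  q <- rowSums(tally@sumsq[idx, cls, drop = FALSE])
  if (length(idx) > 1L && gen == "tot")
    warning("arbitrary-mask uncertainty ignores inter-voxel and ",
      "inter-class correlations; register the region in runMC() for the ",
      "exact estimate")
  m <- s / N
  varm <- pmax(0, (q / N - m^2) / (N - 1))
  mTot <- mean(m)
  2 * sqrt(sum(varm)) / length(idx) / abs(mTot)
}


#' Scatter spectra at depth in a phantom
#'
#' Derives the first- and multiple-scatter energy-fluence spectra from a
#' Monte Carlo run of the (water) phantom, tallied over a radial shell
#' covering the source-to-boundary distances of interest.  These in-phantom
#' spectra, rather than infinite-medium cascade averages, feed the eta/chi
#' medium scaling factors: the scattered field at clinically relevant
#' distances is considerably harder than the asymptotic cascade spectrum.
#'
#' @param phantom a [VoxelPhantom-class] (typically homogeneous water).
#' @param spectrum emission [PhotonSpectrum-class].
#' @param nHistories,seed,forcing Monte Carlo settings.
#' @param shell radial range in cm over which collisions are tallied.
#' @return list with [PhotonSpectrum-class] elements `spec1sc` and
#'   `specMsc`.
#' @export
scatterSpectraAtDepth <- function(phantom, spectrum = irSpectrum(),
                                  nHistories = 2e5, seed = 1,
                                  forcing = TRUE, shell = c(1, 8)) {
  tal <- runMC(phantom, spectrum, nHistories, seed = seed,
    forcing = forcing, specShell = shell)
  list(spec1sc = tal@meta$spectra[["1sc"]],
    specMsc = tal@meta$spectra[["msc"]])
}
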