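# Forced-interaction kernel generation in water, scatter spectra and
# bi-exponential kernel fitting.

# physics pack handed to the C++ transport: log-log tables on the uniform
# log-energy grid shared by all media of a phantom (or water alone)
.physPack <- function(media) {
  E <- energyGrid()
  nmed <- length(media)
  lmu <- lmuen <- fp <- fi <- fc <- matrix(0, length(E), nmed)
  for (m in seq_len(nmed)) {
    lmu[, m] <- log(media[[m]]@muRho)
    lmuen[, m] <- log(media[[m]]@muenRho)
    fp[, m] <- media[[m]]@processFractions[, "photo"]
    fi[, m] <- media[[m]]@processFractions[, "incoh"]
    fc[, m] <- media[[m]]@processFractions[, "coh"]
  }
  list(nE = length(E), nmed = nmed, le0 = log(E[1]),
    dle = diff(log(E[1:2])), lmu = lmu, lmuen = lmuen, fpho = fp,
    finc = fi, fcoh = fc)
}

.kernelBins <- function(rMax = 30, nR = 64, nCones = 48) {
  list(rEdges = c(0, exp(seq(log(0.05), log(rMax), length.out = nR))),
    coneCos = seq(1, -1, length.out = nCones + 1))
}

.specOutEdges <- function(n = 120L) exp(seq(log(1e-3), log(1.5), length.out = n + 1))

.tallyFromCpp <- function(res, generation, bins, seed) {
  edges <- .specOutEdges()
  keep <- res$specOut > 0
  ctr <- sqrt(edges[-length(edges)] * edges[-1])
  sp <- photonSpectrum(ctr[keep], res$specOut[keep])
  attr(sp, "halfWidth") <- (diff(edges) / 2)[keep]
  rel <- res$counters[["released"]]
  new("KernelTally", generation = generation, rEdges = bins$rEdges,
    coneCos = bins$coneCos, energy = res$tally / rel,
    escapeCone = res$escCone / rel, spectrum = sp,
    counters = res$counters, nHistories = res$nhist, seed = seed)
}

#' Generate the first-scatter kernel and spectrum
#'
#' Forced-interaction Monte Carlo in infinite water: a primary photon along
#' +z is forced to interact at the origin; the collision kerma deposited by
#' the emerging first-scatter photon at its next interaction site is tallied
#' in (radius, polar angle) bins per unit released scatter energy.  Incident
#' lines are sampled with scerma-production weights
#' `w_i E_i (mu/rho - muen/rho)(E_i)` so the kernel represents the
#' first-scatter energy actually released by the source spectrum.  The
#' emerging photons are recorded as the first-scatter spectrum with
#' energy-fluence weights, the appropriate weighting for the
#' attenuation/absorption averages used in the medium scaling factors.
#'
#' @param spectrum the primary emission [PhotonSpectrum-class].
#' @param nHistories number of forced histories (warning below 1e4: the
#'   kernel fit becomes unstable).
#' @param seed RNG seed.
#' @param rMax tally radius (cm); deposits beyond it count as escaped.
#' @param nR,nCones radial (log-spaced) and polar bin counts.
#' @param rayleigh include coherent scattering.
#' @return a [KernelTally-class] with the 1sc spectrum attached.
#' @export
generate1scKernel <- function(spectrum = irSpectrum(), nHistories = 2e5,
                              seed = 1, rMax = 30, nR = 64, nCones = 48,
                              rayleigh = TRUE) {
  if (nHistories < 1e4)
    warning("fewer than 1e4 histories: kernel fit may be unstable")
  water <- mediaLibrary()["water"]
  co <- mediumCoefficients(water$water, spectrum@energy)
  wRel <- spectrum@weight * spectrum@energy * (co$muRho - co$muenRho)
  bins <- .kernelBins(rMax, nR, nCones)
  res <- cpp_kernel_mc(1L, spectrum@energy, wRel / sum(wRel),
    rep(0, length(spectrum@energy)), as.integer(nHistories), seed,
    .physPack(water), bins$rEdges, as.integer(nCones), .specOutEdges(),
    rayleigh)
  .tallyFromCpp(res, "1sc", bins, seed)
}

#' Generate the multiple-scatter kernel and spectrum
#'
#' As [generate1scKernel()], but the incident photon energy is drawn from
#' the first-scatter spectrum and the photon emerging from the forced vertex
#' is a second-scatter photon: the collision kerma of the entire descendant
#' cascade (generations >= 2) is tallied per unit released second-scatter
#' energy, so a single kernel closes the infinite scattering series.  The
#' energy-fluence spectrum of all generation >= 2 photons (collision-density
#' estimator, weights E/mu) is recorded as the multiple-scatter spectrum.
#'
#' @param onescSpectrum the first-scatter [PhotonSpectrum-class] (from
#'   [generate1scKernel()]); a `halfWidth` attribute, when present, smears
#'   sampled energies uniformly within histogram bins.
#' @inheritParams generate1scKernel
#' @return a [KernelTally-class] with the msc spectrum attached.
#' @export
generateMscKernel <- function(onescSpectrum, nHistories = 2e5, seed = 1,
                              rMax = 30, nR = 64, nCones = 48,
                              rayleigh = TRUE) {
  if (nHistories < 1e4)
    warning("fewer than 1e4 histories: kernel fit may be unstable")
  hw <- attr(onescSpectrum, "halfWidth")
  if (is.null(hw)) hw <- rep(0, length(onescSpectrum@energy))
  bins <- .kernelBins(rMax, nR, nCones)
  res <- cpp_kernel_mc(2L, onescSpectrum@energy, onescSpectrum@weight, hw,
    as.integer(nHistories), seed, .physPack(mediaLibrary()["water"]),
    bins$rEdges, as.integer(nCones), .specOutEdges(), rayleigh)
  .tallyFromCpp(res, "msc", bins, seed)
}

# weighted log-space rms of a candidate kernel against the profile
.coneRms <- function(r, y, w, C, cc, F, f) {
  pred <- C * exp(-cc * r) + F * exp(-f * r)
  if (any(pred <= 0)) return(Inf)
  sqrt(sum(w * (log(pred) - log(y))^2) / sum(w))
}

# best term split x = F/f in [0, q] for fixed decay constants under the
# conservation constraint C/c + F/f = q (weighted linear least squares in
# linear space; closed form, clamped)
.coneSplit <- function(cc, f, r, y, wl, q) {
  base <- q * cc * exp(-cc * r)
  slope <- f * exp(-f * r) - cc * exp(-cc * r)
  den <- sum(wl * slope^2)
  x <- if (den > 0) sum(wl * slope * (y - base)) / den else 0
  min(max(x, 0), q)
}

.fitCone <- function(r, y, w, q) {
  # Bi-exponential fit under exact energy conservation: the kernel's total
  # integral per steradian is pinned to the cone share q (tallied plus
  # beyond-tally-radius deposits), while the split between the two
  # exponential terms and their decay constants minimize the weighted
  # residual.  Weights combine bin content with a radial taper so the fit
  # represents the radii a phantom-scale dose grid samples.
  wl <- w / y^2                        # linear-space weights ~ counts/y^2
  cand <- function(cc, ff) {
    x <- .coneSplit(cc, ff, r, y, wl, q)
    C <- (q - x) * cc
    F <- x * ff
    list(C = C, c = cc, F = F, f = ff, rms = .coneRms(r, y, w, C, cc, F, ff))
  }
  decays <- exp(seq(log(0.01), log(3), length.out = 16))
  best <- NULL
  for (i in seq_along(decays)) for (j in seq_len(i)) {
    k <- cand(decays[i], decays[j])
    if (is.finite(k$rms) && (is.null(best) || k$rms < best$rms)) best <- k
  }
  obj <- function(p) {
    k <- cand(exp(p[1]), exp(p[2]))
    if (!is.finite(k$rms)) 1e6 else k$rms
  }
  op <- stats::optim(log(c(best$c, best$f)), obj, method = "Nelder-Mead",
    control = list(maxit = 300))
  if (op$value < best$rms) best <- cand(exp(op$par[1]), exp(op$par[2]))
  best$fallback <- best$F == 0
  best
}

#' Fit a bi-exponential collapsed-cone kernel to a tally
#'
#' Per polar cone, the radial energy density per steradian per cm is fitted
#' as `C exp(-c r) + F exp(-f r)` with positive attenuation constants and
#' non-negative magnitudes, under exact energy conservation: the angular
#' kernel integral per cone is pinned to the cone's total energy share
#' (tallied deposits plus deposits booked beyond the tally radius).  The
#' decay constants and the split between the two terms minimize a
#' content-weighted, radially tapered log-space residual (grid profiling
#' plus Nelder-Mead refinement); the split degenerates to a single
#' exponential when one term suffices.
#'
#' @param tally a [KernelTally-class].
#' @param minBins minimum number of nonzero radial bins required per cone.
#' @param rTaper e-folding radius (cm) of the weight taper concentrating
#'   fit fidelity at phantom-scale radii.
#' @return a [KernelFit-class]; per-cone fit RMS (log space) in `rms`.
#' @export
fitKernel <- function(tally, minBins = 8L, rTaper = 6) {
  nc <- ncol(tally@energy)
  dOmega <- 2 * pi * abs(diff(tally@coneCos))
  rmid <- (tally@rEdges[-1] + tally@rEdges[-length(tally@rEdges)]) / 2
  dr <- diff(tally@rEdges)
  params <- matrix(0, nc, 4, dimnames = list(NULL, c("C", "c", "F", "f")))
  rms <- numeric(nc)
  for (i in seq_len(nc)) {
    y <- tally@energy[, i] / (dOmega[i] * dr)
    ok <- y > 0
    if (sum(ok) < minBins)
      stop("cone ", i, " has fewer than ", minBins,
           " nonzero radial bins; increase nHistories")
    q <- (sum(tally@energy[, i]) + tally@escapeCone[i]) / dOmega[i]
    wgt <- sqrt(tally@energy[ok, i]) * exp(-rmid[ok] / rTaper)
    f <- .fitCone(rmid[ok], y[ok], wgt, q)
    params[i, ] <- c(f$C, f$c, f$F, f$f)
    rms[i] <- f$rms
  }
  new("KernelFit", generation = tally@generation,
    coneCos = tally@coneCos, params = params,
    coneSolidAngle = rep(4 * pi / nc, nc), rms = rms)
}

#' Angular-radial integral of a fitted kernel
#'
#' `sum_m dOmega_m (C/c + F/f)`: the fraction of released energy the fitted
#' kernel deposits over all radii and directions.
#'
#' @param fit a [KernelFit-class].
#' @return numeric fraction.
#' @export
kernelFraction <- function(fit) {
  p <- fit@params
  sum(fit@coneSolidAngle * (p[, 1] / p[, 2] + p[, 3] / p[, 4]))
}

#' Rescale a kernel fit to a target deposited fraction
#'
#' Scales the magnitudes C and F so [kernelFraction()] equals `total`.  The
#' multiple-scatter kernel is normalized to 1: it represents all scatter
#' generations above the first, whose energy is eventually absorbed.
#'
#' @param fit a [KernelFit-class].
#' @param total target integral.
#' @return the rescaled [KernelFit-class].
#' @export
normalizeKernel <- function(fit, total = 1) {
  s <- total / kernelFraction(fit)
  fit@params[, c(1, 3)] <- fit@params[, c(1, 3)] * s
  fit
}

#' Read / write kernel fit fixtures
#'
#' Tab-separated fixture with one row per polar cone: `cone`, `cosLo`,
#' `cosHi`, `C`, `c`, `F`, `f`, `dOmega`, `rms`.
#'
#' @param fit a [KernelFit-class] (for writing).
#' @param path file path.
#' @param generation generation tag when reading.
#' @export
writeKernelFixture <- function(fit, path) {
  nc <- nrow(fit@params)
  write.table(data.frame(cone = seq_len(nc),
    cosLo = fit@coneCos[-1], cosHi = fit@coneCos[-(nc + 1)],
    C = fit@params[, 1], c = fit@params[, 2], F = fit@params[, 3],
    f = fit@params[, 4], dOmega = fit@coneSolidAngle, rms = fit@rms),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeKernelFixture
#' @export
readKernelFixture <- function(path, generation) {
  tab <- read.delim(path, comment.char = "#")
  nc <- nrow(tab)
  new("KernelFit", generation = generation,
    coneCos = c(tab$cosHi[1], tab$cosLo),
    params = cbind(C = tab$C, c = tab$c, F = tab$F, f = tab$f),
    coneSolidAngle = tab$dOmega, rms = tab$rms)
}

#' Packaged scatter kernels and spectra
#'
#' The precomputed first- and multiple-scatter kernel fits and scatter
#' spectra for the Ir-192 source in water, shipped as text fixtures so
#' desk-scale engine runs skip kernel regeneration (regenerate with
#' [generate1scKernel()]/[generateMscKernel()] or `scripts` in the source
#' tree).  The msc kernel is normalized to unit deposited fraction.
#'
#' @return list with elements `onesc`, `msc` ([KernelFit-class]) and
#'   `spec1sc`, `specMsc` ([PhotonSpectrum-class]).
#' @export
defaultKernels <- function() {
  if (is.null(.PHYS$kernels)) {
    ext <- function(f) system.file("extdata", f, package = "ccbrachy",
      mustWork = TRUE)
    .PHYS$kernels <- list(
      onesc = readKernelFixture(ext("kernel_1sc.tsv"), "1sc"),
      msc = readKernelFixture(ext("kernel_msc.tsv"), "msc"),
      spec1sc = readSpectrum(ext("spectrum_1sc.tsv")),
      specMsc = readSpectrum(ext("spectrum_msc.tsv")))
  }
  .PHYS$kernels
}
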