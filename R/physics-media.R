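# Media: mixture-rule coefficients, spectral averages and the eta/chi
# medium-to-water scaling factors used by the collapsed-cone transport.

#' Build a medium from its elemental composition
#'
#' Applies the mixture rule `(mu/rho)_mix(E) = sum_k w_k (mu/rho)_k(E)` (and
#' the same for `muen/rho`) over the embedded elemental tables.
#'
#' @param name medium name.
#' @param composition named numeric vector of element mass fractions
#'   (percent or fractions; normalized internally, but must sum to 1 within
#'   1e-3 after percent scaling is resolved).
#' @param density mass density in g/cm^3.
#' @return a [Medium-class] object.
#' @examples
#' buildMedium("water", c(H = 0.112, O = 0.888), 1.0)
#' @export
buildMedium <- function(name, composition, density) {
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of element mass fractions")
  unknown <- setdiff(names(composition), listElements())
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  w <- as.numeric(composition)
  if (any(w < 0)) stop("negative mass fractions")
  s <- sum(w)
  if (abs(s - 100) <= 0.1) w <- w / 100            # percent-by-weight input
  if (abs(sum(w) - 1) > 1e-3)
    stop(sprintf("mass fractions sum to %.5f; must be 1 within 1e-3", sum(w)))
  w <- w / sum(w)
  E <- energyGrid()
  mu <- muen <- pe <- inc <- coh <- numeric(length(E))
  for (i in seq_along(w)) {
    tab <- elementTable(names(composition)[i])
    mu <- mu + w[i] * tab$muRho
    muen <- muen + w[i] * tab$muenRho
    pe <- pe + w[i] * tab$muRho * tab$fracPhoto
    inc <- inc + w[i] * tab$muRho * tab$fracIncoh
    coh <- coh + w[i] * tab$muRho * tab$fracCoh
  }
  new("Medium", name = name, composition = setNames(w, names(composition)),
    density = density, energy = E, muRho = mu, muenRho = muen,
    processFractions = cbind(photo = pe / mu, incoh = inc / mu,
      coh = coh / mu))
}

#' Interpolate medium coefficients at arbitrary energies
#'
#' Log-log interpolation of the medium tables; clamped to the table range so
#' values never leave the bracketing grid entries.
#'
#' @param medium a [Medium-class].
#' @param energy energies in MeV.
#' @return data.frame with columns `energy`, `muRho`, `muenRho`,
#'   `fracPhoto`, `fracIncoh`, `fracCoh`.
#' @export
mediumCoefficients <- function(medium, energy) {
  mu <- .loglogInterp(medium@energy, medium@muRho, energy)
  muen <- .loglogInterp(medium@energy, medium@muenRho, energy)
  fr <- vapply(c("photo", "incoh", "coh"), function(p)
    .loglogInterp(medium@energy, pmax(medium@processFractions[, p], 1e-300),
      energy), numeric(length(energy)))
  fr <- matrix(fr, nrow = length(energy), ncol = 3L)
  fr <- fr / rowSums(fr)
  data.frame(energy = energy, muRho = mu, muenRho = muen,
    fracPhoto = fr[, 1], fracIncoh = fr[, 2], fracCoh = fr[, 3])
}

#' Phantom media library
#'
#' The three benchmark media: water, cortical bone and dry air, with their
#' standard compositions (percent by weight) and densities.
#'
#' @return named list of [Medium-class] objects
#'   (`water`, `cortical_bone`, `air`).
#' @export
mediaLibrary <- function() {
  if (is.null(.PHYS$media)) .PHYS$media <- list(
    water = buildMedium("water", c(H = 11.2, O = 88.8), 1.00),
    cortical_bone = buildMedium("cortical_bone",
      c(H = 3.4, C = 15.5, N = 4.2, O = 43.5, Na = 0.1, Mg = 0.2,
        P = 10.3, S = 0.3, Ca = 22.5), 1.92),
    air = buildMedium("air", c(N = 75.5, O = 23.2, Ar = 1.3), 1.20e-3))
  .PHYS$media
}

#' Read / write a keyed-text media library
#'
#' One block per medium: `name <name>`, `density <g/cm3>`, then
#' `element fraction` pairs (percent by weight), blocks separated by blank
#' lines.
#'
#' @param path file path.
#' @param media named list of [Medium-class] objects (for writing).
#' @return for reading, a named list of [Medium-class] objects.
#' @export
readMediaLibrary <- function(path) {
  lines <- trimws(readLines(path))
  blocks <- split(lines, cumsum(lines == ""))
  out <- list()
  for (b in blocks) {
    b <- b[nzchar(b) & !startsWith(b, "#")]
    if (!length(b)) next
    kv <- strsplit(b, "\\s+")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    nm <- vals[keys == "name"]
    dens <- as.numeric(vals[keys == "density"])
    el <- keys[!keys %in% c("name", "density")]
    fr <- as.numeric(vals[!keys %in% c("name", "density")])
    out[[nm]] <- buildMedium(nm, setNames(fr, el), dens)
  }
  out
}

#' @rdname readMediaLibrary
#' @export
writeMediaLibrary <- function(media, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in media) {
    cat(sprintf("name %s\ndensity %.6g\n", m@name, m@density), file = con)
    cat(sprintf("%s %.6g\n", names(m@composition), 100 * m@composition),
      sep = "", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Spectrum-averaged interaction coefficients
#'
#' Fluence-weighted averages of the mass attenuation and mass
#' energy-absorption coefficients of a medium over a discrete photon
#' spectrum.
#'
#' @param medium a [Medium-class].
#' @param spectrum a [PhotonSpectrum-class].
#' @return named numeric: `muRho`, `muenRho` (cm^2/g).
#' @export
spectralAverage <- function(medium, spectrum) {
  stopifnot(is(spectrum, "PhotonSpectrum"))
  co <- mediumCoefficients(medium, spectrum@energy)
  c(muRho = sum(spectrum@weight * co$muRho),
    muenRho = sum(spectrum@weight * co$muenRho))
}

#' Medium-to-water scaling factors chi and eta
#'
#' `chiFactor` is the ratio of spectrum-averaged *linear* energy absorption
#' of the medium to that of water,
#' `chi = (rho_m / rho_w) * [muen/rho]_m / [muen/rho]_w`, with both averages
#' taken over the same scatter-generation spectrum.  `etaFactor` is the
#' analogous ratio of spectrum-averaged linear attenuation.  Both equal 1
#' for water by construction.
#'
#' @param medium a [Medium-class].
#' @param spectrum a [PhotonSpectrum-class] (typically the first- or
#'   multiple-scatter spectrum).
#' @param water the reference water [Medium-class].
#' @return a single numeric scaling factor.
#' @export
chiFactor <- function(medium, spectrum, water = mediaLibrary()$water) {
  (medium@density / water@density) *
    spectralAverage(medium, spectrum)[["muenRho"]] /
    spectralAverage(water, spectrum)[["muenRho"]]
}

#' @rdname chiFactor
#' @export
etaFactor <- function(medium, spectrum, water = mediaLibrary()$water) {
  (medium@density / water@density) *
    spectralAverage(medium, spectrum)[["muRho"]] /
    spectralAverage(water, spectrum)[["muRho"]]
}

#' Effective interaction coefficients fitted over a distance range
#'
#' Instead of taking spectrum-averaged coefficients at a single depth, fit a
#' single effective attenuation coefficient to the full spectral primary
#' attenuation sampled at several radii, by unweighted least squares on the
#' transmission, and report the matching spectrum-averaged energy-absorption
#' coefficient from the hardened spectra over the range.  This accounts for
#' beam hardening with distance from the source.
#'
#' @param medium a [Medium-class].
#' @param spectrum the source emission [PhotonSpectrum-class].
#' @param range numeric(2) radial range in cm.
#' @param nSamples number of radii sampled across the range (>= 10).
#' @return named numeric: effective `muRho` and `muenRho` (cm^2/g).
#' @export
fitCoeffsOverDistance <- function(medium, spectrum, range = c(0, 10),
                                  nSamples = 11L) {
  stopifnot(length(range) == 2L, all(range >= 0))
  co <- mediumCoefficients(medium, spectrum@energy)
  rho <- medium@density
  if (diff(range) <= 0) {
    warning("degenerate range; using the point spectrum at depth ",
      range[1])
    att <- spectrum@weight * exp(-co$muRho * rho * range[1])
    w <- att / sum(att)
    return(c(muRho = sum(w * co$muRho), muenRho = sum(w * co$muenRho)))
  }
  nSamples <- max(10L, as.integer(nSamples))
  r <- seq(range[1], range[2], length.out = nSamples)
  # spectral transmission of primary energy fluence at each radius
  trans <- vapply(r, function(ri)
    sum(spectrum@weight * spectrum@energy * exp(-co$muRho * rho * ri)) /
      sum(spectrum@weight * spectrum@energy), numeric(1))
  sse <- function(mu) sum((exp(-mu * rho * r) - trans)^2)
  muEff <- optimize(sse, c(min(co$muRho) * 0.5, max(co$muRho) * 1.5),
    tol = 1e-10)$minimum
  # energy-absorption: average of the hardened-spectrum values over range
  muenEff <- mean(vapply(r, function(ri) {
    att <- spectrum@weight * spectrum@energy * exp(-co$muRho * rho * ri)
    sum(att * co$muenRho) / sum(att)
  }, numeric(1)))
  c(muRho = muEff, muenRho = muenEff)
}
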