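# Elemental photon interaction coefficients, 1 keV - 1.5 MeV.
#
# The tables are produced by the package's analytic cross-section model:
# exact free-electron Klein-Nishina incoherent scattering (total and
# energy-transfer cross sections by numerical angular integration) plus
# power-law photoelectric and coherent terms whose constants were calibrated
# once against published water, bone and air attenuation/absorption data.
# Radiative losses are neglected (photon energies <= 1.5 MeV, low-Z media),
# so the energy-absorption and energy-transfer coefficients coincide.

.PHYS <- new.env(parent = emptyenv())

.RE2 <- 7.940787e-26      # classical electron radius squared, cm^2
.NA_AVOGADRO <- 6.022141e23
.MEC2 <- 0.5109989        # electron rest energy, MeV

# photoelectric per atom (cm^2): p1 * Z^4 * E_keV^-p3 * (1 + p4 * k)
.PE_PAR <- c(1.27586e-22, 4.0, 3.5513, 7.31968)
# coherent per atom (cm^2): q1 * Z^2.5 * E_keV^-q3
.COH_PAR <- c(7.50275e-24, 2.5, 2.11943)

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Ar", "Ca"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 18, 20),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
        39.948, 40.078))

#' Package energy grid
#'
#' Log-spaced photon energy grid (MeV) on which all interaction coefficient
#' tables are evaluated; off-grid values are obtained by log-log
#' interpolation.
#'
#' @param n number of grid points.
#' @return numeric vector of energies in MeV.
#' @export
energyGrid <- function(n = 160L) exp(seq(log(1e-3), log(1.5), length.out = n))

# Klein-Nishina per-electron total and energy-transfer cross sections (cm^2)
# by numeric integration over the scattering angle.
.knSigma <- function(E) {
  mu <- seq(-1, 1, length.out = 2001)
  out <- vapply(E, function(e) {
    k <- e / .MEC2
    eps <- 1 / (1 + k * (1 - mu))
    ds <- 0.5 * .RE2 * eps^2 * (eps + 1 / eps - (1 - mu^2))
    h <- diff(mu)
    trapz <- function(y) sum(h * (y[-1] + y[-length(y)]) / 2)
    c(2 * pi * trapz(ds), 2 * pi * trapz(ds * (1 - eps)))
  }, numeric(2))
  list(total = out[1, ], transfer = out[2, ])
}

.peAtom <- function(Z, E)
  .PE_PAR[1] * Z^.PE_PAR[2] * (E * 1e3)^(-.PE_PAR[3]) * (1 + .PE_PAR[4] * E / .MEC2)

.cohAtom <- function(Z, E)
  .COH_PAR[1] * Z^.COH_PAR[2] * (E * 1e3)^(-.COH_PAR[3])

#' Chemical elements with embedded coefficient tables
#' @return character vector of element symbols.
#' @export
listElements <- function() .ELEMENTS$symbol

#' Elemental photon interaction coefficients
#'
#' Mass attenuation and mass energy-absorption coefficients for a chemical
#' element on the package energy grid, with per-process fractions
#' (photoelectric, incoherent, coherent) of the total cross section.
#'
#' @param symbol element symbol (one of [listElements()]).
#' @return data.frame with columns `energy` (MeV), `muRho`, `muenRho`
#'   (cm^2/g), `fracPhoto`, `fracIncoh`, `fracCoh`.
#' @export
elementTable <- function(symbol) {
  key <- paste0("el_", symbol)
  if (!is.null(.PHYS[[key]])) return(.PHYS[[key]])
  i <- match(symbol, .ELEMENTS$symbol)
  if (is.na(i))
    stop("unknown element '", symbol, "'; available: ",
         paste(listElements(), collapse = ", "))
  Z <- .ELEMENTS$Z[i]; A <- .ELEMENTS$A[i]
  E <- energyGrid()
  kn <- .knGrid()
  inc <- .NA_AVOGADRO * Z / A * kn$total
  inctr <- .NA_AVOGADRO * Z / A * kn$transfer
  pe <- .NA_AVOGADRO / A * .peAtom(Z, E)
  coh <- .NA_AVOGADRO / A * .cohAtom(Z, E)
  tot <- inc + pe + coh
  tab <- data.frame(energy = E, muRho = tot, muenRho = inctr + pe,
    fracPhoto = pe / tot, fracIncoh = inc / tot, fracCoh = coh / tot)
  .PHYS[[key]] <- tab
  tab
}

.knGrid <- function() {
  if (is.null(.PHYS$kn)) .PHYS$kn <- .knSigma(energyGrid())
  .PHYS$kn
}

# log-log interpolation of a tabulated positive quantity; clamped at the
# grid ends so interpolation never leaves the bracketing table values.
.loglogInterp <- function(Egrid, val, E) {
  lE <- log(pmin(pmax(E, Egrid[1]), Egrid[length(Egrid)]))
  exp(approx(log(Egrid), log(val), xout = lE, rule = 2)$y)
}

#' Write elemental coefficient fixtures
#'
#' Writes the embedded per-element tables as a single tab-separated file
#' (long format) for external inspection.
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeElementTables <- function(path) {
  tabs <- lapply(listElements(), function(s)
    cbind(symbol = s, elementTable(s)))
  write.table(do.call(rbind, tabs), path, sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}
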