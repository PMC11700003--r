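# Photon spectra: constructor, file I/O and the packaged Ir-192 line
# spectrum.

#' Create a photon spectrum
#'
#' @param energy photon energies in MeV.
#' @param weight relative emission or fluence probabilities (normalized to
#'   unit sum; need not be normalized on input).
#' @return a [PhotonSpectrum-class].
#' @export
photonSpectrum <- function(energy, weight) {
  if (length(energy) == 0L) stop("empty spectrum")
  o <- order(energy)
  energy <- energy[o]; weight <- weight[o]
  s <- sum(weight)
  if (s <= 0) stop("spectrum weights must have positive sum")
  new("PhotonSpectrum", energy = energy, weight = weight / s)
}

#' Mean energy of a spectrum
#' @param spectrum a [PhotonSpectrum-class].
#' @return mean energy in MeV.
#' @export
meanEnergy <- function(spectrum) sum(spectrum@energy * spectrum@weight)

#' Packaged Ir-192 emission spectrum
#'
#' Discrete bare-point-source line spectrum of Ir-192 (principal gamma lines
#' plus the strongest K X-ray lines of the daughters), shipped as a
#' tab-separated fixture.  Weights are per-decay emission probabilities,
#' normalized to unit sum.  Source encapsulation and self-absorption are not
#' modeled.
#'
#' @return a [PhotonSpectrum-class].
#' @export
irSpectrum <- function() {
  if (is.null(.PHYS$ir192))
    .PHYS$ir192 <- readSpectrum(system.file("extdata", "ir192_spectrum.tsv",
      package = "ccbrachy", mustWork = TRUE))
  .PHYS$ir192
}

#' Read / write a spectrum as tab-separated text
#'
#' Columns `energy` (MeV) and `weight`.
#'
#' @param path file path.
#' @param spectrum a [PhotonSpectrum-class] (for writing).
#' @export
readSpectrum <- function(path) {
  tab <- read.delim(path, comment.char = "#")
  photonSpectrum(tab$energy, tab$weight)
}

#' @rdname readSpectrum
#' @export
writeSpectrum <- function(spectrum, path) {
  write.table(data.frame(energy = spectrum@energy, weight = spectrum@weight),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
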