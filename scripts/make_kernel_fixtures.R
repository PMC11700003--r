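#!/usr/bin/env Rscript
# Regenerates the packaged kernel and scatter-spectrum fixtures under
# inst/extdata from the package's own forced-interaction kernel Monte Carlo
# and the in-phantom spectral tally.  Run from the repository root with the
# package installed or loadable via devtools.

if (requireNamespace("devtools", quietly = TRUE) &&
    file.exists("DESCRIPTION")) {
  devtools::load_all(quiet = TRUE)
} else {
  library(ccbrachy)
}

out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

t1 <- generate1scKernel(nHistories = 2e6, seed = 101)
f1 <- fitKernel(t1)
tm <- generateMscKernel(t1@spectrum, nHistories = 1e6, seed = 102)
fm <- normalizeKernel(fitKernel(tm), 1)

# scaling spectra: scatter energy fluence at 1-10 cm depth in the
# desk-scale water phantom
ss <- scatterSpectraAtDepth(waterPhantom(0.25, 30.25), irSpectrum(),
  nHistories = 1e6, seed = 103, shell = c(1, 10))

writeKernelFixture(f1, file.path(out, "kernel_1sc.tsv"))
writeKernelFixture(fm, file.path(out, "kernel_msc.tsv"))
writeSpectrum(ss$spec1sc, file.path(out, "spectrum_1sc.tsv"))
writeSpectrum(ss$specMsc, file.path(out, "spectrum_msc.tsv"))

cat(sprintf("1sc kernel: deposited %.4f escaped %.4f of released; rms max %.3f\n",
  sum(t1@energy), sum(t1@escapeCone), max(f1@rms)))
cat(sprintf("msc kernel: deposited %.4f escaped %.4f of released; rms max %.3f\n",
  sum(tm@energy), sum(tm@escapeCone), max(fm@rms)))
cat(sprintf("spectra: 1sc mean %.1f keV, msc mean %.1f keV\n",
  1000 * meanEnergy(ss$spec1sc), 1000 * meanEnergy(ss$specMsc)))
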