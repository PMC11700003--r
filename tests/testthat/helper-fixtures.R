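# Shared small fixtures, built once per test session.

# fast low-statistics kernel set for engine tests (not used for the
# benchmark comparisons, which load the packaged fixtures)
tinyKernels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      t1 <- generate1scKernel(nHistories = 5e4, seed = 11)
      tm <- generateMscKernel(t1@spectrum, nHistories = 5e4, seed = 12)
      cache <<- list(onesc = fitKernel(t1),
        msc = normalizeKernel(fitKernel(tm), 1),
        spec1sc = t1@spectrum, specMsc = tm@spectrum,
        tally1sc = t1, tallyMsc = tm)
    }
    cache
  }
})

# flat-spectrum helper
flatSpectrum <- function(E) photonSpectrum(E, rep(1, length(E)))

# small homogeneous phantom of an arbitrary medium
uniformPhantom <- function(medium, n = 21L, voxel = 0.2) {
  voxelPhantom(rep(n, 3L), voxel, rep(-n * voxel / 2, 3),
    rep(1L, n^3), setNames(list(medium), medium@name))
}
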