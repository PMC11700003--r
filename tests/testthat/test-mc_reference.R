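# Monte Carlo reference: bookkeeping, estimators and uncertainties.

test_that("bookkeeping numbers follow the generation rules", {
  expect_identical(assignBkn(event = "source"), 0L)
  expect_identical(assignBkn(0L, "compton"), 1L)
  expect_identical(assignBkn(1L, "compton"), 2L)
  expect_identical(assignBkn(2L, "charged"), 2L)
  expect_identical(assignBkn(1L, "bremsstrahlung"), 2L)
  expect_identical(assignBkn(0L, "rayleigh"), 1L)
  expect_identical(assignBkn(0L, "rayleigh", rayleighIncrements = FALSE), 0L)
  expect_error(assignBkn(NULL, "compton"), "parent")
})

test_that("generation tallies sum to the total bit-exactly", {
  ph <- waterPhantom(0.4, 8.4)
  mc <- runMC(ph, irSpectrum(), 2e4, seed = 2)
  tot <- doseComponent(mc, "tot")
  comp <- doseComponent(mc, "prim") + doseComponent(mc, "1sc") +
    doseComponent(mc, "msc")
  expect_identical(as.numeric(tot), as.numeric(comp))
})

test_that("fixed seeds give bit-identical tallies", {
  ph <- waterPhantom(0.4, 8.4)
  a <- runMC(ph, irSpectrum(), 1e4, seed = 5)
  b <- runMC(ph, irSpectrum(), 1e4, seed = 5)
  expect_identical(a@kerma, b@kerma)
  expect_identical(a@counters, b@counters)
  c <- runMC(ph, irSpectrum(), 1e4, seed = 6)
  expect_false(identical(a@kerma, c@kerma))
})

test_that("primary kerma matches the ray-trace closed form within k = 2", {
  ph <- waterPhantom(0.2, 12.2)
  sp <- irSpectrum()
  mask <- local({
    ctr <- voxelCenters(ph)
    d <- sqrt(outer(outer(ctr$x^2, ctr$y^2, "+"), ctr$z^2, "+"))
    d > 1 & d < 5.8
  })
  mc <- runMC(ph, sp, 2e5, seed = 7, regions = list(shell = mask))
  eng <- computePrimary(ph, sp)$dose
  mcPrim <- doseComponent(mc, "prim")
  relUnc <- mcUncertainty(mc, "shell", "prim")
  expect_lt(relUnc, 0.01)
  expect_equal(mean(mcPrim[mask]), mean(eng[mask]),
    tolerance = max(2 * relUnc, 1e-3))
  # also pointwise along the axis at moderate radii
  ic <- 31L
  for (ix in c(36L, 41L, 46L)) {
    expect_equal(mcPrim[ix, ic, ic], eng[ix, ic, ic], tolerance = 0.1)
  }
})

test_that("forced and analog estimators agree within combined k = 2", {
  ph <- waterPhantom(0.4, 8.4)
  sp <- irSpectrum()
  mask <- array(TRUE, ph@dims)
  f <- runMC(ph, sp, 4e4, seed = 9, forcing = TRUE,
    regions = list(all = mask))
  a <- runMC(ph, sp, 2e5, seed = 10, forcing = FALSE,
    regions = list(all = mask))
  for (g in c("prim", "tot")) {
    mf <- mcRegionMean(f, mask, g); ma <- mcRegionMean(a, mask, g)
    unc <- sqrt((mf * mcUncertainty(f, "all", g))^2 +
                (ma * mcUncertainty(a, "all", g))^2)
    expect_lt(abs(mf - ma), max(2 * unc, 0.02 * mf))
  }
})

test_that("region uncertainty scales like one over root n histories", {
  ph <- waterPhantom(0.4, 8.4)
  mask <- array(TRUE, ph@dims)
  u1 <- mcUncertainty(runMC(ph, irSpectrum(), 2e4, seed = 21,
    regions = list(all = mask)), "all", "tot")
  u4 <- mcUncertainty(runMC(ph, irSpectrum(), 8e4, seed = 22,
    regions = list(all = mask)), "all", "tot")
  expect_equal(u4 / u1, 0.5, tolerance = 0.25)
})

test_that("a single-voxel region reproduces the per-voxel estimate", {
  ph <- waterPhantom(0.4, 8.4)
  mask <- array(FALSE, ph@dims)
  mask[13, 11, 11] <- TRUE
  mc <- runMC(ph, irSpectrum(), 5e4, seed = 12, regions = list(one = mask))
  exact <- mcUncertainty(mc, "one", "prim")
  perVox <- mcUncertainty(mc, mask, "prim")
  expect_equal(exact, perVox, tolerance = 1e-9)
})

test_that("tally merging is exactly associative", {
  ph <- waterPhantom(0.4, 6.8)
  mask <- array(TRUE, ph@dims)
  t1 <- runMC(ph, irSpectrum(), 1e4, seed = 31, regions = list(all = mask))
  t2 <- runMC(ph, irSpectrum(), 1e4, seed = 32, regions = list(all = mask))
  t3 <- runMC(ph, irSpectrum(), 1e4, seed = 33, regions = list(all = mask))
  left <- mergeTallies(mergeTallies(t1, t2), t3)
  right <- mergeTallies(t1, mergeTallies(t2, t3))
  expect_equal(left@kerma, right@kerma, tolerance = 1e-12)
  expect_equal(left@sumsq, right@sumsq, tolerance = 1e-12)
  expect_identical(left@nHistories, right@nHistories)
  # merged tally agrees with a single longer run statistically
  big <- runMC(ph, irSpectrum(), 3e4, seed = 34, regions = list(all = mask))
  ml <- mcRegionMean(left, mask); mb <- mcRegionMean(big, mask)
  unc <- sqrt((ml * mcUncertainty(left, "all"))^2 +
              (mb * mcUncertainty(big, "all"))^2)
  expect_lt(abs(ml - mb), max(3 * unc, 0.05 * mb))
})

test_that("energy bookkeeping closes within the estimator variance", {
  ph <- waterPhantom(0.4, 8.4)
  mc <- runMC(ph, irSpectrum(), 5e4, seed = 13, forcing = FALSE)
  cn <- mc@counters
  expect_equal(cn[["emitted"]],
    cn[["absorbed"]] + cn[["escaped"]] + cn[["cutoff"]] + cn[["rrLost"]],
    tolerance = 0.02)
  # kerma-integrated absorbed energy agrees with the absorbed counter
  rhoV <- array(ph@density, ph@dims) * ph@voxelSize^3
  dep <- sum(doseComponent(mc, "tot") * rhoV) * mc@nHistories
  expect_equal(dep, cn[["absorbed"]], tolerance = 0.05)
})

test_that("invalid inputs are rejected", {
  ph <- waterPhantom(0.4, 6.8)
  expect_error(runMC(ph, irSpectrum(), 0), "nHistories")
  expect_error(runMC(ph, irSpectrum(), 10, seed = NA), "seed")
})
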