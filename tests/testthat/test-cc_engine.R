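# Primary ray trace, scerma chain and the collapsed-cone line transport.

test_that("primary dose follows the inverse square law in near-vacuum", {
  air <- mediaLibrary()$air
  ph <- uniformPhantom(air, n = 31L, voxel = 0.2)
  pr <- computePrimary(ph, photonSpectrum(0.3565, 1))
  ic <- 16L
  d1 <- pr$dose[ic + 5L, ic, ic]   # 1 cm
  d2 <- pr$dose[ic + 10L, ic, ic]  # 2 cm
  expect_equal(d1 / d2, 4, tolerance = 1e-3)
})

test_that("primary dose matches the homogeneous closed form", {
  ph <- waterPhantom(0.2, 10.2)
  sp <- photonSpectrum(0.3565, 1)
  pr <- computePrimary(ph, sp)
  co <- mediumCoefficients(mediaLibrary()$water, 0.3565)
  ctr <- voxelCenters(ph)
  ix <- 28:48
  d <- ctr$x[ix]
  cf <- pr$dose[ix, 26, 26] * d^2 * exp(co$muRho * d)
  expect_lt(diff(range(cf)) / mean(cf), 1e-6)
})

test_that("primary attenuation through the bone slab matches the segment oracle", {
  phA <- buildCase("A", 0.2, 16.2, snapBox = TRUE)
  phW <- waterPhantom(0.2, 16.2)
  sp <- photonSpectrum(0.3565, 1)
  co <- lapply(phA@media, mediumCoefficients, energy = 0.3565)
  prA <- computePrimary(phA, sp)$dose
  prW <- computePrimary(phW, sp)$dose
  ic <- 41L
  # voxel center at x = 7.9 cm: bone spans [4.9, 7.1] on the snapped grid
  x <- 7.9
  ix <- ic + as.integer(x / 0.2)
  extra <- (co$cortical_bone$muRho * 1.92 - co$water$muRho) * (7.1 - 4.9)
  ratio <- prA[ix, ic, ic] / prW[ix, ic, ic] *
    (co$water$muenRho / co$water$muenRho)
  expect_equal(ratio, exp(-extra), tolerance = 1e-6)
})

test_that("first-scatter scerma obeys the mu ratios", {
  ph <- waterPhantom(0.2, 6.2)
  sp <- photonSpectrum(0.3565, 1)
  pr <- computePrimary(ph, sp)
  s1 <- computeScerma1sc(pr$field, ph)
  co <- mediumCoefficients(mediaLibrary()$water, 0.3565)
  expect_equal(s1[20, 16, 16] / pr$dose[20, 16, 16],
    (co$muRho - co$muenRho) / co$muenRho, tolerance = 1e-12)

  # a hypothetical pure absorber (muen = mu) releases no scatter energy
  pure <- mediaLibrary()$water
  pure@muenRho <- pure@muRho
  pure@name <- "absorber"
  php <- uniformPhantom(pure, n = 15L)
  prp <- computePrimary(php, sp)
  s1p <- computeScerma1sc(prp$field, php)
  expect_true(all(s1p == 0))
})

test_that("second-scatter scerma scales the first-scatter dose by medium ratios", {
  k <- tinyKernels()
  ph <- buildCase("B", 0.2, 8.2, snapBox = TRUE)
  d1 <- array(1, ph@dims)
  s2 <- computeScerma2sc(ph, d1, k$spec1sc)
  ratio <- function(m) {
    av <- spectralAverage(m, k$spec1sc)
    (av[["muRho"]] - av[["muenRho"]]) / av[["muenRho"]]
  }
  w <- which(array(ph@medium, ph@dims) == 1L)[1]
  b <- which(array(ph@medium, ph@dims) == 2L)[1]
  expect_equal(s2[w], ratio(mediaLibrary()$water), tolerance = 1e-12)
  expect_equal(s2[b], ratio(mediaLibrary()$cortical_bone), tolerance = 1e-12)
  # bone converts less of its absorbed dose back into scatter than water
  expect_lt(s2[b], s2[w])
  expect_true(all(computeScerma2sc(ph, array(0, ph@dims), k$spec1sc) == 0))
})

test_that("the msc recursion conserves energy per step in both modes", {
  set.seed(31)
  for (mode in c("original", "corrected")) {
    steps <- data.frame(
      dl = rep(0.23, 40),
      rho = sample(c(1, 1.92, 1.2e-3), 40, replace = TRUE),
      scerma = runif(40, 0, 2),
      eta = sample(c(1, 2.1, 1.1e-3), 40, replace = TRUE),
      chiOverEta = sample(c(1, 1.45, 0.98), 40, replace = TRUE))
    out <- mscLineRecursion(steps, C = 0.02, cc = 0.08, dOmega = 0.17,
      dlMax = 0.23, mode = mode, R0 = 0.4)
    Rin <- c(0.4, out$R[-40])
    # R_in + released = absorbed + R_out, including the Rcorr balance
    lhs <- Rin + out$sigma * steps$dl
    rhs <- out$absorbedFluence + out$R
    expect_lt(max(abs(lhs - rhs) / pmax(lhs, 1e-300)), 1e-12)
  }
})

test_that("chi/eta > 1 steps absorb more and transmit less when corrected", {
  steps <- data.frame(dl = 0.2, rho = 1.92, scerma = 1.5, eta = 2.1,
    chiOverEta = 1.45)
  o <- mscLineRecursion(steps, 0.02, 0.08, 0.17, 0.2, "original", R0 = 1)
  c <- mscLineRecursion(steps, 0.02, 0.08, 0.17, 0.2, "corrected", R0 = 1)
  expect_gt(c$dose, o$dose)
  expect_lt(c$R, o$R)
  # reversed for chi/eta < 1
  steps$chiOverEta <- 0.9
  o2 <- mscLineRecursion(steps, 0.02, 0.08, 0.17, 0.2, "original", R0 = 1)
  c2 <- mscLineRecursion(steps, 0.02, 0.08, 0.17, 0.2, "corrected", R0 = 1)
  expect_lt(c2$dose, o2$dose)
  expect_gt(c2$R, o2$R)
})

test_that("compiled line transport matches the reference recursion", {
  # single-row phantom, one axis-aligned direction, uniform kernel cones
  n <- 31L
  bone <- mediaLibrary()$cortical_bone
  med <- rep(1L, n); med[20:25] <- 2L
  ph <- voxelPhantom(c(n, 1L, 1L), 0.2, c(-n * 0.1, -0.1, -0.1),
    med, mediaLibrary()[c("water", "cortical_bone")])
  set.seed(5)
  scerma <- array(runif(n), c(n, 1, 1))
  spec <- photonSpectrum(c(0.1, 0.3), c(1, 1))
  kern <- new("KernelFit", generation = "msc",
    coneCos = seq(1, -1, length.out = 5),
    params = matrix(rep(c(0.02, 0.09, 0.004, 0.03), each = 4), 4),
    coneSolidAngle = rep(pi, 4), rms = rep(0, 4))
  for (mode in c("original", "corrected")) {
    dose <- .ccTransport(ph, scerma, kern, spec, nDirs = NULL,
      corrected = identical(mode, "corrected"),
      directions = matrix(c(1, 0, 0), 1))
    eta <- etaFactor(bone, spec); chi <- chiFactor(bone, spec)
    stepdf <- data.frame(dl = 0.2, rho = ph@density,
      scerma = as.numeric(scerma),
      eta = c(1, eta)[ph@medium],
      chiOverEta = c(1, chi / eta)[ph@medium])
    refC <- mscLineRecursion(stepdf, 0.02, 0.09, 4 * pi, 0.2, mode)
    refF <- mscLineRecursion(stepdf, 0.004, 0.03, 4 * pi, 0.2, mode)
    expect_equal(as.numeric(dose), refC$dose + refF$dose,
      tolerance = 1e-12)
  }
})

test_that("corrected and original transport coincide bitwise in water", {
  k <- tinyKernels()
  ph <- waterPhantom(0.2, 6.2)
  set.seed(8)
  s2 <- array(runif(prod(ph@dims)), ph@dims)
  a <- transportMsc(ph, s2, k, 24L, "original")
  b <- transportMsc(ph, s2, k, 24L, "corrected")
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("the transport balances released, absorbed and escaped energy", {
  k <- tinyKernels()
  ph <- buildCase("B", 0.2, 8.2, snapBox = TRUE)
  set.seed(9)
  s2 <- array(runif(prod(ph@dims)), ph@dims)
  for (mode in c("original", "corrected")) {
    d <- transportMsc(ph, s2, k, 72L, mode)
    b <- attr(d, "balance")
    # per-line conservation closes exactly
    expect_equal(b[["absorbed"]] + b[["escaped"]], b[["released"]],
      tolerance = 1e-12)
    # released equals the scerma integral within the direction quadrature
    expect_equal(b[["released"]], sum(s2 * ph@density) * ph@voxelSize^3,
      tolerance = 5e-3)
    # absorbed matches the dose grid integral
    expect_equal(sum(d * ph@density) * ph@voxelSize^3, b[["absorbed"]],
      tolerance = 1e-9)
  }
})

test_that("the correction redistributes rather than creates energy", {
  k <- tinyKernels()
  ph <- buildCase("B", 0.25, 20.25, snapBox = TRUE)
  pr <- computePrimary(ph, irSpectrum())
  s1 <- computeScerma1sc(pr$field, ph)
  d1 <- transport1sc(ph, s1, k, 48L)
  s2 <- computeScerma2sc(ph, d1, k$spec1sc)
  dO <- transportMsc(ph, s2, k, 24L, "original")
  dC <- transportMsc(ph, s2, k, 24L, "corrected")
  rhoV <- array(ph@density, ph@dims) * ph@voxelSize^3
  net <- sum((dC - dO) * rhoV)
  expect_lt(abs(net) / sum(dC * rhoV), 0.01)
})

test_that("point scerma produces dose confined to the cone lattice lines", {
  k <- tinyKernels()
  ph <- waterPhantom(0.2, 8.2)
  s <- array(0, ph@dims)
  s[21, 21, 21] <- 1   # single release voxel at the center
  d <- transportMsc(ph, s, k, 16L, "corrected")
  # a small direction set leaves most voxels untouched: the spiky pattern
  expect_lt(mean(d > 0), 0.25)
  expect_gt(sum(d), 0)
})

test_that("mode flip changes only the msc component; runs are deterministic", {
  k <- tinyKernels()
  ph <- buildCase("C", 0.2, 6.2, snapBox = TRUE)
  res <- runEngine(ph, irSpectrum(), k, nDirs1sc = 24L, nDirsMsc = 12L,
    modes = c("original", "corrected"))
  expect_identical(res$original@prim, res$corrected@prim)
  expect_identical(res$original@onesc, res$corrected@onesc)
  expect_false(identical(res$original@msc, res$corrected@msc))
  expect_identical(res$original@tot,
    res$original@prim + res$original@onesc + res$original@msc)
  rerun <- runEngine(ph, irSpectrum(), k, nDirs1sc = 24L, nDirsMsc = 12L,
    modes = "original")
  expect_identical(rerun@msc, res$original@msc)
})
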