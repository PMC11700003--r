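# Benchmark phantom geometry, ray tracing and the transport line lattice.

test_that("case builders reproduce the benchmark geometry", {
  ph <- buildCase("A", voxelSize = 0.1)
  expect_identical(ph@dims, rep(301L, 3))
  expect_equal(ph@box$lo, c(4.95, -1.05, -1.55))
  expect_equal(ph@box$hi, c(7.05, 1.05, 1.55))
  # all box faces on voxel boundaries
  expect_true(all(abs((c(ph@box$lo, ph@box$hi) - rep(ph@origin, 2)) /
    ph@voxelSize - round((c(ph@box$lo, ph@box$hi) - rep(ph@origin, 2)) /
    ph@voxelSize)) < 1e-9))
  expect_identical(sum(boxMask(ph)), 21L * 21L * 31L)
  expect_identical(sum(ph@medium == 2L), 21L * 21L * 31L)

  phC <- buildCase("C", voxelSize = 0.1)
  expect_equal(phC@media[[2]]@density, 1.20e-3)
  expect_equal(unique(phC@density[boxMask(phC)]), 1.20e-3)
  expect_equal(phC@box$lo[1], 1.95)
})

test_that("case builders are deterministic and water-identical outside the box", {
  a1 <- buildCase("B", 0.2, 16.2, snapBox = TRUE)
  a2 <- buildCase("B", 0.2, 16.2, snapBox = TRUE)
  expect_identical(a1@medium, a2@medium)
  expect_identical(a1@density, a2@density)
  w <- waterPhantom(0.2, 16.2)
  outside <- !boxMask(a1)
  expect_true(all(a1@medium[outside] == 1L))
  expect_identical(a1@density[outside], w@density[outside])
  # replacing the box medium by water recovers the homogeneous phantom
  a1@medium[] <- 1L
  a1@density[] <- 1.0
  expect_identical(array(a1@medium, a1@dims), array(w@medium, w@dims))
})

test_that("misaligned voxel sizes are rejected with the boundary rule", {
  expect_error(buildCase("A", voxelSize = 0.2, side = 16.2),
    "boundary")
  expect_error(waterPhantom(0.2, 16.0), "odd")
  ph <- buildCase("A", 0.2, 16.2, snapBox = TRUE)
  onGrid <- abs((c(ph@box$lo, ph@box$hi) - rep(ph@origin, 2)) /
    ph@voxelSize - round((c(ph@box$lo, ph@box$hi) - rep(ph@origin, 2)) /
    ph@voxelSize)) < 1e-9
  expect_true(all(onGrid))
})

test_that("radiological path matches closed forms and segment sums", {
  ph <- waterPhantom(0.1, 12.1)
  expect_equal(radiologicalPath(ph, c(0, 0, 0), c(5, 0, 0),
    muLinear = c(water = 0.1)), 0.5, tolerance = 1e-9)
  expect_equal(radiologicalPath(ph, c(0, 0, 0), c(0, 0, 0)), 0)

  # Case A along +x at y = z = 0: water up to 4.95, bone 4.95-7.05
  phA <- buildCase("A", 0.1, 30.1)
  muW <- 0.1; muB <- 0.25
  got <- radiologicalPath(phA, c(0, 0, 0), c(10, 0, 0),
    muLinear = c(water = muW, cortical_bone = muB))
  # hand-summed analytic segments (oracle)
  oracleTau <- muW * 4.95 + muB * (7.05 - 4.95) + muW * (10 - 7.05)
  expect_equal(got, oracleTau, tolerance = 1e-9)
  # direction reversal symmetry
  rev <- radiologicalPath(phA, c(10, 0, 0), c(0, 0, 0),
    muLinear = c(water = muW, cortical_bone = muB))
  expect_equal(rev, got, tolerance = 1e-9)
})

test_that("cone direction sets partition the sphere into equal solid angles", {
  for (m in c(8L, 72L, 320L)) {
    cs <- coneDirections(m)
    expect_identical(nrow(cs$directions), m)
    expect_equal(sum(cs$solidAngle), 4 * pi, tolerance = 1e-9)
    expect_equal(max(abs(rowSums(cs$directions^2) - 1)), 0, tolerance = 1e-12)
    expect_equal(cs$solidAngle, rep(4 * pi / m, m))
  }
})

test_that("line lattice covers every voxel with constant step length", {
  ph <- voxelPhantom(c(11L, 11L, 11L), 0.2, rep(-1.1, 3), rep(1L, 11^3),
    mediaLibrary()["water"])
  # axis-aligned direction: every step has dl = voxelSize
  ax <- buildLineLattice(ph, matrix(c(1, 0, 0), 1))[[1]]
  expect_equal(ax@dlMax, 0.2)
  expect_true(all(ax@steps$dl == 0.2))
  expect_identical(sort(unique(ax@steps$voxel)), 1:(11L^3))

  # oblique direction: brute-force accumulation of per-voxel step lengths
  d <- c(0.3, 0.5, 0.81); d <- d / sqrt(sum(d^2))
  ob <- buildLineLattice(ph, matrix(d, 1))[[1]]
  acc <- tapply(ob@steps$dl, ob@steps$voxel, sum)
  expect_identical(length(acc), 1331L)          # every voxel crossed
  expect_lt(max(abs(acc - ob@dlMax)) / ob@dlMax, 1e-6)

  # antiparallel direction: identical voxel chains in reversed order
  fw <- buildLineLattice(ph, matrix(d, 1))[[1]]
  bw <- buildLineLattice(ph, matrix(-d, 1))[[1]]
  expect_identical(sort(unique(bw@steps$voxel)), sort(unique(fw@steps$voxel)))
  f1 <- fw@steps$voxel[fw@steps$line == fw@steps$line[1]]
  match_line <- bw@steps$line[match(f1[length(f1)], bw@steps$voxel)]
  b1 <- bw@steps$voxel[bw@steps$line == match_line]
  expect_identical(rev(b1), f1)
})

test_that("phantoms round-trip through volume files", {
  ph <- buildCase("C", 0.2, 8.2, snapBox = TRUE)
  dir <- tempfile(); dir.create(dir)
  writePhantom(ph, dir)
  back <- readPhantom(dir)
  expect_identical(back@dims, ph@dims)
  expect_equal(back@voxelSize, ph@voxelSize)
  expect_identical(back@medium, ph@medium)
  expect_equal(back@density, ph@density)
  expect_equal(back@box$lo, ph@box$lo)
})
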