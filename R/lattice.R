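# Transport direction sets and line lattices.

#' Equal-solid-angle cone directions
#'
#' Deterministic zenith-uniform partition of the unit sphere into `m` cells
#' of exactly equal solid angle (4*pi/m each): zenith rings whose
#' cos(theta) extents match integer cell counts, each ring split uniformly
#' in azimuth with a golden-angle ring offset to avoid azimuthal alignment.
#' Cone axes are placed at the cell centers.
#'
#' @param m number of directions.
#' @return list with `directions` (m x 3 matrix of unit vectors) and
#'   `solidAngle` (numeric m, all equal to 4*pi/m).
#' @export
coneDirections <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  nr <- max(1L, as.integer(round(sqrt(m / 2))))
  th <- seq(0, pi, length.out = nr + 1L)           # zenith-uniform rings
  areas <- -diff(cos(th)) / 2                      # fractional ring areas
  counts <- floor(areas * m)
  rem <- m - sum(counts)
  if (rem > 0) {                                   # largest remainders
    o <- order(areas * m - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  keep <- counts > 0
  counts <- counts[keep]
  # reset ring cos-boundaries so each cell has exactly 4*pi/m solid angle
  cb <- 1 - 2 * cumsum(c(0, counts)) / m
  golden <- pi * (3 - sqrt(5))
  dirs <- do.call(rbind, lapply(seq_along(counts), function(i) {
    k <- counts[i]
    cz <- (cb[i] + cb[i + 1]) / 2
    sz <- sqrt(max(0, 1 - cz^2))
    phi <- (seq_len(k) - 0.5) * 2 * pi / k + (i - 1) * golden
    cbind(sz * cos(phi), sz * sin(phi), rep(cz, k))
  }))
  list(directions = dirs, solidAngle = rep(4 * pi / m, m))
}

#' Build the transport line lattice for given directions
#'
#' For each direction the grid is swept slab-by-slab along the dominant
#' axis: every voxel belongs to exactly one line (lines are sheared voxel
#' chains obtained by rounding the accumulated transverse drift), and every
#' step has the direction's constant step length
#' `dlMax = voxelSize / max(abs(direction))`.  The summed step length per
#' voxel therefore equals `dlMax` exactly for every voxel, which is the
#' defining property of the per-direction total step length.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param directions matrix of unit direction vectors (rows), e.g. from
#'   [coneDirections()].
#' @return list of [TransportLineLattice-class], one per direction.
#' @export
buildLineLattice <- function(phantom, directions) {
  directions <- rbind(directions)
  lapply(seq_len(nrow(directions)), function(i) {
    d <- directions[i, ] / sqrt(sum(directions[i, ]^2))
    st <- cpp_lattice_steps(phantom@dims, d)
    new("TransportLineLattice", direction = d,
      dlMax = phantom@voxelSize / max(abs(d)),
      steps = data.frame(line = st$line, order = st$order,
        voxel = st$voxel, dl = rep(phantom@voxelSize / max(abs(d)),
          length(st$voxel))))
  })
}
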