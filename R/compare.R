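# Figure-of-merit layer: percentage dose difference ratio maps, region
# statistics, histograms and profiles.

#' Percentage dose difference ratio map
#'
#' `Delta_gen = 100 (D_gen^test - D_gen^MC) / D_tot^MC` per voxel: the
#' difference of one generation component between the engine and the Monte
#' Carlo reference, normalized by the *total* MC dose.  With a shared
#' denominator the component maps add exactly:
#' `Delta_tot = Delta_prim + Delta_1sc + Delta_msc`.
#'
#' @param test a [DoseComponents-class] engine result.
#' @param mc a [KermaTally-class] reference on the same grid.
#' @param gen `"prim"`, `"1sc"`, `"msc"` or `"tot"`.
#' @return 3D array of percentages; voxels with zero MC total dose are NA
#'   and counted in the `maskedVoxels` attribute.
#' @export
deltaMap <- function(test, mc, gen = "tot") {
  stopifnot(identical(phantomDims(test), phantomDims(mc)))
  den <- doseComponent(mc, "tot")
  bad <- den <= 0
  den[bad] <- NA_real_
  out <- 100 * (doseComponent(test, gen) - doseComponent(mc, gen)) / den
  attr(out, "maskedVoxels") <- sum(bad)
  out
}

#' Moments of a difference-ratio distribution over a region
#'
#' Mean, standard deviation, median and skewness (Fisher's standardized
#' third moment) of the in-region values, plus the mean-median difference
#' used as a robustness check.
#'
#' @param delta a Delta map from [deltaMap()] (or any numeric array).
#' @param mask logical region mask (e.g. [boxMask()]).
#' @return named numeric: `mean`, `sd`, `median`, `skewness`,
#'   `meanMinusMedian`, `n`.
#' @export
regionStats <- function(delta, mask) {
  x <- delta[mask]
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty region mask")
  m <- mean(x)
  s <- sd(x)
  z <- x - m
  skew <- if (s > 0) mean(z^3) / (mean(z^2))^1.5 else 0
  c(mean = m, sd = s, median = median(x), skewness = skew,
    meanMinusMedian = m - median(x), n = length(x))
}

#' Histogram of a difference-ratio distribution
#'
#' Fixed-width bins (default 0.5 percentage points) scaled so that the
#' integral `sum(height * width)` equals 100.
#'
#' @param delta a Delta map from [deltaMap()].
#' @param mask logical region mask.
#' @param binWidth bin width in percentage points.
#' @return data.frame with `mid`, `lo`, `hi`, `height`.
#' @export
deltaHistogram <- function(delta, mask, binWidth = 0.5) {
  x <- delta[mask]
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty region mask")
  lo <- floor(min(x) / binWidth) * binWidth
  hi <- ceiling(max(x) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  br <- seq(lo, hi, by = binWidth)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
    nbins = length(br) - 1)
  height <- 100 * cnt / sum(cnt) / binWidth
  data.frame(mid = (br[-1] + br[-length(br)]) / 2, lo = br[-length(br)],
    hi = br[-1], height = height)
}

#' Dose profile along the +/- x axis through the source
#'
#' Extracts the voxel-center line at y = z = 0 and divides by a
#' homogeneous-water reference dose at matched positions (the standard
#' water-geometry normalization used for profile plotting).  The source
#' voxel is masked.
#'
#' @param dose 3D dose array.
#' @param reference 3D reference dose array on the same grid (engine or MC
#'   run of the homogeneous water phantom).
#' @param phantom the [VoxelPhantom-class] defining the geometry.
#' @return data.frame with `x` (cm) and `ratio`.
#' @export
doseProfile <- function(dose, reference, phantom) {
  n <- phantom@dims
  jc <- (n[2] + 1L) %/% 2L
  kc <- (n[3] + 1L) %/% 2L
  x <- voxelCenters(phantom)$x
  num <- dose[, jc, kc]
  den <- reference[, jc, kc]
  ratio <- ifelse(den > 0, num / den, NA_real_)
  ic <- (n[1] + 1L) %/% 2L
  ratio[ic] <- NA_real_  # source voxel masked
  data.frame(x = x, ratio = ratio)
}

#' Generation-resolved comparison statistics table
#'
#' One row per generation with the region moments of the Delta distribution
#' and the MC Type A (k = 2) uncertainty of the region-mean component dose
#' when the region was registered in the tally.
#'
#' @param test a [DoseComponents-class].
#' @param mc a [KermaTally-class].
#' @param mask logical region mask.
#' @param region optional region name registered in [runMC()] for exact MC
#'   uncertainties.
#' @return data.frame with columns `mode`, `gen`, `mean`, `sd`, `median`,
#'   `skewness`, `mcRelUnc`.
#' @export
deltaStats <- function(test, mc, mask, region = NULL) {
  gens <- c("prim", "1sc", "msc", "tot")
  rows <- lapply(gens, function(g) {
    st <- regionStats(deltaMap(test, mc, g), mask)
    unc <- if (!is.null(region)) mcUncertainty(mc, region, g) else NA_real_
    data.frame(mode = test@mode, gen = g, mean = st[["mean"]],
      sd = st[["sd"]], median = st[["median"]],
      skewness = st[["skewness"]], mcRelUnc = unc)
  })
  do.call(rbind, rows)
}

#' Isodose level masks
#'
#' Voxel masks at given percentages of a reference dose value (the
#' normalization point is supplied explicitly).
#'
#' @param dose 3D dose array.
#' @param reference reference dose value (same units as `dose`).
#' @param levels percentages of `reference`.
#' @return named list of logical arrays (`dose >= level`).
#' @export
isodoseMasks <- function(dose, reference, levels = c(100, 10, 3)) {
  setNames(lapply(levels, function(l) dose >= reference * l / 100),
    paste0("L", levels))
}
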