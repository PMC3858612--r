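#' Bivariate reference ("normal rule") bandwidth
#'
#' h_ref = sigma_pooled * n^(-1/6), with
#' sigma_pooled = sqrt((var(x) + var(y)) / 2). This is the base bandwidth
#' from which the ad hoc rule scales down.
#'
#' @param xy n x 2 matrix of planar coordinates (m), n >= 5 distinct
#'   points.
#' @return bandwidth in meters.
#' @export
referenceBandwidth <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(unique(xy)) < 5)
    stop("need at least 5 distinct points for a bandwidth")
  s2 <- (stats::var(xy[, 1]) + stats::var(xy[, 2])) / 2
  if (s2 == 0) stop("degenerate input: all points identical")
  sqrt(s2) * nrow(xy)^(-1 / 6)
}

#' Fixed-kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian fixed-kernel density (bandwidth `h` = kernel standard
#' deviation in both directions), evaluated on a grid padded at least
#' `pad * h` beyond the data extent and renormalized so the cell Riemann
#' sum is exactly 1. The grid is computed with [MASS::kde2d()].
#'
#' @param xy n x 2 matrix of coordinates (m).
#' @param h bandwidth in meters (> 0); default the reference rule.
#' @param cell target cell size in meters (default 2.5, a quarter of a
#'   10-m field grid). Actual spacing is the extent divided into whole
#'   cells, so it can be slightly smaller.
#' @param pad grid padding in bandwidths beyond the data extent (>= 3).
#' @return a [UtilizationDistribution-class].
#' @export
kernelUD <- function(xy, h = referenceBandwidth(xy), cell = 2.5, pad = 3.5) {
  xy <- as.matrix(xy)
  stopifnot(h > 0, cell > 0, pad >= 3)
  lims <- c(range(xy[, 1]) + c(-1, 1) * pad * h,
            range(xy[, 2]) + c(-1, 1) * pad * h)
  nx <- max(16L, ceiling(diff(lims[1:2]) / cell) + 1L)
  ny <- max(16L, ceiling(diff(lims[3:4]) / cell) + 1L)
  # kde2d treats its bandwidth argument as 4 x the kernel sd
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * h, n = c(nx, ny),
                    lims = lims)
  cx <- kd$x[2] - kd$x[1]
  cy <- kd$y[2] - kd$y[1]
  # per-axis spacings differ slightly; the geometric mean keeps
  # sum(z) * cell^2 == sum(z) * cx * cy == 1 exact
  cellsz <- sqrt(cx * cy)
  z <- kd$z / (sum(kd$z) * cx * cy)
  new("UtilizationDistribution", xg = kd$x, yg = kd$y, cell = cellsz,
      z = z, h = h)
}

# 8-connected component count of a logical grid mask
.componentCount <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start]) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          nxt <- ii + (jj - 1L) * nr
          if (mask[nxt] && !lab[nxt]) {
            lab[nxt] <- comp
            queue <- c(queue, nxt)
          }
        }
      }
    }
  }
  comp
}

# density threshold whose >= set is the smallest cell set with cumulative
# probability >= level
.isoplethThreshold <- function(ud, level) {
  dens <- sort(as.vector(ud@z), decreasing = TRUE)
  cum <- cumsum(dens) * ud@cell^2
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(dens)
  dens[k]
}

#' Ad hoc bandwidth: smallest contiguous-contour multiplier
#'
#' Scans multipliers c in {1.0, 0.9, ..., 0.1} of the reference bandwidth
#' and returns `c * h_ref` for the smallest c at which the isopleth at
#' `level` is still a single connected region (8-connectivity of the
#' above-threshold cells). If no multiplier yields a connected contour the
#' reference bandwidth itself is returned. This stepwise-contiguity rule
#' avoids the over-smoothing of the plain reference rule while keeping the
#' home range in one piece; the plain rule remains available via
#' [referenceBandwidth()].
#'
#' @inheritParams kernelUD
#' @param level isopleth level used for the contiguity check (default
#'   0.95).
#' @return bandwidth in meters.
#' @export
adhocBandwidth <- function(xy, cell = 2.5, level = 0.95) {
  xy <- as.matrix(xy)
  href <- referenceBandwidth(xy)
  best <- href
  for (c in seq(1.0, 0.1, by = -0.1)) {
    ud <- kernelUD(xy, h = c * href, cell = cell)
    thr <- .isoplethThreshold(ud, level)
    if (.componentCount(ud@z >= thr) == 1L) best <- c * href
  }
  best
}

# signed shoelace area of one ring (m^2)
.ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# total area of a ring list in m^2 (signed sum, even-odd consistent)
.ringsArea <- function(rings) {
  abs(sum(vapply(rings, .ringArea, 0)))
}

#' Extract an isopleth home-range polygon from a UD
#'
#' Cells are ranked by density and the smallest set whose cumulative
#' probability reaches `level` defines the home range; its boundary is
#' traced with [grDevices::contourLines()] at the limiting density. The
#' reported area is the cell-count area of that set, in hectares.
#'
#' @param ud a [UtilizationDistribution-class].
#' @param level isopleth level in (0, 1), conventionally 0.95.
#' @param id individual identifier carried into the polygon.
#' @return a [RangePolygon-class].
#' @export
isopleth <- function(ud, level = 0.95, id = NA_character_) {
  stopifnot(is(ud, "UtilizationDistribution"), level > 0, level < 1)
  thr <- .isoplethThreshold(ud, level)
  areaHa <- sum(ud@z >= thr) * ud@cell^2 / 1e4
  cl <- grDevices::contourLines(ud@xg, ud@yg, ud@z, levels = thr)
  rings <- lapply(cl, function(r) cbind(r$x, r$y))
  rings <- Filter(function(r) nrow(r) >= 3, rings)
  if (!length(rings))
    stop("isopleth contour could not be traced; grid too coarse?")
  new("RangePolygon", id = id, level = level, rings = rings,
      areaHa = areaHa, h = ud@h)
}

#' Minimum convex polygon range
#'
#' Convex hull of the fixes; used as the per-night range when too few
#' fixes make a kernel estimate unstable (default threshold 15 fixes in
#' the pipeline).
#'
#' @param xy n x 2 matrix of coordinates (m), n >= 3 non-collinear points.
#' @param id individual identifier.
#' @return a [RangePolygon-class] with `level = 1` and `h = NA`.
#' @export
mcpPolygon <- function(xy, id = NA_character_) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3) stop("need at least 3 distinct points for an MCP")
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  a <- abs(.ringArea(hull))
  if (a <= 0) stop("degenerate input: collinear points")
  new("RangePolygon", id = id, level = 1,
      rings = list(unname(hull)), areaHa = a / 1e4, h = NA_real_)
}

#' Kernel home range in one call
#'
#' Convenience wrapper: 5-min subsampling, ad hoc (or reference) bandwidth,
#' kernel UD, and the isopleth polygon.
#'
#' @param traj a [Trajectory-class].
#' @param level isopleth level (default 0.95).
#' @param cell grid cell size in m.
#' @param bandwidth `"adhoc"` (stepwise-contiguity rule, default) or
#'   `"reference"`.
#' @param subsample fix interval in seconds applied first (default 300;
#'   `NULL` to skip).
#' @return a [RangePolygon-class].
#' @export
homeRange <- function(traj, level = 0.95, cell = 2.5,
                      bandwidth = c("adhoc", "reference"),
                      subsample = 300) {
  bandwidth <- match.arg(bandwidth)
  if (!is.null(subsample)) traj <- subsampleFixes(traj, subsample)
  xy <- coords(traj)
  h <- if (bandwidth == "adhoc") adhocBandwidth(xy, cell = cell, level = level)
       else referenceBandwidth(xy)
  isopleth(kernelUD(xy, h = h, cell = cell), level = level, id = traj@id)
}
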