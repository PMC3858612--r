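# convert a RangePolygon's rings to the list-of-lists form polyclip uses
.toPolyclip <- function(p) {
  lapply(p@rings, function(r) list(x = r[, 1], y = r[, 2]))
}

.polyclipArea <- function(rings) {
  if (!length(rings)) return(0)
  abs(sum(vapply(rings, function(r) {
    .ringArea(cbind(r$x, r$y))
  }, 0)))
}

# fixed origin and nanometer resolution keep axis-aligned cases exact to
# double precision instead of depending on data-driven scaling
.clip <- function(A, B, op) {
  polyclip::polyclip(A, B, op = op, eps = 1e-9, x0 = 0, y0 = 0)
}

#' Directional percent overlap of two range polygons
#'
#' Kernohan-style percent overlap: the share of A's area lying inside B,
#' and vice versa, computed by exact polygon clipping. For multi-ring
#' isopleths areas are summed across rings (even-odd fill) before
#' division, so `area(A intersect B)` is identical in both directions.
#'
#' @param a,b [RangePolygon-class] objects.
#' @return a data.frame with one row: `id_a, id_b, pct_a_in_b, pct_b_in_a,
#'   area_a_ha, area_b_ha` (percentages in \\[0, 100\\]; areas here are
#'   ring-geometry areas, consistent with the intersection).
#' @examples
#' sq <- function(x0, x1, id) new("RangePolygon", id = id, level = 0.95,
#'   rings = list(cbind(c(x0, x1, x1, x0), c(0, 0, 10, 10))),
#'   areaHa = (x1 - x0) * 10 / 1e4)
#' percentOverlap(sq(0, 10, "A"), sq(5, 15, "B"))  # 50 / 50
#' @export
percentOverlap <- function(a, b) {
  stopifnot(is(a, "RangePolygon"), is(b, "RangePolygon"))
  pa <- .toPolyclip(a); pb <- .toPolyclip(b)
  areaA <- .polyclipArea(pa); areaB <- .polyclipArea(pb)
  if (areaA <= 0 || areaB <= 0)
    stop("degenerate input: zero-area polygon")
  # clipping resolution can overshoot by ~1e-10; the intersection can
  # never exceed either operand
  inter <- min(.polyclipArea(.clip(pa, pb, "intersection")),
               areaA, areaB)
  data.frame(id_a = a@id, id_b = b@id,
             pct_a_in_b = 100 * inter / areaA,
             pct_b_in_a = 100 * inter / areaB,
             area_a_ha = areaA / 1e4, area_b_ha = areaB / 1e4,
             stringsAsFactors = FALSE)
}

#' Union area of two range polygons
#'
#' Exact polygon union, in square meters. Used as the pair's joint home
#' range when computing the density parameter of the encounter models
#' (rho = 1 / union area).
#'
#' @param a,b [RangePolygon-class] objects.
#' @return numeric(1), m^2.
#' @export
unionArea <- function(a, b) {
  .polyclipArea(.clip(.toPolyclip(a), .toPolyclip(b), "union"))
}

# minimum distance between the convex hulls of two ring sets (0 if the
# polygons intersect); adequate for a neighbor screen
.polyDistance <- function(a, b) {
  if (.polyclipArea(.clip(.toPolyclip(a), .toPolyclip(b),
                          "intersection")) > 0)
    return(0)
  pa <- do.call(rbind, a@rings); pb <- do.call(rbind, b@rings)
  d2 <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    (pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2
  })
  sqrt(min(d2))
}

#' Pairwise directional overlap of a set of range polygons
#'
#' All unordered pairs, each reported directionally. With
#' `neighborsOnly = TRUE` the summary is restricted to polygons whose
#' vertices come within `adjacency` meters of each other (neighboring
#' ranges), the set over which neighbor-overlap statistics are averaged.
#'
#' @param polys list of [RangePolygon-class] objects (>= 2).
#' @param neighborsOnly restrict to adjacent pairs?
#' @param adjacency neighbor distance threshold in meters (default 50).
#' @return data.frame, one row per retained pair, columns as in
#'   [percentOverlap()].
#' @export
overlapMatrix <- function(polys, neighborsOnly = FALSE, adjacency = 50) {
  stopifnot(length(polys) >= 2)
  rows <- list()
  n <- length(polys)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (neighborsOnly &&
        .polyDistance(polys[[i]], polys[[j]]) > adjacency) next
    rows[[length(rows) + 1]] <- percentOverlap(polys[[i]], polys[[j]])
  }
  if (!length(rows))
    return(data.frame(id_a = character(0), id_b = character(0),
                      pct_a_in_b = numeric(0), pct_b_in_a = numeric(0),
                      area_a_ha = numeric(0), area_b_ha = numeric(0)))
  do.call(rbind, rows)
}
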