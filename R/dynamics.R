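#' Random gas model: expected encounter rate
#'
#' Ideal-gas expected number of encounters between two independently and
#' ballistically moving animals per observation period:
#' f = (4 * rho * v / pi) * (2 d + s), where rho is pair density (here
#' 1 / the pair's union home range in m^2), v the distance covered during
#' the observation period (m), s the group spread (m) and d the distance
#' criterion (m).
#'
#' @param rho density per m^2 (> 0).
#' @param v distance covered per observation period, m (>= 0).
#' @param d distance criterion, m (default 15).
#' @param s group spread, m (default 0).
#' @return expected encounters per observation period.
#' @examples
#' gasExpectedRate(rho = 1/3000, v = 500, d = 15)  # ~ 6.37
#' @export
gasExpectedRate <- function(rho, v, d = 15, s = 0) {
  stopifnot(rho > 0, v >= 0, d >= 0, s >= 0)
  (4 * rho * v / pi) * (2 * d + s)
}

#' Hutchinson's model: expected associations for instantaneous sampling
#'
#' f = N * rho * pi * d^2, the expected number of point samples at which
#' two independently located animals fall within d of each other, out of N
#' instantaneous observations at density rho.
#'
#' @param N number of instantaneous observations (>= 0).
#' @param rho density per m^2 (> 0).
#' @param d distance criterion, m (default 15).
#' @return expected number of associations.
#' @examples
#' hutchinsonExpected(100, 1/10000, 15)  # ~ 7.07
#' @export
hutchinsonExpected <- function(N, rho, d = 15) {
  stopifnot(N >= 0, rho > 0, d >= 0)
  N * rho * pi * d^2
}

#' Observed associations and encounter (entry) events of a dyad
#'
#' Two observed counts against the two expected-rate models:
#' `associations` is the number of aligned time points with inter-partner
#' distance <= d (Hutchinson's observed side); `entries` is the number of
#' below-d points whose previous point was above d, plus one if the series
#' starts below d (the gas model's observed encounter count — an encounter
#' begins when the pair crosses under d).
#'
#' @param dy a [DyadSeries-class].
#' @param d distance criterion, m (>= 0, default 15).
#' @return named list `list(associations =, entries =, N =)`.
#' @export
observedEncounters <- function(dy, d = 15) {
  stopifnot(is(dy, "DyadSeries"), d >= 0)
  dist <- dyadDistances(dy)
  n <- length(dist)
  if (n == 0) return(list(associations = 0L, entries = 0L, N = 0L))
  below <- dist <= d
  entries <- sum(below & !c(FALSE, below[-n]))
  list(associations = sum(below), entries = as.integer(entries),
       N = n)
}

#' Percent of time a dyad spends within a distance criterion
#'
#' 100 * (aligned points with inter-partner distance <= d) / (aligned
#' points): the share of the activity period the partners spend in
#' proximity.
#'
#' @param dy a nonempty [DyadSeries-class].
#' @param d distance criterion in m (commonly 10 or 20 for cross-species
#'   comparison).
#' @return percent in \\[0, 100\\].
#' @export
proximityTime <- function(dy, d) {
  stopifnot(is(dy, "DyadSeries"))
  if (length(dy@t) == 0) stop("empty dyad series")
  100 * mean(dyadDistances(dy) <= d)
}

#' Doncaster's contingency test of dynamic interaction
#'
#' Compares the N observed simultaneous inter-partner distances with the
#' N^2 distances of all cross-pairings of the same two point sets (male
#' fix i vs female fix j for all i, j; the observed pairings are included)
#' in a 2 x 2 table of counts below/above the distance criterion d, tested
#' by chi-square with df = 1 (no continuity correction by default).
#' Direction is `attraction` when the observed below-d proportion exceeds
#' the cross-pairing proportion and the test is significant, `avoidance`
#' when it is lower, `none` otherwise.
#'
#' The chi-square approximation requires successive points to be
#' independent; subsample the series so the animal can traverse its range
#' between fixes before testing.
#'
#' @param dy a [DyadSeries-class] with at least `minN` entries.
#' @param d distance criterion, m (default 15).
#' @param alpha significance level for the direction call (default 0.05).
#' @param correct continuity correction (default FALSE).
#' @param minN minimum series length (default 20).
#' @return list with `model`, `observed` (below-d count), `expected`
#'   (below-d count scaled from the N^2 pairings), `table`, `statistic`,
#'   `df`, `p.value`, `direction`, `N`.
#' @export
doncasterTest <- function(dy, d = 15, alpha = 0.05, correct = FALSE,
                          minN = 20) {
  stopifnot(is(dy, "DyadSeries"))
  N <- length(dy@t)
  if (N < minN)
    stop("doncasterTest: need at least ", minN, " aligned fixes")
  obsBelow <- sum(dyadDistances(dy) <= d)
  d2 <- outer(dy@mx, dy@fx, "-")^2 + outer(dy@my, dy@fy, "-")^2
  allBelow <- sum(d2 <= d^2)
  tab <- rbind(observed = c(below = obsBelow, above = N - obsBelow),
               all = c(allBelow, N^2 - allBelow))
  ht <- chisqIndependence2x2(tab, correct = correct)
  pObs <- obsBelow / N
  pAll <- allBelow / N^2
  direction <- if (ht$p.value > alpha) "none"
    else if (pObs > pAll) "attraction" else "avoidance"
  list(model = "doncaster", observed = obsBelow, expected = pAll * N,
       table = tab, statistic = unname(ht$statistic), df = 1,
       p.value = ht$p.value, direction = direction, N = N, d = d)
}

#' Wilcoxon signed-rank comparison of observed vs expected across dyads
#'
#' Exact signed-rank test of per-dyad observed values against the model's
#' expected values (paired by dyad). Delegates to [signedRankExact()].
#'
#' @param observed,expected numeric vectors of equal length, one entry per
#'   dyad.
#' @return an `"htest"` (see [signedRankExact()]).
#' @export
wilcoxonAcrossPairs <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  signedRankExact(observed - expected)
}

#' Full dynamic-interaction analysis of one dyad
#'
#' Computes the parameters and all three tests for a male-female dyad:
#' rho = 1 / (union area of the two 95% range polygons, m^2), v = mean of
#' the partners' path lengths per observation period, the gas-model and
#' Hutchinson expected values, the observed association and entry counts,
#' Doncaster's test (on an independence-subsampled series), and proximity
#' time at 10/15/20 m.
#'
#' @param dy a [DyadSeries-class] (full-resolution alignment).
#' @param maleRange,femaleRange [RangePolygon-class] 95% ranges.
#' @param maleTraj,femaleTraj [Trajectory-class] objects used for the
#'   path-length (velocity) input; subsampled to `subsample` seconds
#'   first.
#' @param nights number of observation periods pooled in `dy`; observed
#'   and expected encounter values are reported per observation period.
#' @param d distance criterion, m (default 15).
#' @param s group spread, m (default 0).
#' @param subsample fix interval (s) for path lengths (default 300).
#' @param independenceInterval subsampling interval (s) applied to the
#'   series before Doncaster's test so successive points are independent
#'   (default 1800).
#' @param alpha significance level (default 0.05).
#' @return list with `params` (rho, v, s, d, N), `gas`, `hutchinson`,
#'   `doncaster`, `proximity` components.
#' @export
dyadInteraction <- function(dy, maleRange, femaleRange, maleTraj,
                            femaleTraj, nights = 1, d = 15, s = 0,
                            subsample = 300, independenceInterval = 1800,
                            alpha = 0.05) {
  uArea <- unionArea(maleRange, femaleRange)
  rho <- 1 / uArea
  v <- mean(c(pathLength(subsampleFixes(maleTraj, subsample)),
              pathLength(subsampleFixes(femaleTraj, subsample)))) / nights
  obs <- observedEncounters(dy, d)
  gasExp <- gasExpectedRate(rho, v, d = d, s = s)
  hutExp <- hutchinsonExpected(obs$N, rho, d = d)
  dySub <- .subsampleDyad(dy, independenceInterval)
  don <- doncasterTest(dySub, d = d, alpha = alpha)
  list(
    params = list(rho = rho, v = v, s = s, d = d, N = obs$N,
                  unionAreaHa = uArea / 1e4, nights = nights),
    gas = list(model = "gas", observed = obs$entries / nights,
               expected = gasExp),
    hutchinson = list(model = "hutchinson", observed = obs$associations,
                      expected = hutExp),
    doncaster = don,
    proximity = list(pct10 = proximityTime(dy, 10),
                     pct15 = proximityTime(dy, 15),
                     pct20 = proximityTime(dy, 20))
  )
}

# greedy subsampling of a DyadSeries, same rule as subsampleFixes
.subsampleDyad <- function(dy, interval) {
  n <- length(dy@t)
  if (n == 0 || is.null(interval) || interval <= 0) return(dy)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- dy@t[1]
  for (i in seq_len(n)[-1]) {
    if (dy@t[i] - last >= interval) {
      keep[i] <- TRUE
      last <- dy@t[i]
    }
  }
  new("DyadSeries", maleId = dy@maleId, femaleId = dy@femaleId,
      t = dy@t[keep], mx = dy@mx[keep], my = dy@my[keep],
      fx = dy@fx[keep], fy = dy@fy[keep])
}
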