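# axis-aligned rectangle as a RangePolygon (areaHa from its geometry)
rectPolygon <- function(x0, x1, y0, y1, id = "rect", level = 0.95) {
  new("RangePolygon", id = id, level = level,
      rings = list(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))),
      areaHa = (x1 - x0) * (y1 - y0) / 1e4)
}

# dyad with the male pinned at the origin and the female at given
# distances along the x axis, one fix per minute
dyadAtDistances <- function(dists) {
  n <- length(dists)
  new("DyadSeries", maleId = "m", femaleId = "f",
      t = 60 * seq_len(n), mx = rep(0, n), my = rep(0, n),
      fx = dists, fy = rep(0, n))
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# vectors (independent oracle; n must be small)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vall <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vall <= V), mean(Vall >= V)))
}

quietly <- function(expr) suppressMessages(expr)
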