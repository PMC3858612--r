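test_that("reference bandwidth follows the pooled-SD normal rule", {
  n <- 100
  th <- 2 * pi * (seq_len(n) - 1) / n
  xy <- cbind(cos(th), sin(th))        # unit circle, known moments
  sig <- sqrt((var(xy[, 1]) + var(xy[, 2])) / 2)
  expect_equal(referenceBandwidth(xy), sig * n^(-1 / 6))

  expect_equal(referenceBandwidth(2 * xy), 2 * referenceBandwidth(xy))

  # doubling n at (essentially) fixed spread shrinks h by 2^(-1/6)
  expect_equal(referenceBandwidth(rbind(xy, xy)) / referenceBandwidth(xy),
               2^(-1 / 6), tolerance = 0.01)

  expect_error(referenceBandwidth(matrix(1, 10, 2)), "distinct")
})

test_that("kernel UD mass is conserved for any bandwidth and cell size", {
  set.seed(3)
  xy <- matrix(rnorm(200, sd = 10), ncol = 2)
  for (h in c(1, 3, 8)) for (cell in c(1, 2.5)) {
    ud <- kernelUD(xy, h = h, cell = cell)
    expect_equal(sum(ud@z) * ud@cell^2, 1, tolerance = 1e-9)
  }
  # a single point is a single Gaussian bump of unit mass
  ud1 <- kernelUD(cbind(0, 0), h = 2, cell = 0.5)
  expect_equal(sum(ud1@z) * ud1@cell^2, 1, tolerance = 1e-9)
  expect_equal(which.max(ud1@z),
               which.min(outer(ud1@xg^2, ud1@yg^2, "+")))
})

test_that("two far-apart points give two equal-mass modes", {
  ud <- kernelUD(rbind(c(0, 0), c(100, 0)), h = 2, cell = 1)
  half <- sum(ud@z[ud@xg < 50, ]) * ud@cell^2
  expect_equal(half, 0.5, tolerance = 1e-6)
})

test_that("95% isopleth of a Gaussian sample matches the analytic ellipse", {
  set.seed(11)
  xy <- matrix(rnorm(8000), ncol = 2)
  ud <- kernelUD(xy, cell = 0.05)
  rp <- isopleth(ud, 0.95, id = "gauss")
  analytic <- pi * qchisq(0.95, df = 2)        # ~18.8 m^2 for sd 1
  expect_lt(abs(rp@areaHa * 1e4 - analytic) / analytic, 0.10)
})

test_that("isopleth area is monotone in level and stable under grid refinement", {
  set.seed(5)
  xy <- matrix(rnorm(2000), ncol = 2)
  ud <- kernelUD(xy, cell = 0.1)
  areas <- vapply(c(0.5, 0.8, 0.95, 0.99),
                  function(l) areaHa(isopleth(ud, l)), 0)
  expect_true(all(diff(areas) > 0))

  h <- referenceBandwidth(xy)
  a1 <- areaHa(isopleth(kernelUD(xy, h = h, cell = 0.1), 0.95))
  a2 <- areaHa(isopleth(kernelUD(xy, h = h, cell = 0.05), 0.95))
  expect_lt(abs(a2 - a1) / a1, 0.05)
})

test_that("ad hoc bandwidth shrinks for one cluster but stops before fragmenting", {
  set.seed(21)
  one <- matrix(rnorm(600, sd = 5), ncol = 2)
  hrefOne <- referenceBandwidth(one)
  hOne <- adhocBandwidth(one, cell = 1)
  # multiplier grid is {0.1, ..., 1.0} times the reference bandwidth
  cOne <- hOne / hrefOne
  expect_true(any(abs(cOne - seq(0.1, 1, by = 0.1)) < 1e-10))
  expect_lt(cOne, 1 - 1e-10)          # unimodal data supports shrinking
  # the chosen bandwidth yields one connected 95% cell region
  udOne <- kernelUD(one, h = hOne, cell = 1)
  thr <- dyadMove:::.isoplethThreshold(udOne, 0.95)
  expect_equal(dyadMove:::.componentCount(udOne@z >= thr), 1L)

  two <- rbind(matrix(rnorm(300, sd = 3), ncol = 2),
               matrix(rnorm(300, sd = 3), ncol = 2) +
                 matrix(rep(c(60, 0), each = 150), ncol = 2))
  hrefTwo <- referenceBandwidth(two)
  hTwo <- adhocBandwidth(two, cell = 1)
  expect_gt(hTwo, 0.1 * hrefTwo + 1e-10)
  # widely separated clusters force a larger multiplier than one cluster
  expect_gt(hTwo / hrefTwo, cOne - 1e-10)
})

test_that("MCP fallback computes hull areas and rejects degenerate input", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(5, 5))
  expect_equal(areaHa(mcpPolygon(sq)), 0.01)
  expect_error(mcpPolygon(cbind(1:5, 1:5)), "collinear|2 columns|distinct")
})
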