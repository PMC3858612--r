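test_that("gas-model expected rate matches the closed form", {
  expect_equal(gasExpectedRate(rho = 1 / 3000, v = 0, d = 15), 0)
  expect_equal(gasExpectedRate(rho = 1 / 3000, v = 500, d = 0, s = 0), 0)
  expect_equal(gasExpectedRate(rho = 1 / 3000, v = 500, d = 15),
               4 * (1 / 3000) * 500 / pi * 30)   # ~6.366
  # linear in rho, monotone in d
  expect_equal(gasExpectedRate(2e-4, 300, 15), 2 * gasExpectedRate(1e-4, 300, 15))
  expect_lt(gasExpectedRate(1e-4, 300, 10), gasExpectedRate(1e-4, 300, 20))
})

test_that("Hutchinson expected associations match the closed form", {
  expect_equal(hutchinsonExpected(0, 1e-4, 15), 0)
  expect_equal(hutchinsonExpected(100, 1 / 10000, 15), pi * 225 / 100)
  expect_equal(hutchinsonExpected(50, 2e-4, 15),
               2 * hutchinsonExpected(50, 1e-4, 15))
})

test_that("observed associations and entry events follow their definitions", {
  dy <- dyadAtDistances(c(20, 10, 10, 20, 5))
  obs <- observedEncounters(dy, d = 15)
  expect_equal(obs$associations, 3L)
  expect_equal(obs$entries, 2L)

  same <- new("DyadSeries", maleId = "m", femaleId = "f", t = 1:10,
              mx = rnorm(10), my = rnorm(10), fx = numeric(10),
              fy = numeric(10))
  same@fx <- same@mx; same@fy <- same@my
  obs2 <- observedEncounters(same, d = 5)
  expect_equal(obs2$associations, 10L)
  expect_equal(obs2$entries, 1L)

  empty <- new("DyadSeries")
  expect_equal(observedEncounters(empty, 15)$associations, 0)
})

test_that("observed associations of independent pairs match Hutchinson's formula", {
  # both animals i.i.d. uniform on a 200x200 torus; rho = 1/area
  set.seed(53)
  L <- 200; N <- 4000; reps <- 40
  hits <- replicate(reps, {
    dx <- abs(runif(N, 0, L) - runif(N, 0, L)); dx <- pmin(dx, L - dx)
    dyv <- abs(runif(N, 0, L) - runif(N, 0, L)); dyv <- pmin(dyv, L - dyv)
    sum(dx^2 + dyv^2 <= 225)
  })
  expected <- hutchinsonExpected(N, 1 / L^2, 15)
  expect_lt(abs(mean(hits) - expected) / expected, 0.05)
})

test_that("Doncaster's table matches a brute-force cross-pairing count", {
  set.seed(59)
  n <- 25
  dy <- new("DyadSeries", maleId = "m", femaleId = "f", t = 1:n,
            mx = runif(n, 0, 40), my = runif(n, 0, 40),
            fx = runif(n, 0, 40), fy = runif(n, 0, 40))
  res <- doncasterTest(dy, d = 15)
  below <- 0L
  for (i in 1:n) for (j in 1:n) {
    dd <- sqrt((dy@mx[i] - dy@fx[j])^2 + (dy@my[i] - dy@fy[j])^2)
    if (dd <= 15) below <- below + 1L
  }
  expect_equal(unname(res$table["all", "below"]), below)
  expect_equal(unname(res$table["observed", "below"]), res$observed)
  expect_equal(res$statistic,
               unname(chisq.test(res$table, correct = FALSE)$statistic))
  expect_equal(sum(res$table["observed", ]), n)
  expect_equal(sum(res$table["all", ]), n^2)
})

test_that("Doncaster direction calls follow the observed vs cross proportions", {
  # female glued to the male: every observed pairing is at distance 0
  set.seed(61)
  n <- 30
  mx <- runif(n, 0, 100); my <- runif(n, 0, 100)
  glued <- new("DyadSeries", maleId = "m", femaleId = "f", t = 1:n,
               mx = mx, my = my, fx = mx, fy = my)
  res <- doncasterTest(glued, d = 15)
  expect_true(res$direction %in% c("attraction", "none"))
  expect_equal(res$observed, n)

  short <- dyadAtDistances(c(1, 2, 3))
  expect_error(doncasterTest(short), "at least")
})

test_that("proximity time is the below-d share of aligned points", {
  dy <- dyadAtDistances(c(5, 25, 25, 25))
  expect_equal(proximityTime(dy, 10), 25)
  same <- dyadAtDistances(rep(0, 8))
  expect_equal(proximityTime(same, 1), 100)
  expect_error(proximityTime(new("DyadSeries"), 10), "empty")
})

test_that("across-pair Wilcoxon reproduces the extreme-V exact p", {
  obs <- c(5, 7, 9, 11, 13, 15, 17)
  expected <- obs - 1          # all positive differences -> V = 28
  res <- wilcoxonAcrossPairs(obs, expected)
  expect_equal(unname(res$statistic), 28)
  expect_equal(round(res$p.value, 2), 0.02)
  resLo <- wilcoxonAcrossPairs(expected, obs)   # all negative -> V = 0
  expect_equal(unname(resLo$statistic), 0)
  expect_equal(resLo$p.value, res$p.value)
})

test_that("full dyad analysis wires parameters from geometry and movement", {
  set.seed(67)
  cfg <- simConfig("paper", nightsPerDyad = 4)
  d <- simulateDyad(cfg, seed = 5)
  hrM <- homeRange(d$male); hrF <- homeRange(d$female)
  rep <- dyadInteraction(d$series, hrM, hrF, d$male, d$female,
                         nights = 4)
  expect_equal(rep$params$rho, 1 / (rep$params$unionAreaHa * 1e4))
  expect_gt(rep$params$v, 0)
  expect_equal(rep$hutchinson$expected,
               hutchinsonExpected(rep$params$N, rep$params$rho, 15))
  expect_true(rep$doncaster$direction %in%
                c("attraction", "avoidance", "none"))
  expect_lte(rep$proximity$pct10, rep$proximity$pct20)
})

test_that("discrete sampling inflates encounters over the gas model more than Hutchinson", {
  # independent pairs: entry events exceed the ballistic gas expectation
  # by a larger factor than point associations exceed Hutchinson's
  set.seed(71)
  cfg <- simConfig(eta = 0, nightsPerDyad = 4)
  ratios <- replicate(8, {
    d <- simulateDyad(cfg, seed = sample.int(2^20, 1))
    hrM <- homeRange(d$male); hrF <- homeRange(d$female)
    r <- dyadInteraction(d$series, hrM, hrF, d$male, d$female, nights = 4)
    c(gas = r$gas$observed / r$gas$expected,
      hut = r$hutchinson$observed / r$hutchinson$expected)
  })
  expect_gt(mean(ratios["gas", ]), mean(ratios["hut", ]))
  expect_gt(mean(ratios["gas", ]), 1)
})
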