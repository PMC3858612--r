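test_that("simulation is bitwise reproducible under a fixed seed", {
  for (eta in c(0, -1.1)) {
    cfg <- simConfig(eta = eta, nightsPerDyad = 2)
    a <- simulateDyad(cfg, seed = 123)
    b <- simulateDyad(cfg, seed = 123)
    expect_identical(coords(a$male), coords(b$male))
    expect_identical(coords(a$female), coords(b$female))
  }
  s1 <- simulateStudy(simConfig("paper", nDyads = 2, nightsPerDyad = 1),
                      seed = 5)
  s2 <- simulateStudy(simConfig("paper", nDyads = 2, nightsPerDyad = 1),
                      seed = 5)
  expect_identical(s1$sleep, s2$sleep)
  expect_identical(s1$interactions, s2$interactions)
})

test_that("the OU walk attains its configured stationary spread", {
  cfg <- simConfig(eta = 0, nightsPerDyad = 8)
  d <- simulateDyad(cfg, seed = 31)
  emp <- sqrt((var(d$male@x) + var(d$male@y)) / 2)
  expect_equal(emp, cfg$sigmaM, tolerance = 0.1)
  empF <- sqrt((var(d$female@x) + var(d$female@y)) / 2)
  expect_equal(empF, cfg$sigmaF, tolerance = 0.1)
})

test_that("negative coupling pushes partners apart, positive pulls together", {
  meanDist <- function(eta, seeds) {
    cfg <- simConfig(eta = eta, nightsPerDyad = 1, nightHours = 4)
    mean(vapply(seeds, function(s)
      mean(dyadDistances(simulateDyad(cfg, seed = s)$series)), 0))
  }
  seeds <- 1:150
  dAvoid <- meanDist(-1.5, seeds)
  dZero <- meanDist(0, seeds)
  dAttract <- meanDist(1.5, seeds)
  expect_gt(dAvoid, dZero)
  expect_lt(dAttract, dZero)
})

test_that("proximity time is monotone in the coupling strength", {
  prox <- function(eta, seeds) {
    cfg <- simConfig(eta = eta, nightsPerDyad = 1, nightHours = 4)
    mean(vapply(seeds, function(s)
      proximityTime(simulateDyad(cfg, seed = s)$series, 20), 0))
  }
  seeds <- 200 + 1:100
  p <- vapply(c(-0.5, 0, 0.5), prox, 0, seeds = seeds)
  expect_true(all(diff(p) > 0))
})

test_that("zero simultaneity probability forbids simultaneous tree use", {
  cfg <- simConfig("paper", obsDays = 120)
  soc <- simulateSocial(cfg, seed = 83)
  tally <- sleepingTally(soc$sleep,
                         data.frame(male_id = "m1", female_id = "f1"))
  expect_equal(tally$simultaneous_days, 0L)
  expect_equal(tally$observation_days, 120L)
  expect_gt(tally$shared_trees + tally$exclusive_m + tally$exclusive_f, 0)

  relaxed <- simConfig(obsDays = 400, simultaneityProb = 1,
                       nTreesM = 1, nTreesF = 1, nTreesShared = 3)
  socR <- simulateSocial(relaxed, seed = 89)
  tallyR <- sleepingTally(socR$sleep,
                          data.frame(male_id = "m1", female_id = "f1"))
  expect_gt(tallyR$simultaneous_days, 0L)
})

test_that("interaction events arrive at the configured Poisson rate", {
  cfg <- simConfig(rateNeutral = 0.14, rateAgonistic = 0,
                   rateAffiliative = 0, hoursInSight = 516)
  soc <- simulateSocial(cfg, seed = 97)
  n <- nrow(soc$interactions)
  lambda <- 0.14 * 516                  # ~72 expected events
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))

  silent <- simConfig(rateNeutral = 0, rateAgonistic = 0,
                      rateAffiliative = 0)
  expect_equal(nrow(simulateSocial(silent, seed = 101)$interactions), 0L)
})

test_that("the study preset reproduces its qualitative field pattern", {
  cfg <- simConfig("paper", nDyads = 3, nightsPerDyad = 3)
  study <- simulateStudy(cfg, seed = 7)
  expect_equal(length(study$dyads), 3L)
  d1 <- study$dyads[[1]]
  expect_equal(nFixes(d1$series), nFixes(d1$male))
  # avoidance preset: partners mostly beyond 15 m
  expect_lt(proximityTime(d1$series, 15), 50)
  # neighbor centers one spacing apart
  expect_gt(min(study$dyads[[2]]$female@x) - min(d1$female@x), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(bogus = 1), "unknown SimConfig")
  expect_error(simConfig(preset = "other"), "unknown preset")
  expect_error(simConfig(sigmaF = -1))
})
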