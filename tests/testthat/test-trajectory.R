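test_that("subsampling keeps the first fix and enforces the interval", {
  tr <- Trajectory("a", t = c(0, 1, 2, 5, 6, 10) * 60,
                   x = 1:6, y = rep(0, 6))
  expect_equal(fixTimes(subsampleFixes(tr, 300)), c(0, 300, 600))

  empty <- new("Trajectory", id = "e")
  expect_equal(nFixes(subsampleFixes(empty, 300)), 0L)

  exact <- Trajectory("a", t = c(0, 300, 600), x = 1:3, y = 1:3)
  expect_equal(fixTimes(subsampleFixes(exact, 300)), c(0, 300, 600))
})

test_that("subsampling is idempotent on random fix streams", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    tr <- Trajectory("a", t = cumsum(runif(n, 10, 400)),
                     x = rnorm(n), y = rnorm(n))
    iv <- sample(c(60, 300, 900), 1)
    once <- subsampleFixes(tr, iv)
    twice <- subsampleFixes(once, iv)
    expect_equal(fixTimes(twice), fixTimes(once))
    if (nFixes(once) > 1) expect_true(all(diff(once@t) >= iv))
  }
})

test_that("path length matches Euclidean geometry and its invariances", {
  expect_equal(pathLength(Trajectory("a", c(0, 1), c(0, 3), c(0, 4))), 5)
  expect_equal(pathLength(Trajectory("a", 0, 2, 3)), 0)
  expect_equal(
    pathLength(Trajectory("a", c(0, 1, 2), c(0, 3, 3), c(0, 4, 4))), 5)
  expect_error(pathLength(new("Trajectory", id = "e")), "no fixes")

  set.seed(7)
  xy <- matrix(rnorm(40), ncol = 2)
  base <- pathLength(Trajectory("a", 1:20, xy[, 1], xy[, 2]))
  th <- runif(1, 0, 2 * pi)
  rot <- xy %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(
    pathLength(Trajectory("a", 1:20, rot[, 1] + 50, rot[, 2] - 20)),
    base)
})

test_that("dyad alignment pairs nearest fixes within tolerance, each once", {
  a <- Trajectory("m", t = c(0, 60, 120), x = 1:3, y = 1:3, sex = "M")
  b <- Trajectory("f", t = c(0, 60, 120), x = 4:6, y = 4:6, sex = "F")
  expect_equal(nFixes(alignDyad(a, b, tol = 150)), 3L)

  a2 <- Trajectory("m", t = c(0, 600), x = 1:2, y = 1:2, sex = "M")
  b2 <- Trajectory("f", t = c(5, 300), x = 1:2, y = 1:2, sex = "F")
  dy <- alignDyad(a2, b2, tol = 60)
  expect_equal(nFixes(dy), 1L)
  expect_equal(dy@t, 0)

  a3 <- Trajectory("m", t = 0, x = 1, y = 1, sex = "M")
  b3 <- Trajectory("f", t = c(0, 30), x = c(10, 20), y = c(0, 0),
                   sex = "F")
  dy3 <- alignDyad(a3, b3, tol = 60)
  expect_equal(dy3@fx, 10)  # nearest-in-time fix chosen

  # sex slots, not argument order, assign the male/female roles
  dySwap <- alignDyad(b, a, tol = 150)
  expect_equal(dySwap@maleId, "m")
  expect_equal(dySwap@femaleId, "f")
})

test_that("alignment output is bounded and empty when windows disjoint", {
  set.seed(9)
  for (i in 1:10) {
    na <- sample(1:30, 1); nb <- sample(1:30, 1)
    a <- Trajectory("m", t = sort(runif(na, 0, 1e4)) + 1:na * 1e-3,
                    x = rnorm(na), y = rnorm(na), sex = "M")
    b <- Trajectory("f", t = sort(runif(nb, 0, 1e4)) + 1:nb * 1e-3,
                    x = rnorm(nb), y = rnorm(nb), sex = "F")
    expect_lte(nFixes(alignDyad(a, b, tol = 120)), min(na, nb))
  }
  far <- Trajectory("f", t = c(1e6, 1e6 + 60), x = 1:2, y = 1:2,
                    sex = "F")
  near <- Trajectory("m", t = c(0, 60), x = 1:2, y = 1:2, sex = "M")
  expect_equal(nFixes(alignDyad(near, far, tol = 150)), 0L)
})

test_that("trajectory CSV round-trips and rejects malformed input", {
  tdir <- withr::local_tempdir()
  f <- file.path(tdir, "traj.csv")
  tr1 <- Trajectory("m1", t = c(0, 300), x = c(1.5, 2.5), y = c(0, 1),
                    sex = "M", night = "n01")
  tr2 <- Trajectory("f1", t = c(0, 300, 600), x = 1:3, y = 3:1,
                    sex = "F", night = "n01")
  writeTrajectories(list(tr1, tr2), f)
  back <- readTrajectories(f)
  expect_setequal(names(back), c("m1.n01", "f1.n01"))
  expect_equal(coords(back$m1.n01), coords(tr1))
  expect_equal(back$f1.n01@sex, "F")

  bad <- file.path(tdir, "bad.csv")
  writeLines(c("individual_id,sex,night_id,timestamp,x,y",
               "a,M,n01,0,1,2", "a,M,n01,60,NaN,2"), bad)
  expect_error(readTrajectories(bad), "line")
  writeLines(c("individual_id,night_id,timestamp,x,y",
               "a,n01,0,1,2"), bad)
  expect_error(readTrajectories(bad), "sex")
})

test_that("trajectory validity rejects unordered times and NA coords", {
  expect_error(new("Trajectory", id = "a", sex = "M", night = "n",
                   t = c(2, 1), x = c(0, 0), y = c(0, 0),
                   inSight = c(TRUE, TRUE)), "increasing")
  expect_error(new("Trajectory", id = "a", sex = "M", night = "n",
                   t = c(1, 2), x = c(0, NA), y = c(0, 0),
                   inSight = c(TRUE, TRUE)), "finite")
})
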