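test_that("standardizeIntensities centers and scales with the population convention", {
  expect_equal(standardizeIntensities(matrix(7, 3, 3)),
               matrix(0, 3, 3))
  expect_equal(as.vector(standardizeIntensities(matrix(c(0, 2), 1))),
               c(-1, 1))
  expect_equal(as.vector(standardizeIntensities(matrix(1:3, 1))),
               c(-1, 0, 1) * sqrt(3 / 2))  # population sd: divide by sqrt(2/3)
  out <- standardizeIntensities(matrix(rnorm(35, 50, 9), 5, 7))
  expect_equal(dim(out), c(5L, 7L))
  expect_equal(mean(out), 0)
  expect_equal(sqrt(mean(out^2)), 1)
  # affine invariance
  m <- matrix(runif(12), 3, 4)
  expect_equal(standardizeIntensities(3.2 * m + 17), standardizeIntensities(m))
})

test_that("standardizeIntensities names the offending pixel on non-finite input", {
  m <- matrix(1, 2, 3)
  m[2, 3] <- NaN
  expect_error(standardizeIntensities(m), "\\(2,3\\)")
})

test_that("crpWeights follows the CRP predictive", {
  expect_equal(crpWeights(integer(0), 1, normalize = TRUE), 1)
  w <- crpWeights(c(1, 1, 1), 1, normalize = TRUE)
  expect_equal(w[4], 0.25)
  expect_equal(crpWeights(c(5, 3), 0.01), c(5, 3, 0.01))
  expect_equal(crpWeights(c(5, 3), 0.01, normalize = TRUE),
               c(5, 3, 0.01) / 8.01)
  expect_error(crpWeights(c(2, 0), 1), "positive")
})

test_that("crpWeights properties: normalization and alpha0 monotonicity", {
  set.seed(1)
  for (rep in 1:25) {
    counts <- sample(1:20, sample(1:6, 1), replace = TRUE)
    a <- runif(1, 0.01, 5)
    w <- crpWeights(counts, a, normalize = TRUE)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w[length(w)], a / (a + sum(counts)))
    # new-cluster mass strictly increases in alpha0
    w2 <- crpWeights(counts, a * 2, normalize = TRUE)
    expect_gt(w2[length(w2)], w[length(w)])
  }
})

test_that("logPredictive is the NIG posterior predictive (Student-t)", {
  hp <- hyperParameters(baseMu0 = 0, baseKappa0 = 1, baseA0 = 1, baseB0 = 1)
  # symmetry and unimodality of the prior predictive
  for (cc in c(0.3, 1, 4))
    expect_equal(logPredictive(cc, atomStats(), hp),
                 logPredictive(-cc, atomStats(), hp))
  expect_gt(logPredictive(0, atomStats(), hp),
            logPredictive(5, atomStats(), hp))
  # closed form at x = 0: Student-t(df 2, scale sqrt(2))
  expect_equal(logPredictive(0, atomStats(), hp),
               dt(0 / sqrt(2), df = 2, log = TRUE) - log(sqrt(2)))
  # against direct numerical integration of Normal x NIG over (mu, sigma2)
  numInt <- integrate(function(s2) {
    sapply(s2, function(v)
      integrate(function(mu)
        dnorm(0, mu, sqrt(v)) * dnorm(mu, 0, sqrt(v / 1)), -30, 30)$value *
        1 / gamma(1) * v^(-1 - 1) * exp(-1 / v))
  }, 0, Inf)$value
  expect_equal(logPredictive(0, atomStats(), hp), log(numInt),
               tolerance = 1e-4)
})

test_that("logPredictive converges to the Gaussian density at large count", {
  hp <- hyperParameters()
  m <- 0.7; v <- 1.9; n <- 1e4
  stats <- c(n, n * m, n * (v + m^2))
  for (x in c(-1, 0.7, 3))
    expect_equal(logPredictive(x, stats, hp),
                 dnorm(x, m, sqrt(v), log = TRUE), tolerance = 1e-2)
})

test_that("atomAdd/atomRemove are exact inverses", {
  s <- atomAdd(atomStats(), 2)
  expect_equal(atomCount(s), 1L)
  expect_equal(s@sumX, 2)
  expect_equal(s@sumX2, 4)
  expect_error(atomRemove(atomStats(), 1), "empty")
  set.seed(4)
  s0 <- atomStats(3L, 1.5, 4.2)
  x <- rnorm(1)
  s1 <- atomRemove(atomAdd(s0, x), x)
  expect_equal(s1@count, s0@count)
  expect_equal(s1@sumX, s0@sumX, tolerance = 1e-9)
  expect_equal(s1@sumX2, s0@sumX2, tolerance = 1e-9)
  # add ten, remove in shuffled order -> empty
  xs <- rnorm(10)
  s <- Reduce(atomAdd, xs, atomStats())
  for (x in sample(xs)) s <- atomRemove(s, x)
  expect_equal(atomCount(s), 0L)
  expect_equal(s@sumX, 0, tolerance = 1e-9)
  expect_equal(s@sumX2, 0, tolerance = 1e-9)
})

test_that("hyperparameter validity rejects out-of-range values", {
  expect_error(hyperParameters(alpha0 = 0), "alpha0")
  expect_error(hyperParameters(lam = -1), "lam")
  expect_error(hyperParameters(baseA0 = -2), "baseA0")
  hp <- hyperParameters()
  expect_equal(hp@alpha0, 0.01)
  expect_equal(hp@lam, 0.001)
  expect_equal(hp@gamma, 1)
})
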