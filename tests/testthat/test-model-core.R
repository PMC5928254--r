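test_that("null density matches the closed-form normal pdf", {
  expect_equal(nullDensity(0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # one SD out at the typical GWAS noise scale
  expect_equal(nullDensity(0.03, 0.03^2),
               exp(-0.5) / (0.03 * sqrt(2 * pi)), tolerance = 1e-12)
  # far tail underflows to 0 without error
  expect_identical(nullDensity(10, 1e-4), 0)
  expect_error(nullDensity(0, 0), "must be > 0")
  expect_error(nullDensity(0, -1), "must be > 0")
})

test_that("non-null density collapses, sums and respects symmetry", {
  g2 <- effectGrid(points = c(-0.05, 0.05))
  # all mass on one point: plain shifted normal at its mode
  expect_equal(nonnullDensity(0.05, 0.01, mixturePrior(1, c(0, 1), g2)),
               dnorm(0, 0, 0.1), tolerance = 1e-12)

  # uniform masses on the default grid vs direct 120-term summation
  grid <- effectGrid()
  b <- gridPoints(grid)
  pr <- uniformPrior(0.5, grid)
  direct <- sum(rep(1 / 120, 120) * dnorm(0, b, 1))
  expect_equal(nonnullDensity(0, 1, pr), direct, tolerance = 1e-12)

  # symmetric masses: f1(y) == f1(-y)
  set.seed(1)
  half <- runif(60)
  sym <- c(rev(half), half); sym <- sym / sum(sym)
  prSym <- mixturePrior(0.5, sym, grid)
  for (y in c(0.01, 0.07, 0.2))
    expect_equal(nonnullDensity(y, 0.004, prSym),
                 nonnullDensity(-y, 0.004, prSym), tolerance = 1e-12)

  expect_error(nonnullDensity(0, 1, c(0.5, 0.5), effectGrid()),
               "misaligned")
})

test_that("marginal log-likelihood reduces correctly at pi = 0 and pi = 1", {
  ss <- tinySumstats()
  grid <- effectGrid(points = c(-0.1, 0.02, 0.1))
  expect_equal(marginalLogLik(ss, uniformPrior(0, grid)),
               sum(dnorm(ss$y, 0, sqrt(ss$v), log = TRUE)),
               tolerance = 1e-10)
  prPoint <- mixturePrior(1, c(0, 1, 0), grid)
  expect_equal(marginalLogLik(ss, prPoint),
               sum(dnorm(ss$y, 0.02, sqrt(ss$v), log = TRUE)),
               tolerance = 1e-10)
})

test_that("marginal log-likelihood matches the naive summation oracle", {
  ss <- tinySumstats(m = 10)
  grid <- effectGrid(points = c(-0.08, -0.02, 0.03, 0.11))
  set.seed(3)
  masses <- runif(4); masses <- masses / sum(masses)
  pr <- mixturePrior(0.37, masses, grid)
  expect_equal(marginalLogLik(ss, pr),
               naiveLoglik(ss$y, ss$v, 0.37, masses, gridPoints(grid)),
               tolerance = 1e-10)
})

test_that("log-shifted likelihood stays finite where naive evaluation fails", {
  # v ~ 1e-4 and |y| far outside the grid: every component underflows in
  # direct double-precision evaluation
  ss <- sumstats(c("a", "b"), beta = c(1.5, -2), var = c(1e-4, 1e-4))
  pr <- uniformPrior(0.3)
  expect_true(is.finite(marginalLogLik(ss, pr)))
  expect_true(is.infinite(naiveLoglik(ss$y, ss$v, 0.3, priorMasses(pr),
                                      gridPoints(pr))))
})

test_that("marginal density is a convex combination of components", {
  ss <- tinySumstats(m = 25, seed = 5)
  pr <- uniformPrior(0.42)
  f0 <- nullDensity(ss$y, ss$v)
  f1 <- nonnullDensity(ss$y, ss$v, pr)
  f <- (1 - 0.42) * f0 + 0.42 * f1
  expect_true(all(f >= pmin(f0, f1) - 1e-15))
  expect_true(all(f <= pmax(f0, f1) + 1e-15))
  expect_true(all(f0 >= 0) && all(f1 >= 0))
})

test_that("log-likelihood is continuous in pi and in the masses", {
  ss <- tinySumstats(m = 15, seed = 7)
  grid <- effectGrid(points = c(-0.1, 0.1))
  base <- marginalLogLik(ss, mixturePrior(0.3, c(0.4, 0.6), grid))
  eps <- 1e-7
  perturbedPi <- marginalLogLik(ss, mixturePrior(0.3 + eps, c(0.4, 0.6),
                                                 grid))
  perturbedP <- marginalLogLik(
    ss, mixturePrior(0.3, c(0.4 + eps, 0.6 - eps), grid))
  expect_lt(abs(perturbedPi - base), 1e-4)
  expect_lt(abs(perturbedP - base), 1e-4)
})

test_that("grid and prior constructors enforce their invariants", {
  g <- effectGrid()
  b <- gridPoints(g)
  expect_length(b, 120)
  expect_equal(range(b), c(-0.3, 0.3))
  expect_false(0 %in% b)
  expect_true(all(diff(b) > 0))

  expect_error(effectGrid(points = c(0.1, 0, 0.2)), "admissible")
  expect_error(effectGrid(points = c(0.2, 0.1)), "increasing")
  expect_error(effectGrid(points = 0.1), "2 points")

  expect_error(mixturePrior(1.2, c(0.5, 0.5), effectGrid(points = c(-1, 1))))
  expect_error(mixturePrior(0.5, c(0.5, 0.4), effectGrid(points = c(-1, 1))),
               "sum")
  expect_error(mixturePrior(0.5, c(0.2, 0.2, 0.6)), "misaligned")
})
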