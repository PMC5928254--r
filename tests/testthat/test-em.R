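test_that("E-step degenerates correctly at pi = 0 and pi = 1", {
  ss <- tinySumstats()
  grid <- effectGrid(points = c(-0.05, 0.05))
  r0 <- eStep(ss, uniformPrior(0, grid))$r0
  expect_equal(r0, rep(1, nrow(ss)), tolerance = 1e-12)
  r0 <- eStep(ss, uniformPrior(1, grid))$r0
  expect_equal(r0, rep(0, nrow(ss)), tolerance = 1e-12)
})

test_that("E-step matches naive Bayes-rule arithmetic and rows sum to 1", {
  ss <- tinySumstats(m = 5, seed = 11)
  grid <- effectGrid(points = c(-0.06, 0.01, 0.09))
  masses <- c(0.2, 0.5, 0.3)
  pr <- mixturePrior(0.35, masses, grid)
  got <- eStep(ss, pr)
  ora <- naiveEStep(ss$y, ss$v, 0.35, masses, gridPoints(grid))
  expect_equal(got$r0, ora$r0, tolerance = 1e-12)
  expect_equal(got$r, ora$r, tolerance = 1e-12)
  expect_equal(got$r0 + rowSums(got$r), rep(1, 5), tolerance = 1e-10)
  expect_true(all(got$r0 >= 0 & got$r0 <= 1) & all(got$r >= 0 & got$r <= 1))
})

test_that("M-step reproduces hand-summed ratios and handles degeneracy", {
  grid <- effectGrid(points = c(-0.1, 0.02, 0.2))
  pr <- uniformPrior(0.5, grid)

  # all-null responsibilities: pi -> 0 with a warning, masses untouched
  respNull <- list(r0 = rep(1, 4), r = matrix(0, 4, 3))
  expect_warning(up <- mStep(respNull, pr), "null")
  expect_equal(priorPi(up), 0)
  expect_equal(priorMasses(up), priorMasses(pr))

  # all non-null, mass concentrated on point 3
  respOne <- list(r0 = rep(0, 4),
                  r = matrix(rep(c(0, 0, 1), each = 4), 4, 3))
  up <- mStep(respOne, pr)
  expect_equal(priorPi(up), 1)
  expect_equal(priorMasses(up), c(0, 0, 1))

  # random valid responsibilities vs spreadsheet arithmetic
  set.seed(13)
  raw <- matrix(runif(4 * 4), 4, 4)
  raw <- raw / rowSums(raw)
  resp <- list(r0 = raw[, 1], r = raw[, -1, drop = FALSE])
  up <- mStep(resp, pr)
  denom <- sum(1 - resp$r0)
  expect_equal(priorPi(up), mean(1 - resp$r0), tolerance = 1e-12)
  expect_equal(priorMasses(up), colSums(resp$r) / denom, tolerance = 1e-12)
  expect_equal(sum(priorMasses(up)), 1, tolerance = 1e-10)
})

test_that("EM drives pi toward 0 on pure-noise data", {
  sim <- simulateSumstats(m = 10000, piTrue = 0, nCase = 5e4,
                          nControl = 5e4, seed = 17)
  fit <- sphmmFit(sim$sumstats, fastConfig())
  expect_lt(priorPi(fit), 0.01)

  # exactly null-centered data: y = 0, v = 1; the full schedule (its long
  # final stage) is what walks pi down toward the boundary
  ssZero <- sumstats(sprintf("z%03d", 1:200), beta = rep(0, 200),
                     var = rep(1, 200))
  fitZero <- sphmmFit(ssZero)
  expect_lt(priorPi(fitZero), 0.01)
})

test_that("log-likelihood trace is monotone and runEM honors update flags", {
  ss <- simulateSumstats(m = 400, piTrue = 0.3, nCase = 2e4,
                         nControl = 2e4, seed = 19)$sumstats
  start <- uniformPrior(0.5, effectGrid(points = seq(-0.2, 0.2, 0.05)[-5]))
  res <- runEM(ss, start, maxIters = 100, relTol = 0)
  expect_true(all(diff(res$loglikTrace) >= -1e-8))

  # frozen pi stays frozen; frozen masses stay frozen
  resPi <- runEM(ss, start, maxIters = 20, relTol = 0, updatePi = FALSE,
                 monitor = "loglik")
  expect_equal(priorPi(resPi$prior), 0.5)
  resMass <- runEM(ss, start, maxIters = 20, relTol = 0,
                   updateMasses = FALSE)
  expect_equal(priorMasses(resMass$prior), priorMasses(start))
})

test_that("fitted likelihood matches exhaustive lattice search (B = 2)", {
  grid <- effectGrid(points = c(-0.1, 0.1))
  set.seed(23)
  m <- 80
  truthNonnull <- runif(m) < 0.4
  beta <- ifelse(truthNonnull, sample(c(-0.1, 0.1), m, TRUE, c(0.3, 0.7)), 0)
  v <- runif(m, 1e-3, 4e-3)
  ss <- sumstats(sprintf("s%02d", 1:m), beta = rnorm(m, beta, sqrt(v)),
                 var = v)
  cfg <- fitConfig(gridLo = -0.1, gridHi = 0.1, gridStep = 0.2,
                   finalRelTol = 1e-10, finalMaxIters = 50000L)
  suppressWarnings(fit <- sphmmFit(ss, cfg))
  expect_length(gridPoints(fit@prior@grid), 2L)
  oracle <- latticeMaxLoglik(ss$y, ss$v, c(-0.1, 0.1))
  expect_lt(abs(tail(loglikTrace(fit), 1) - oracle$best), 1e-6)
})

test_that("three-stage schedule records initialization and is deterministic", {
  sim <- simulateSumstats(m = 800, piTrue = 0.2, nCase = 5e4,
                          nControl = 5e4, seed = 29)
  cfg <- fastConfig()
  f1 <- sphmmFit(sim$sumstats, cfg)
  f2 <- sphmmFit(sim$sumstats, cfg)
  expect_identical(priorPi(f1), priorPi(f2))
  expect_identical(priorMasses(f1), priorMasses(f2))
  expect_identical(loglikTrace(f1), loglikTrace(f2))

  # stage-1 table covers every candidate and selected the best likelihood
  expect_equal(f1@stage1Table$pi_start, seq(0.1, 0.9, 0.1))
  expect_equal(f1@piInit,
               f1@stage1Table$pi_after[which.max(f1@stage1Table$loglik)])
  expect_equal(sum(f1@gInit), 1, tolerance = 1e-10)
  expect_s4_class(f1, "SphmmFit")
  expect_true(validObject(f1))
})

test_that("mass conservation holds after every update of a full run", {
  ss <- simulateSumstats(m = 300, piTrue = 0.15, nCase = 3e4,
                         nControl = 3e4, seed = 31)$sumstats
  pr <- uniformPrior(0.4, effectGrid(points = seq(-0.15, 0.15, 0.03)[-6]))
  for (i in 1:10) {
    pr <- mStep(eStep(ss, pr), pr)
    expect_equal(sum(priorMasses(pr)), 1, tolerance = 1e-10)
  }
})

test_that("small-sample warning fires below 100 SNPs", {
  ss <- tinySumstats(m = 20)
  expect_warning(sphmmFit(ss, fastConfig()), "fewer than 100")
})
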