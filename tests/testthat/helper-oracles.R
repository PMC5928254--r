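# Independent oracles and small fixtures shared across test files. These
# deliberately use naive, direct formulas (plain loops and sums) so they
# stay independent of the package's vectorized/log-shifted code paths.

# Naive marginal log-likelihood: direct summation, no log-scale shifting.
naiveLoglik <- function(y, v, pi, masses, b) {
  ll <- 0
  for (j in seq_along(y)) {
    f0 <- dnorm(y[j], 0, sqrt(v[j]))
    f1 <- sum(masses * dnorm(y[j], b, sqrt(v[j])))
    ll <- ll + log((1 - pi) * f0 + pi * f1)
  }
  ll
}

# Naive per-cell E-step by Bayes' rule.
naiveEStep <- function(y, v, pi, masses, b) {
  m <- length(y); B <- length(b)
  r0 <- numeric(m); r <- matrix(0, m, B)
  for (j in seq_len(m)) {
    f0 <- (1 - pi) * dnorm(y[j], 0, sqrt(v[j]))
    fb <- pi * masses * dnorm(y[j], b, sqrt(v[j]))
    tot <- f0 + sum(fb)
    r0[j] <- f0 / tot
    r[j, ] <- fb / tot
  }
  list(r0 = r0, r = r)
}

# Exhaustive lattice maximization of the B = 2 likelihood over (pi, p1),
# with iterative zooming around the best lattice point.
latticeMaxLoglik <- function(y, v, b, zooms = 5L, width = 41L) {
  stopifnot(length(b) == 2L)
  evalGrid <- function(pis, p1s) {
    K1 <- dnorm(y, b[1], sqrt(v)); K2 <- dnorm(y, b[2], sqrt(v))
    f0 <- dnorm(y, 0, sqrt(v))
    best <- -Inf; arg <- c(NA, NA)
    for (pi in pis) {
      # m x length(p1s): mixture density for every p1 at once
      F1 <- outer(K1, p1s) + outer(K2, 1 - p1s)
      ll <- colSums(log((1 - pi) * f0 + pi * F1))
      i <- which.max(ll)
      if (ll[i] > best) { best <- ll[i]; arg <- c(pi, p1s[i]) }
    }
    list(best = best, arg = arg)
  }
  lo <- c(0, 0); hi <- c(1, 1)
  res <- NULL
  for (z in seq_len(zooms)) {
    pis <- seq(lo[1], hi[1], length.out = width)
    p1s <- seq(lo[2], hi[2], length.out = width)
    res <- evalGrid(pis, p1s)
    stepPi <- (hi[1] - lo[1]) / (width - 1)
    stepP1 <- (hi[2] - lo[2]) / (width - 1)
    lo <- pmax(c(res$arg[1] - 2 * stepPi, res$arg[2] - 2 * stepP1), 0)
    hi <- pmin(c(res$arg[1] + 2 * stepPi, res$arg[2] + 2 * stepP1), 1)
  }
  res
}

# From-scratch liability-scale variance oracle: penetrance constraint
# solved by plain uniroot bisection, means and variance by the printed
# formulas, anchored at an *arbitrary* location (mu_0 = 0) to double as a
# check that the package's threshold-anchored convention is immaterial.
oracleLiabilityVariance <- function(beta, p, K) {
  h <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  constraint <- function(a)
    sum(h / (1 + exp(-a - beta * 0:2))) - K
  a <- uniroot(constraint, c(-60, 60), tol = 1e-14)$root
  phi <- 1 / (1 + exp(-a - beta * 0:2))
  # Phi^{-1}(1 - phi_x) = T - mu_x; fix mu_0 = 0, so T = qnorm(1 - phi_0)
  Tthr <- qnorm(1 - phi[1])
  mu <- Tthr - qnorm(1 - phi)
  muAll <- sum(h * mu)
  vStar <- sum(h * (mu - muAll)^2)
  vStar / (1 + vStar)
}

# Checker for pruned SNP sets: kept set must be an independent set of the
# r2 > threshold graph, and every removed SNP must be linked to some kept
# SNP selected before it could be reached (maximality).
checkPrunedSet <- function(kept, allIds, ldPairs, r2Threshold) {
  linked <- ldPairs[ldPairs$R2 > r2Threshold, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- unique(key(linked$SNP_A, linked$SNP_B))
  keptPairs <- outer(kept, kept, key)
  independent <- !any(keptPairs[upper.tri(keptPairs)] %in% edges)
  removed <- setdiff(allIds, kept)
  coverable <- vapply(removed, function(s)
    any(key(s, kept) %in% edges), logical(1))
  maximal <- length(removed) == 0L || all(coverable)
  independent && maximal
}

# Small deterministic dataset used across files.
tinySumstats <- function(m = 10, seed = 99) {
  set.seed(seed)
  sumstats(sprintf("s%02d", seq_len(m)),
           beta = round(rnorm(m, 0, 0.05), 4),
           var = round(runif(m, 5e-4, 5e-3), 6))
}

# Reduced-effort fit configuration for unit tests on small m, where the
# full 200/200/2000 schedule is unnecessary.
fastConfig <- function(...)
  fitConfig(stage1Iters = 30L, stage2MaxIters = 50L,
            finalMaxIters = 300L, ...)
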