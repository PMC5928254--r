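# Model core: null / non-null / marginal densities of the two-group
# semi-parametric hierarchical mixture model.
#
# Per SNP j the observed log-odds ratio y_j is modeled as
#   null:     y_j ~ N(0, v_j)
#   non-null: y_j | beta_j ~ N(beta_j, v_j),  beta_j ~ g  (grid masses p)
#   marginal: f_j(y_j) = (1 - pi) f0_j(y_j) + pi f1_j(y_j)
# Mutual independence across SNPs is assumed, which is reasonable for an
# LD-pruned panel.

#' Null-component density
#'
#' Density of the asymptotic null distribution \eqn{N(0, v)} of an estimated
#' log-odds ratio with sampling variance \eqn{v}, evaluated at `y`.
#'
#' @param y observed log-odds ratio(s).
#' @param v positive sampling variance(s), recycled against `y`.
#' @return nonnegative density values; far-tail evaluations underflow to 0
#'   without error.
#' @examples
#' nullDensity(0, 1)           # 1/sqrt(2*pi)
#' nullDensity(0.03, 0.03^2)   # value one SD out
#' @export
nullDensity <- function(y, v) {
  if (any(!is.finite(v) | v <= 0)) stop("sampling variance v must be > 0")
  dnorm(y, mean = 0, sd = sqrt(v))
}

#' Non-null-component density
#'
#' Marginal density of the non-null component: the true effect is drawn from
#' the grid prior \eqn{g} and observed with normal noise, giving the mixture
#' \eqn{f_1(y) = \sum_b p_b\, N(y;\, b,\, v)}.
#'
#' @inheritParams nullDensity
#' @param prior a [MixturePrior-class] (its `pi` is not used here) or a
#'   numeric vector of masses, in which case `grid` must be supplied.
#' @param grid an [EffectGrid-class], required when `prior` is a bare vector.
#' @return nonnegative density values, vectorized over `y`/`v`.
#' @examples
#' g <- effectGrid(points = c(-0.05, 0.05))
#' pr <- mixturePrior(1, c(0, 1), g)
#' nonnullDensity(0.05, 0.01, pr)  # == dnorm(0, sd = 0.1)
#' @export
nonnullDensity <- function(y, v, prior, grid = NULL) {
  if (is(prior, "MixturePrior")) {
    masses <- prior@masses
    b <- gridPoints(prior@grid)
  } else {
    if (is.null(grid)) stop("grid must be supplied with bare masses")
    masses <- as.numeric(prior)
    b <- gridPoints(grid)
    if (length(masses) != length(b))
      stop("masses (", length(masses), ") and grid (", length(b),
           ") are misaligned")
  }
  if (any(!is.finite(v) | v <= 0)) stop("sampling variance v must be > 0")
  n <- max(length(y), length(v))
  y <- rep_len(y, n); v <- rep_len(v, n)
  # m x B kernel; fine uncached at this call granularity
  K <- dnorm(outer(y, b, "-"), sd = sqrt(v))
  as.numeric(K %*% masses)
}

# Internal kernel cache: everything the EM reuses across iterations.
# Row-wise log-scale shift keeps tail densities representable (v can be
# ~1e-4, so raw densities underflow); all mixture evaluations downstream are
# exact up to the shared per-row factor exp(shift_j).
.kernelCache <- function(data, grid) {
  y <- data$y; v <- data$v
  sdv <- sqrt(v)
  b <- gridPoints(grid)
  logF0 <- dnorm(y, 0, sdv, log = TRUE)
  logK <- dnorm(outer(y, b, "-"), sd = sdv, log = TRUE)
  rowMax <- logK[cbind(seq_along(y), max.col(logK, ties.method = "first"))]
  shift <- pmax(logF0, rowMax)
  list(f0 = exp(logF0 - shift), K = exp(logK - shift), shift = shift,
       m = length(y), B = length(b), grid = grid)
}

# Internal: marginal density (shifted scale) and loglik given a cache.
.marginalFromCache <- function(cache, pi, masses) {
  f1 <- as.numeric(cache$K %*% masses)
  f <- (1 - pi) * cache$f0 + pi * f1
  list(f = f, f1 = f1, loglik = sum(log(f) + cache$shift))
}

#' Marginal log-likelihood of the two-group mixture
#'
#' Total log-likelihood \eqn{\sum_j \log[(1-\pi) f_{0j}(y_j) + \pi
#' f_{1j}(y_j)]} over independent SNPs, evaluated with per-SNP log-scale
#' shifting so that finite inputs never produce \eqn{-\infty}.
#'
#' @param data summary-statistics data.frame (see [sumstats()]).
#' @param prior a [MixturePrior-class].
#' @return a single finite number.
#' @examples
#' ss <- sumstats("rs1", beta = 0.1, se = 0.05)
#' marginalLogLik(ss, uniformPrior(0.2))
#' @export
marginalLogLik <- function(data, prior) {
  .checkSumstats(data)
  stopifnot(is(prior, "MixturePrior"))
  cache <- .kernelCache(data, prior@grid)
  .marginalFromCache(cache, prior@pi, prior@masses)$loglik
}
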