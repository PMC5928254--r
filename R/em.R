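# Empirical Bayes estimation of (pi, g) by the smoothing-and-roughening EM
# for a nonparametric mixing distribution on a fixed grid, wrapped in the
# three-stage schedule: candidate-pi sweep -> g warm-up at fixed pi -> full
# EM. Early stopping (iteration caps) is the smoothing mechanism; no
# explicit penalty is placed on g.

.PI_EPS <- 1e-12

#' Fit configuration for the three-stage EM
#'
#' Collects the tunables of [sphmmFit()]. Defaults reproduce the standard
#' schedule: candidate starts \eqn{\pi = 0.1, \dots, 0.9} run for 200 EM
#' iterations each (stage 1); the best-likelihood candidate fixes
#' \eqn{\pi_{init}} and \eqn{g} is re-estimated from uniform at that fixed
#' \eqn{\pi} until the relative log-likelihood change falls below 0.005\% or
#' 200 iterations (stage 2); the full EM then runs from
#' \eqn{(\pi_{init}, g_{init})} until the relative change of \eqn{\pi} in one
#' iteration is below 0.005\% or 2000 iterations (stage 3).
#'
#' @param gridLo,gridHi,gridStep effect-size grid specification passed to
#'   [effectGrid()]; defaults give the 120-point grid on \eqn{[-0.3, 0.3]}.
#' @param candidatePis stage-1 starting values for \eqn{\pi}.
#' @param stage1Iters EM iterations per stage-1 candidate.
#' @param stage2MaxIters,stage2RelTol stage-2 cap and relative
#'   log-likelihood tolerance (0 disables the tolerance, making the cap the
#'   only stopping rule).
#' @param finalMaxIters,finalRelTol stage-3 cap and relative-\eqn{\pi}
#'   tolerance.
#' @return a named list of validated settings.
#' @export
fitConfig <- function(gridLo = -0.3, gridHi = 0.3, gridStep = 0.005,
                      candidatePis = seq(0.1, 0.9, by = 0.1),
                      stage1Iters = 200L,
                      stage2MaxIters = 200L, stage2RelTol = 5e-5,
                      finalMaxIters = 2000L, finalRelTol = 5e-5) {
  stopifnot(stage1Iters >= 1L, stage2MaxIters >= 1L, finalMaxIters >= 1L,
            stage2RelTol >= 0, finalRelTol >= 0,
            all(candidatePis > 0 & candidatePis < 1))
  list(gridLo = gridLo, gridHi = gridHi, gridStep = gridStep,
       candidatePis = sort(candidatePis),
       stage1Iters = as.integer(stage1Iters),
       stage2MaxIters = as.integer(stage2MaxIters),
       stage2RelTol = stage2RelTol,
       finalMaxIters = as.integer(finalMaxIters),
       finalRelTol = finalRelTol)
}

#' E-step: posterior responsibilities under the current prior
#'
#' For each SNP computes the posterior probability of the null component,
#' \eqn{r_{0j} = (1-\pi) f_{0j}(y_j) / f_j(y_j)}, and of each grid point,
#' \eqn{r_{jb} = \pi p_b N(y_j; b, v_j) / f_j(y_j)}; each row sums to 1.
#'
#' @inheritParams marginalLogLik
#' @return list with `r0` (length-m vector) and `r` (m x B matrix).
#' @export
eStep <- function(data, prior) {
  .checkSumstats(data)
  stopifnot(is(prior, "MixturePrior"))
  cache <- .kernelCache(data, prior@grid)
  .eStepCache(cache, prior@pi, prior@masses)
}

.eStepCache <- function(cache, pi, masses) {
  mar <- .marginalFromCache(cache, pi, masses)
  r0 <- (1 - pi) * cache$f0 / mar$f
  r <- cache$K * rep(pi * masses, each = cache$m) / mar$f
  list(r0 = r0, r = r)
}

#' M-step: update the mixture prior from responsibilities
#'
#' \eqn{\pi \leftarrow \mathrm{mean}_j(1 - r_{0j})} and \eqn{p_b \leftarrow
#' \sum_j r_{jb} / \sum_j (1 - r_{0j})}. If no posterior mass is non-null
#' the masses are left at their previous values, \eqn{\pi} is set to 0, and
#' a warning is raised rather than an error.
#'
#' @param resp responsibilities from [eStep()].
#' @param prior the current [MixturePrior-class] (source of the grid and of
#'   fallback masses in the degenerate all-null case).
#' @return the updated [MixturePrior-class].
#' @export
mStep <- function(resp, prior) {
  stopifnot(is(prior, "MixturePrior"))
  nonnull <- 1 - resp$r0
  denom <- sum(nonnull)
  if (denom <= 0) {
    warning("all posterior mass is null; pi set to 0, masses unchanged")
    return(mixturePrior(0, prior@masses, prior@grid))
  }
  piNew <- mean(nonnull)
  pNew <- colSums(resp$r) / denom
  mixturePrior(piNew, pNew / sum(pNew), prior@grid)
}

# Internal EM engine over a kernel cache. monitor = "pi" stops on the
# relative change of pi; "loglik" on the relative change of the
# log-likelihood (used when pi is frozen). relTol = 0 never triggers, so the
# iteration cap is the stopping rule. pi is clipped away from {0, 1} so
# relative changes stay defined.
.runEMCache <- function(cache, pi, masses, maxIters, relTol,
                        updatePi = TRUE, updateMasses = TRUE,
                        monitor = c("pi", "loglik")) {
  monitor <- match.arg(monitor)
  m <- cache$m
  trace <- numeric(maxIters + 1L)
  converged <- FALSE
  iters <- 0L
  degenerate <- FALSE
  mar <- .marginalFromCache(cache, pi, masses)
  trace[1L] <- mar$loglik
  for (t in seq_len(maxIters)) {
    w <- 1 / mar$f
    # sum_j r_jb = pi * p_b * sum_j K_jb / f_j ; sum_j (1 - r0_j) = pi *
    # sum_j f1_j / f_j  -- the E-step never needs materializing
    nonnullSum <- pi * sum(mar$f1 * w)
    piNew <- if (updatePi) nonnullSum / m else pi
    if (updateMasses) {
      if (nonnullSum > 0) {
        p <- pi * masses * as.numeric(crossprod(cache$K, w)) / nonnullSum
        massesNew <- p / sum(p)
      } else {
        degenerate <- TRUE
        massesNew <- masses
        if (updatePi) piNew <- 0
      }
    } else massesNew <- masses
    piNew <- min(max(piNew, .PI_EPS), 1 - .PI_EPS)
    relPi <- abs(piNew - pi) / pi
    pi <- piNew; masses <- massesNew
    mar <- .marginalFromCache(cache, pi, masses)
    iters <- t
    trace[t + 1L] <- mar$loglik
    relLL <- abs(trace[t + 1L] - trace[t]) / abs(trace[t])
    crit <- if (monitor == "pi") relPi else relLL
    if (relTol > 0 && crit < relTol) { converged <- TRUE; break }
  }
  list(pi = pi, masses = masses, loglikTrace = trace[seq_len(iters + 1L)],
       nIters = iters, converged = converged, degenerate = degenerate)
}

#' Run the EM from a given starting prior
#'
#' Alternates [eStep()] and [mStep()] (in a fused, cache-reusing form) from
#' `start`, optionally holding \eqn{\pi} or the masses fixed. The marginal
#' log-likelihood is non-decreasing across iterations, a property the
#' returned trace lets you verify.
#'
#' @inheritParams marginalLogLik
#' @param start starting [MixturePrior-class].
#' @param maxIters iteration cap (>= 1).
#' @param relTol relative-change stopping tolerance; 0 disables it.
#' @param updatePi,updateMasses which parameters the M-step updates.
#' @param monitor monitored scalar for the stopping rule: `"pi"` or
#'   `"loglik"`.
#' @return list with elements `prior`, `loglikTrace`, `nIters`, `converged`.
#' @export
runEM <- function(data, start, maxIters = 2000L, relTol = 5e-5,
                  updatePi = TRUE, updateMasses = TRUE,
                  monitor = c("pi", "loglik")) {
  .checkSumstats(data)
  stopifnot(is(start, "MixturePrior"), maxIters >= 1L)
  cache <- .kernelCache(data, start@grid)
  res <- .runEMCache(cache, start@pi, start@masses, maxIters, relTol,
                     updatePi, updateMasses, match.arg(monitor))
  list(prior = mixturePrior(res$pi, res$masses, start@grid),
       loglikTrace = res$loglikTrace, nIters = res$nIters,
       converged = res$converged)
}

#' Fit the semi-parametric hierarchical mixture model
#'
#' Estimates the proportion of disease-associated SNPs \eqn{\hat\pi} and the
#' nonparametric effect-size distribution \eqn{\hat g} from LD-pruned GWAS
#' summary statistics by the three-stage EM schedule (see [fitConfig()]).
#' Deterministic: identical data and configuration give identical results.
#'
#' @inheritParams marginalLogLik
#' @param config a [fitConfig()] list.
#' @return an [SphmmFit-class].
#' @examples
#' sim <- simulateSumstats(m = 500, piTrue = 0.2, nCase = 5e4,
#'                         nControl = 5e4, seed = 1)
#' fit <- sphmmFit(sim$sumstats,
#'                 config = fitConfig(stage1Iters = 20, finalMaxIters = 50))
#' priorPi(fit)
#' @export
sphmmFit <- function(data, config = fitConfig()) {
  .checkSumstats(data)
  if (nrow(data) < 100L)
    warning("fewer than 100 SNPs; estimates of (pi, g) may be unstable")
  grid <- effectGrid(config$gridLo, config$gridHi, config$gridStep)
  B <- length(grid)
  cache <- .kernelCache(data, grid)
  unif <- rep(1 / B, B)

  # Stage 1: candidate-pi sweep, both parameters free, fixed iteration count
  sweep <- lapply(config$candidatePis, function(p0)
    .runEMCache(cache, p0, unif, config$stage1Iters, relTol = 0))
  stage1 <- data.frame(
    pi_start = config$candidatePis,
    pi_after = vapply(sweep, `[[`, numeric(1), "pi"),
    loglik = vapply(sweep, function(s) tail(s$loglikTrace, 1L), numeric(1)))
  best <- which.max(stage1$loglik)  # ties resolve to the smaller candidate
  piInit <- stage1$pi_after[best]

  # Stage 2: g warm-up from uniform at frozen pi; likelihood-based stopping
  warm <- .runEMCache(cache, piInit, unif, config$stage2MaxIters,
                      config$stage2RelTol, updatePi = FALSE,
                      monitor = "loglik")
  gInit <- warm$masses

  # Stage 3: full EM from (piInit, gInit)
  fin <- .runEMCache(cache, piInit, gInit, config$finalMaxIters,
                     config$finalRelTol, monitor = "pi")

  new("SphmmFit",
      prior = mixturePrior(fin$pi, fin$masses, grid),
      loglikTrace = fin$loglikTrace, nIters = fin$nIters,
      converged = fin$converged, stage1Table = stage1,
      piInit = piInit, gInit = gInit, config = config)
}

#' Serialize a fit to JSON
#'
#' Writes `{pi, grid, masses, loglik_trace, n_iters, converged,
#' stage1_table}` (plus `bootstrap` when supplied) as a JSON file.
#'
#' @param fit an [SphmmFit-class].
#' @param path output file path.
#' @param bootstrap optional [SphmmBootstrap-class] appended under
#'   `"bootstrap"`.
#' @return `path`, invisibly.
#' @export
writeFitJson <- function(fit, path, bootstrap = NULL) {
  out <- list(pi = fit@prior@pi, grid = gridPoints(fit@prior@grid),
              masses = fit@prior@masses, loglik_trace = fit@loglikTrace,
              n_iters = fit@nIters, converged = fit@converged,
              stage1_table = fit@stage1Table,
              pi_init = fit@piInit, g_init = fit@gInit)
  if (!is.null(bootstrap))
    out$bootstrap <- list(n_boot = bootstrap@nBoot, pis = bootstrap@pis,
                          Vs = bootstrap@Vs, se_pi = bootstrap@sePi,
                          se_V = bootstrap@seV, seed = bootstrap@seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
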