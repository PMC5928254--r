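# Synthetic GWAS summary statistics with the statistical structure the
# mixture model assumes: a fraction piTrue of SNPs carry a true log-odds
# ratio drawn from an effect distribution, the rest are null, and each SNP
# is observed with case-control sampling noise. Two noise mechanisms are
# provided: "asymptotic" draws y ~ N(beta, v) with the Wald allele-count
# variance implied by the sample sizes, and "genotype" actually samples
# allele counts and computes the 2x2-table Wald estimator, serving as the
# ground-truth check of the asymptotic shortcut.

#' Effect-size distribution specifications
#'
#' Helpers describing the distribution of true non-null effects for
#' [simulateSumstats()]: a centered normal with standard deviation `sd`
#' (the validation-study default, sd = 0.03), discrete point masses, or a
#' uniform on `[lo, hi]`.
#'
#' @param sd,values,weights,lo,hi distribution parameters.
#' @return a specification list with a `kind` field.
#' @export
effectNormal <- function(sd = 0.03) {
  stopifnot(sd > 0)
  list(kind = "normal", sd = sd)
}

#' @rdname effectNormal
#' @export
effectPointMass <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  list(kind = "point_masses", values = values,
       weights = weights / sum(weights))
}

#' @rdname effectNormal
#' @export
effectUniform <- function(lo, hi) {
  stopifnot(lo < hi)
  list(kind = "uniform", lo = lo, hi = hi)
}

.drawEffects <- function(spec, n) {
  switch(spec$kind,
         normal = rnorm(n, 0, spec$sd),
         point_masses = sample(spec$values, n, replace = TRUE,
                               prob = spec$weights),
         uniform = runif(n, spec$lo, spec$hi),
         stop("unknown effect distribution kind: ", spec$kind))
}

# Case-side derived allele frequency induced by a per-allele log-odds ratio
# beta at population frequency p (allele-level logistic shift).
.caseFreq <- function(p, beta) p * exp(beta) / (1 - p + p * exp(beta))

#' Simulate a GWAS summary-statistics dataset
#'
#' Per SNP: a derived allele frequency is drawn from `freqRange`, the SNP is
#' non-null with probability `piTrue`, and its true log-odds ratio
#' \eqn{\beta_j} is drawn from `effect` (0 if null). In `"asymptotic"` mode
#' the sampling variance is the allele-count Wald form \eqn{v_j = 1/(2
#' n_{case} \tilde p \tilde q) + 1/(2 n_{control} p q)} with the case-side
#' frequency \eqn{\tilde p = p e^\beta / (1 - p + p e^\beta)}, and \eqn{y_j
#' \sim N(\beta_j, v_j)}. In `"genotype"` mode derived-allele counts are
#' drawn from binomials in cases and controls and the log-odds ratio and
#' its \eqn{1/a + 1/b + 1/c + 1/d} variance are computed from the 2x2
#' allele table (0.5 added to every cell when any count is zero; a SNP
#' whose table is still degenerate is redrawn, up to a bounded number of
#' retries).
#'
#' @param m number of SNPs.
#' @param piTrue true proportion of non-null SNPs, in \[0, 1\].
#' @param effect effect-size specification ([effectNormal()] and friends).
#' @param nCase,nControl numbers of cases and controls.
#' @param freqRange range of the uniform derived-allele-frequency
#'   distribution (common-variant default 0.05--0.95).
#' @param mode `"asymptotic"` or `"genotype"` (see above).
#' @param seed integer seed; every draw is derived from it.
#' @return list of class `"sphmmSim"`: `sumstats` (data.frame ready for
#'   [sphmmFit()]), `truth` (data.frame `snp_id`, `is_nonnull`,
#'   `beta_true`), `config` echo.
#' @examples
#' sim <- simulateSumstats(m = 1000, piTrue = 0.1, seed = 7)
#' mean(sim$truth$is_nonnull)
#' @export
simulateSumstats <- function(m, piTrue = 0.1, effect = effectNormal(0.03),
                             nCase = 1e5, nControl = 1e5,
                             freqRange = c(0.05, 0.95),
                             mode = c("asymptotic", "genotype"),
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(m >= 1, piTrue >= 0, piTrue <= 1, nCase >= 1, nControl >= 1,
            length(freqRange) == 2L, freqRange[1] > 0, freqRange[2] < 1,
            freqRange[1] < freqRange[2])
  if (!is.null(seed)) set.seed(seed)
  p <- runif(m, freqRange[1], freqRange[2])
  nonnull <- runif(m) < piTrue
  beta <- numeric(m)
  beta[nonnull] <- .drawEffects(effect, sum(nonnull))
  pt <- .caseFreq(p, beta)
  if (mode == "asymptotic") {
    v <- 1 / (2 * nCase * pt * (1 - pt)) + 1 / (2 * nControl * p * (1 - p))
    y <- rnorm(m, beta, sqrt(v))
  } else {
    y <- v <- numeric(m)
    for (j in seq_len(m)) {
      ok <- FALSE
      for (try in 1:100) {
        a <- rbinom(1L, 2L * nCase, pt[j])
        c_ <- rbinom(1L, 2L * nControl, p[j])
        b <- 2 * nCase - a; d <- 2 * nControl - c_
        if (any(c(a, b, c_, d) == 0)) {
          a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
        }
        yj <- log(a * d / (b * c_))
        vj <- 1 / a + 1 / b + 1 / c_ + 1 / d
        if (is.finite(yj) && is.finite(vj) && vj > 0) { ok <- TRUE; break }
      }
      if (!ok) stop("could not simulate a nondegenerate table for SNP ", j)
      y[j] <- yj; v[j] <- vj
    }
  }
  ids <- sprintf("snp%0*d", nchar(m), seq_len(m))
  out <- list(
    sumstats = data.frame(snp_id = ids, y = y, v = v, daf = p,
                          stringsAsFactors = FALSE),
    truth = data.frame(snp_id = ids, is_nonnull = nonnull,
                       beta_true = beta, stringsAsFactors = FALSE),
    config = list(m = m, piTrue = piTrue, effect = effect, nCase = nCase,
                  nControl = nControl, freqRange = freqRange, mode = mode,
                  seed = seed))
  class(out) <- "sphmmSim"
  out
}

#' @export
print.sphmmSim <- function(x, ...) {
  cat(sprintf(
    "Simulated GWAS summary statistics: %d SNPs (%d non-null), %s mode\n",
    x$config$m, sum(x$truth$is_nonnull), x$config$mode))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Standard summary-statistics TSV (see [writeSumstats()]) plus a truth TSV
#' (`snp_id`, `is_nonnull`, `beta_true`) for evaluation.
#'
#' @param sim a [simulateSumstats()] result.
#' @param sumstatsPath,truthPath output paths (`NULL` skips either file).
#' @return `sim`, invisibly.
#' @export
writeSimulation <- function(sim, sumstatsPath = NULL, truthPath = NULL) {
  if (!is.null(sumstatsPath)) writeSumstats(sim$sumstats, sumstatsPath)
  if (!is.null(truthPath))
    utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(sim)
}

#' Validation experiment: recover pi and g across sample sizes
#'
#' Reruns the validation design — true \eqn{\pi} = `piTrue`, effects
#' \eqn{N(0, sd^2)} — over a grid of sample sizes with several seeded
#' replicates each, fitting the full three-stage EM every time.
#'
#' @param nValues vector of case (= control) sample sizes.
#' @param m SNPs per replicate.
#' @param reps replicates per sample size.
#' @param seed master seed; replicate seeds are derived from it.
#' @param piTrue,effectSd generator truth.
#' @param config fit configuration (see [fitConfig()]).
#' @return list with `table` (data.frame `n`, `rep`, `seed`, `pi_hat`),
#'   `summary` (per-n mean and SD of \eqn{\hat\pi}), and `gbar` (matrix of
#'   per-n averaged fitted mass curves, grid points as rownames).
#' @export
validationExperiment <- function(nValues, m = 20000L, reps = 10L,
                                 seed = 1L, piTrue = 0.1, effectSd = 0.03,
                                 config = fitConfig()) {
  set.seed(seed)
  repSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                length(nValues) * reps),
                     nrow = length(nValues))
  rows <- list()
  grid <- effectGrid(config$gridLo, config$gridHi, config$gridStep)
  gbar <- matrix(0, length(grid), length(nValues),
                 dimnames = list(format(gridPoints(grid)), nValues))
  for (i in seq_along(nValues)) {
    n <- nValues[i]
    for (r in seq_len(reps)) {
      sim <- simulateSumstats(m, piTrue, effectNormal(effectSd),
                              nCase = n, nControl = n,
                              seed = repSeeds[i, r])
      fit <- sphmmFit(sim$sumstats, config)
      rows[[length(rows) + 1L]] <-
        data.frame(n = n, rep = r, seed = repSeeds[i, r],
                   pi_hat = priorPi(fit))
      gbar[, i] <- gbar[, i] + priorMasses(fit) / reps
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$n), function(d)
    data.frame(n = d$n[1], mean_pi_hat = mean(d$pi_hat),
               sd_pi_hat = sd(d$pi_hat))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ[order(summ$n), ], gbar = gbar)
}
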