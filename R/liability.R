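# Liability threshold model: convert per-allele log-odds ratios into
# liability-scale explained variance. Disease liability is latent standard
# normal; individuals above threshold T are affected. Genotypes shift the
# mean liability but share residual variance 1; anchoring T = qnorm(1 - K)
# fixes the arbitrary location (the variance is invariant to this choice).

#' Hardy-Weinberg genotype frequencies
#'
#' @param p derived allele frequency, strictly in (0, 1); vectorized.
#' @return matrix with columns `h0`, `h1`, `h2` = \eqn{(1-p)^2, 2p(1-p),
#'   p^2} (a named vector for scalar `p`).
#' @examples
#' genotypeFrequencies(0.5)  # 0.25 0.50 0.25
#' @export
genotypeFrequencies <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("allele frequency must lie strictly inside (0, 1)")
  out <- cbind(h0 = (1 - p)^2, h1 = 2 * p * (1 - p), h2 = p^2)
  if (length(p) == 1L) out[1L, ] else out
}

# Internal vectorized prevalence-constraint solver. Finds alpha with
#   sum_x h_x / (1 + exp(-alpha - beta x)) = K
# by damped Newton (the constraint is smooth and strictly increasing in
# alpha), with a bisection fallback for any element that fails to reach the
# residual tolerance.
.solveAlphaVec <- function(beta, p, K, tol = 1e-12) {
  n <- max(length(beta), length(p), length(K))
  beta <- rep_len(beta, n); p <- rep_len(p, n); K <- rep_len(K, n)
  h0 <- (1 - p)^2; h1 <- 2 * p * (1 - p); h2 <- p^2
  f <- function(a) h0 * plogis(a) + h1 * plogis(a + beta) +
    h2 * plogis(a + 2 * beta) - K
  alpha <- qlogis(K) - beta * 2 * p  # start near the small-beta solution
  for (i in 1:100) {
    phi0 <- plogis(alpha); phi1 <- plogis(alpha + beta)
    phi2 <- plogis(alpha + 2 * beta)
    res <- h0 * phi0 + h1 * phi1 + h2 * phi2 - K
    if (all(abs(res) < tol)) break
    grad <- h0 * phi0 * (1 - phi0) + h1 * phi1 * (1 - phi1) +
      h2 * phi2 * (1 - phi2)
    step <- res / pmax(grad, 1e-300)
    alpha <- alpha - pmin(pmax(step, -10), 10)
  }
  res <- f(alpha)
  bad <- which(abs(res) >= 1e-10)
  for (j in bad) {
    r <- stats::uniroot(function(a) f(a)[j],
                        lower = alpha[j] - 50, upper = alpha[j] + 50,
                        tol = tol, extendInt = "upX", check.conv = TRUE)
    alpha[j] <- r$root
  }
  if (any(abs(f(alpha)) >= 1e-10))
    stop("prevalence constraint could not be solved to tolerance")
  alpha
}

#' Solve the baseline penetrance parameter under the prevalence constraint
#'
#' Given the additive logistic penetrance \eqn{\phi_x = 1/(1 +
#' e^{-\alpha - \beta x})} over genotype dosage \eqn{x = 0, 1, 2}, returns
#' the \eqn{\alpha} at which the population prevalence \eqn{K = \sum_x h_x
#' \phi_x} holds (Hardy-Weinberg \eqn{h_x}). The constraint is strictly
#' increasing in \eqn{\alpha}, so the solution is unique; the residual is
#' guaranteed below 1e-10.
#'
#' @param beta per-allele log-odds ratio(s).
#' @param p derived allele frequency in (0, 1).
#' @param K disease prevalence in (0, 1).
#' @return \eqn{\alpha} value(s); for `beta = 0` this is exactly
#'   `qlogis(K)`.
#' @examples
#' solveAlpha(0, 0.3, 0.01)    # log(0.01/0.99)
#' solveAlpha(0.1, 0.3, 0.01)
#' @export
solveAlpha <- function(beta, p, K) {
  if (any(!is.finite(K) | K <= 0 | K >= 1))
    stop("prevalence K must lie strictly inside (0, 1)")
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stop("allele frequency must lie strictly inside (0, 1)")
  n <- max(length(beta), length(p), length(K))
  beta <- rep_len(beta, n); p <- rep_len(p, n); K <- rep_len(K, n)
  out <- .solveAlphaVec(beta, p, K)
  out[beta == 0] <- qlogis(K[beta == 0])  # exact closed form at beta = 0
  out
}

#' Liability-scale variance explained by one SNP effect
#'
#' Converts a log-odds ratio \eqn{\beta} with derived allele frequency `p`
#' and disease prevalence `K` to the variance explained on the
#' unit-variance liability scale. Genotype penetrances come from
#' [solveAlpha()]; genotype mean liabilities satisfy \eqn{\Phi^{-1}(1 -
#' \phi_x) = T - \mu_x} with \eqn{T = \Phi^{-1}(1-K)}; the raw
#' between-genotype variance \eqn{v^* = \sum_x h_x (\mu_x - \mu_{all})^2}
#' is normalized to \eqn{v = v^*/(1 + v^*)}, the variance under the
#' standard liability threshold model with unit total variance.
#'
#' @inheritParams solveAlpha
#' @return variance value(s) in \[0, 1); exactly 0 when `beta = 0`.
#' @examples
#' liabilityVariance(0.05, 0.5, 0.01)
#' liabilityVariance(0, 0.3, 0.05)  # 0
#' @export
liabilityVariance <- function(beta, p, K) {
  n <- max(length(beta), length(p), length(K))
  beta <- rep_len(beta, n); p <- rep_len(p, n); K <- rep_len(K, n)
  alpha <- solveAlpha(beta, p, K)
  h0 <- (1 - p)^2; h1 <- 2 * p * (1 - p); h2 <- p^2
  Tthr <- qnorm(1 - K)
  # mu_x = T - qnorm(1 - phi_x) = T + qnorm(phi_x)
  mu0 <- Tthr + qnorm(plogis(alpha))
  mu1 <- Tthr + qnorm(plogis(alpha + beta))
  mu2 <- Tthr + qnorm(plogis(alpha + 2 * beta))
  muAll <- h0 * mu0 + h1 * mu1 + h2 * mu2
  vStar <- h0 * (mu0 - muAll)^2 + h1 * (mu1 - muAll)^2 +
    h2 * (mu2 - muAll)^2
  vStar / (1 + vStar)
}

#' Per-SNP liability variance under a fitted prior
#'
#' The point estimate \eqn{\hat v_j = \hat\pi \sum_b \hat p_b\,
#' v(b, p_j, K)}: the non-null probability times the mean explained
#' variance over the fitted effect-size distribution, at the SNP's own
#' derived allele frequency.
#'
#' @param prior a [MixturePrior-class] or [SphmmFit-class].
#' @param p derived allele frequency (scalar or vector, one per SNP).
#' @param K disease prevalence.
#' @return \eqn{\hat v_j} value(s).
#' @export
snpLiabilityVariance <- function(prior, p, K) {
  if (is(prior, "SphmmFit")) prior <- prior@prior
  stopifnot(is(prior, "MixturePrior"))
  if (prior@pi == 0) return(rep(0, length(p)))
  b <- gridPoints(prior@grid)
  B <- length(b)
  # v(b, p_j, K) for all grid x SNP pairs in one vectorized solve
  vb <- liabilityVariance(rep(b, times = length(p)),
                          rep(p, each = B), K)
  vb <- matrix(vb, nrow = B)
  prior@pi * as.numeric(crossprod(vb, prior@masses) / sum(prior@masses))
}

#' Total liability-scale variance explained by a SNP set
#'
#' Sums \eqn{\hat v_j} over all SNPs with an available derived allele
#' frequency; SNPs lacking one are skipped with a warning and counted.
#' This is the SNP-heritability estimate \eqn{\hat V} for the (pruned) set.
#'
#' @inheritParams marginalLogLik
#' @param prior a [MixturePrior-class] or [SphmmFit-class].
#' @param K disease prevalence in (0, 1).
#' @return an object of class `"sphmmVarianceReport"`: list with `perSnp`
#'   (data.frame `snp_id`, `daf`, `v_hat`), `Vhat`, `nUsed`, `nSkipped`,
#'   `K`.
#' @export
totalLiabilityVariance <- function(data, prior, K) {
  .checkSumstats(data, requireDaf = TRUE)
  if (is(prior, "SphmmFit")) prior <- prior@prior
  ok <- !is.na(data$daf)
  nSkip <- sum(!ok)
  if (nSkip > 0)
    warning(nSkip, " SNP(s) lack a derived allele frequency; skipped")
  if (!any(ok)) stop("no SNP has a derived allele frequency")
  vhat <- snpLiabilityVariance(prior, data$daf[ok], K)
  rep <- list(perSnp = data.frame(snp_id = data$snp_id[ok],
                                  daf = data$daf[ok], v_hat = vhat,
                                  stringsAsFactors = FALSE),
              Vhat = sum(vhat), nUsed = sum(ok), nSkipped = nSkip, K = K)
  class(rep) <- "sphmmVarianceReport"
  rep
}

#' @export
print.sphmmVarianceReport <- function(x, ...) {
  cat(sprintf("Liability-scale variance report (K = %g)\n", x$K))
  cat(sprintf("  V-hat = %.4f over %d SNPs (%d skipped)\n",
              x$Vhat, x$nUsed, x$nSkipped))
  invisible(x)
}

#' Write a variance report to disk
#'
#' Per-SNP table as TSV plus totals as JSON
#' (`{V_hat, n_used, n_skipped, K}`).
#'
#' @param report a [totalLiabilityVariance()] result.
#' @param tsvPath,jsonPath output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
writeVarianceReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath))
    utils::write.table(report$perSnp, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(V_hat = report$Vhat, n_used = report$nUsed,
                              n_skipped = report$nSkipped, K = report$K),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Fraction of family-based heritability explained
#'
#' Reporting arithmetic: `(V + mhcShare) / h2Family`, e.g. the share of a
#' 55\% family heritability recovered once the variance of an excluded MHC
#' region is added back to the SNP-set estimate.
#'
#' @param V liability-scale variance explained by the SNP set.
#' @param mhcShare variance attributed to regions excluded from the set
#'   (default 0).
#' @param h2Family family-based heritability (> 0).
#' @return the fraction (e.g. 0.473 for 47.3\%).
#' @examples
#' familyHeritabilityFraction(0.14, 0.12, 0.55)  # 0.4727...
#' @export
familyHeritabilityFraction <- function(V, mhcShare = 0, h2Family) {
  stopifnot(h2Family > 0, V >= 0, mhcShare >= 0)
  (V + mhcShare) / h2Family
}

#' Fold enrichment of per-SNP explained variance between two SNP sets
#'
#' @param reportNum,reportDenom [totalLiabilityVariance()] reports for the
#'   numerator (e.g. eQTL) and denominator (e.g. non-eQTL) sets.
#' @return ratio of mean per-SNP \eqn{\hat v_j}.
#' @export
foldEnrichment <- function(reportNum, reportDenom) {
  (reportNum$Vhat / reportNum$nUsed) /
    (reportDenom$Vhat / reportDenom$nUsed)
}
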