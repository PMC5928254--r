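# Per-SNP empirical Bayes posterior summaries under a fitted prior.
# The posterior mean is the winner's-curse-adjusted effect size: selection
# bias is absorbed by shrinkage toward the fitted architecture (pi, g).

#' Posterior summaries for each SNP
#'
#' Under the fitted prior \eqn{(\hat\pi, \hat g)}, computes for every SNP
#' the posterior probability of being non-null, \eqn{1 - r_{0j}}, and the
#' posterior mean effect size \eqn{\sum_b b\, r_{jb}} (the null component
#' contributes 0 to the mean).
#'
#' @inheritParams marginalLogLik
#' @param prior a [MixturePrior-class] or [SphmmFit-class].
#' @param returnMasses if `TRUE`, attach the m x B matrix of normalized
#'   non-null posterior masses as attribute `"post_masses"`.
#' @return data.frame with columns `snp_id`, `y`, `v`, `p_nonnull`,
#'   `post_mean`, `post_mean_OR` (`= exp(post_mean)`).
#' @examples
#' ss <- sumstats(c("a", "b"), beta = c(0.2, 0.0), se = c(0.02, 0.02))
#' posteriorSummary(ss, uniformPrior(0.5))
#' @export
posteriorSummary <- function(data, prior, returnMasses = FALSE) {
  .checkSumstats(data)
  if (is(prior, "SphmmFit")) prior <- prior@prior
  stopifnot(is(prior, "MixturePrior"))
  resp <- eStep(data, prior)
  b <- gridPoints(prior@grid)
  pNonnull <- pmin(pmax(1 - resp$r0, 0), 1)
  postMean <- as.numeric(resp$r %*% b)
  out <- data.frame(snp_id = data$snp_id, y = data$y, v = data$v,
                    p_nonnull = pNonnull, post_mean = postMean,
                    post_mean_OR = exp(postMean),
                    stringsAsFactors = FALSE)
  if (returnMasses) {
    tot <- rowSums(resp$r)
    pm <- resp$r / ifelse(tot > 0, tot, 1)
    attr(out, "post_masses") <- pm
  }
  out
}

#' Rank SNPs by posterior mean effect size
#'
#' Returns the SNPs whose posterior mean log-odds ratio exceeds a threshold
#' in absolute value, sorted by `|post_mean|` descending (ties broken by
#' `snp_id` for determinism). This is the empirical Bayes top list:
#' posterior means are shrunken toward the fitted architecture, so ranking
#' on them counteracts the winner's curse.
#'
#' @inheritParams posteriorSummary
#' @param thresholdAbsBeta keep SNPs with `|post_mean|` strictly above this
#'   value (log-odds-ratio scale; 0.05 is about a 5\% odds change).
#' @return data.frame as in [posteriorSummary()], filtered and ordered.
#' @export
rankSnps <- function(data, prior, thresholdAbsBeta = 0.05) {
  ps <- posteriorSummary(data, prior)
  keep <- ps[abs(ps$post_mean) > thresholdAbsBeta, , drop = FALSE]
  keep <- keep[order(-abs(keep$post_mean), keep$snp_id), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Write the posterior table as TSV
#'
#' @param posterior output of [posteriorSummary()] or [rankSnps()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePosteriorTsv <- function(posterior, path) {
  utils::write.table(posterior, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
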