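# Parametric bootstrap for the fitted mixture model: datasets are redrawn
# from the estimated (pi-hat, g-hat) with the observed per-SNP sampling
# variances, and each replicate is refit with the full three-stage
# schedule, so the reported SEs include initialization variability.

#' Parametric bootstrap standard errors
#'
#' For each of `nBoot` replicates and each SNP \eqn{j}: with probability
#' \eqn{\hat\pi} draw \eqn{\beta_j} from \eqn{\hat g} (discrete over the
#' grid), otherwise set \eqn{\beta_j = 0}; draw \eqn{y_j^* \sim N(\beta_j,
#' v_j)} reusing the observed variance; refit with [sphmmFit()]. The
#' standard error of \eqn{\hat\pi} is the sample SD of the replicate
#' \eqn{\hat\pi^*}; when `prevalence` is supplied and the data carry
#' frequencies, replicate \eqn{\hat V^*} and its SE are computed the same
#' way with the observed frequencies held fixed.
#'
#' Each replicate runs on its own seed derived from `seed`, so results do
#' not depend on execution order.
#'
#' @inheritParams sphmmFit
#' @param fitted an [SphmmFit-class] from the same data.
#' @param nBoot number of replicates (>= 2); 100 is the conventional
#'   choice.
#' @param seed master integer seed.
#' @param prevalence optional disease prevalence enabling bootstrap SEs for
#'   the liability-scale variance total.
#' @return an [SphmmBootstrap-class].
#' @export
parametricBootstrap <- function(data, fitted, nBoot = 100L, seed = 1L,
                                prevalence = NULL,
                                config = fitted@config) {
  .checkSumstats(data)
  stopifnot(is(fitted, "SphmmFit"))
  if (nBoot < 2L) stop("nBoot must be at least 2")
  prior <- fitted@prior
  b <- gridPoints(prior@grid)
  m <- nrow(data)
  doV <- !is.null(prevalence) && !is.null(data$daf) && any(!is.na(data$daf))
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nBoot)
  pis <- numeric(nBoot)
  Vs <- if (doV) numeric(nBoot) else numeric(0)
  for (r in seq_len(nBoot)) {
    set.seed(repSeeds[r])
    nonnull <- runif(m) < prior@pi
    beta <- numeric(m)
    if (any(nonnull))
      beta[nonnull] <- sample(b, sum(nonnull), replace = TRUE,
                              prob = prior@masses)
    ystar <- rnorm(m, beta, sqrt(data$v))
    dstar <- data
    dstar$y <- ystar
    refit <- sphmmFit(dstar, config)
    pis[r] <- priorPi(refit)
    if (doV)
      Vs[r] <- totalLiabilityVariance(dstar, refit, prevalence)$Vhat
  }
  new("SphmmBootstrap", nBoot = as.integer(nBoot), pis = pis, Vs = Vs,
      sePi = sd(pis), seV = if (doV) sd(Vs) else NA_real_,
      seed = as.integer(seed))
}
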