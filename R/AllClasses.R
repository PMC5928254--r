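#' @import methods
#' @importFrom stats dnorm pnorm qnorm rnorm rbinom runif plogis qlogis sd
#'   setNames complete.cases
NULL

#' Grid of candidate effect sizes for the nonparametric prior
#'
#' An `EffectGrid` holds the ordered, strictly increasing, nonzero support
#' points \eqn{b_1 < b_2 < \dots < b_B} (log-odds-ratio scale) on which the
#' nonparametric effect-size distribution \eqn{g} places probability mass.
#' Zero is excluded: the null component of the mixture owns it.
#'
#' @slot points numeric vector of strictly increasing nonzero grid points.
#' @seealso [effectGrid()] for the standard constructor.
#' @export
setClass("EffectGrid", representation(points = "numeric"))

setValidity("EffectGrid", function(object) {
  b <- object@points
  if (length(b) < 2L) return("grid needs at least 2 points")
  if (anyNA(b) || any(!is.finite(b))) return("grid points must be finite")
  if (any(b == 0)) return("0 is not an admissible grid point")
  if (any(diff(b) <= 0)) return("grid points must be strictly increasing")
  TRUE
})

#' Construct an effect-size grid
#'
#' Builds the default equally spaced grid on the log-odds-ratio scale,
#' dropping zero. The defaults `(-0.3, 0.3, 0.005)` give the standard
#' 120-point support \eqn{(-0.300, -0.295, \dots, -0.005, 0.005, \dots,
#' 0.300)}, wide enough (odds ratios 0.74--1.35) for the effect-size
#' distributions seen in most complex diseases.
#'
#' @param lo,hi grid range (inclusive), log-odds-ratio scale.
#' @param step spacing between adjacent points.
#' @param points optional explicit vector of nonzero points; overrides
#'   `lo`/`hi`/`step`.
#' @return an [EffectGrid-class] object.
#' @examples
#' g <- effectGrid()
#' length(gridPoints(g))  # 120
#' @export
effectGrid <- function(lo = -0.3, hi = 0.3, step = 0.005, points = NULL) {
  if (is.null(points)) {
    stopifnot(is.numeric(lo), is.numeric(hi), lo < hi, step > 0)
    points <- seq(lo, hi, by = step)
    # drop zero (incl. -1e-17 style accumulated-rounding zeros)
    points <- points[abs(points) > step * 1e-8]
    points <- round(points, 12)
  }
  new("EffectGrid", points = as.numeric(points))
}

#' @describeIn effectGrid extract the numeric support points.
#' @param x an `EffectGrid` (or an object carrying one).
#' @export
gridPoints <- function(x) {
  if (is(x, "MixturePrior")) x <- x@grid
  x@points
}

#' @export
setMethod("length", "EffectGrid", function(x) length(x@points))

setMethod("show", "EffectGrid", function(object) {
  b <- object@points
  cat(sprintf("EffectGrid with %d nonzero points in [%.4g, %.4g]\n",
              length(b), min(b), max(b)))
})

#' Two-group mixture prior over SNP effect sizes
#'
#' A `MixturePrior` couples the non-null probability \eqn{\pi} with the
#' nonparametric effect-size distribution \eqn{g}, represented as probability
#' masses \eqn{p_1,\dots,p_B} on the points of an [EffectGrid-class]. A SNP
#' is disease-associated with prior probability \eqn{\pi}; if so its true
#' log-odds ratio is drawn from \eqn{g}.
#'
#' @slot pi numeric(1) in \[0, 1\], prior probability of being non-null.
#' @slot masses nonnegative numeric vector summing to 1, aligned with `grid`.
#' @slot grid the [EffectGrid-class] supporting the masses.
#' @seealso [mixturePrior()], [uniformPrior()]
#' @export
setClass("MixturePrior",
         representation(pi = "numeric", masses = "numeric",
                        grid = "EffectGrid"))

setValidity("MixturePrior", function(object) {
  if (length(object@pi) != 1L || is.na(object@pi) ||
      object@pi < 0 || object@pi > 1)
    return("pi must be a single value in [0, 1]")
  p <- object@masses
  if (length(p) != length(object@grid))
    return("masses and grid have different lengths")
  if (anyNA(p) || any(p < 0)) return("masses must be nonnegative")
  if (abs(sum(p) - 1) > 1e-10) return("masses must sum to 1 (tol 1e-10)")
  TRUE
})

#' Construct a mixture prior
#'
#' @param pi prior probability a SNP is non-null, in \[0, 1\].
#' @param masses nonnegative masses over the grid points; normalized to sum
#'   to 1 if within rounding of it, otherwise must already sum to 1.
#' @param grid an [EffectGrid-class].
#' @return a [MixturePrior-class].
#' @examples
#' pr <- uniformPrior(0.5)
#' priorPi(pr)
#' @export
mixturePrior <- function(pi, masses, grid = effectGrid()) {
  if (length(masses) != length(grid))
    stop("masses (", length(masses), ") and grid (", length(grid),
         ") are misaligned")
  s <- sum(masses)
  if (s > 0 && abs(s - 1) < 1e-8) masses <- masses / s
  new("MixturePrior", pi = as.numeric(pi), masses = as.numeric(masses),
      grid = grid)
}

#' @describeIn mixturePrior uniform masses \eqn{p_b = 1/B} on the grid.
#' @export
uniformPrior <- function(pi, grid = effectGrid()) {
  B <- length(grid)
  mixturePrior(pi, rep(1 / B, B), grid)
}

#' @describeIn mixturePrior the non-null probability \eqn{\pi}.
#' @param object a `MixturePrior` or [SphmmFit-class].
#' @export
priorPi <- function(object) {
  if (is(object, "SphmmFit")) object <- object@prior
  object@pi
}

#' @describeIn mixturePrior the probability masses of \eqn{g}.
#' @export
priorMasses <- function(object) {
  if (is(object, "SphmmFit")) object <- object@prior
  object@masses
}

setMethod("show", "MixturePrior", function(object) {
  b <- gridPoints(object@grid)
  mu <- sum(object@masses * b)
  cat(sprintf("MixturePrior: pi = %.4g; g on %d grid points, mean %.4g\n",
              object@pi, length(b), mu))
})

#' Fitted semi-parametric hierarchical mixture model
#'
#' Returned by [sphmmFit()]. Records the estimated prior
#' \eqn{(\hat\pi, \hat g)}, the final-stage log-likelihood trajectory,
#' convergence diagnostics, and the initialization produced by the
#' candidate-\eqn{\pi} sweep and the \eqn{g} warm-up stage.
#'
#' @slot prior the fitted [MixturePrior-class] \eqn{(\hat\pi, \hat p)}.
#' @slot loglikTrace marginal log-likelihood at each final-stage iterate
#'   (including the final one); non-decreasing up to numerical slack.
#' @slot nIters number of final-stage EM iterations performed.
#' @slot converged `TRUE` if the relative-change tolerance was met before the
#'   iteration cap.
#' @slot stage1Table data.frame with one row per candidate \eqn{\pi}:
#'   `pi_start`, `pi_after`, `loglik`.
#' @slot piInit,gInit initialization selected by stages 1 and 2.
#' @slot config the fit configuration used (see [fitConfig()]).
#' @export
setClass("SphmmFit",
         representation(prior = "MixturePrior", loglikTrace = "numeric",
                        nIters = "integer", converged = "logical",
                        stage1Table = "data.frame", piInit = "numeric",
                        gInit = "numeric", config = "list"))

setValidity("SphmmFit", function(object) {
  tr <- object@loglikTrace
  if (length(tr) && any(diff(tr) < -1e-8 * pmax(1, abs(tr[-length(tr)]))))
    return("log-likelihood trace decreases beyond numerical slack")
  TRUE
})

setMethod("show", "SphmmFit", function(object) {
  cat("SphmmFit (semi-parametric hierarchical mixture model)\n")
  cat(sprintf("  pi-hat: %.4f  (initialized at %.4f)\n",
              object@prior@pi, object@piInit))
  cat(sprintf("  g-hat:  %d grid points, mean effect %.4g\n",
              length(object@prior@grid),
              sum(object@prior@masses * gridPoints(object@prior@grid))))
  cat(sprintf("  final stage: %d iterations, %s; loglik %.4f\n",
              object@nIters,
              if (object@converged) "converged" else "iteration cap",
              tail(object@loglikTrace, 1L)))
})

#' @describeIn SphmmFit-class final marginal log-likelihood.
#' @param object,... fitted model (and unused extra arguments).
#' @export
setMethod("logLik", "SphmmFit", function(object, ...) {
  structure(tail(object@loglikTrace, 1L), class = "logLik",
            df = NA_integer_)
})

#' @describeIn SphmmFit-class the per-iteration log-likelihood trace.
#' @param fit a fitted model.
#' @export
loglikTrace <- function(fit) fit@loglikTrace

#' Parametric bootstrap replicates for a fitted model
#'
#' Returned by [parametricBootstrap()]. Holds the replicate estimates of
#' \eqn{\pi} (and, when prevalence and allele frequencies were available, of
#' the liability-scale variance \eqn{V}) and their standard deviations.
#'
#' @slot nBoot number of bootstrap replicates.
#' @slot pis replicate \eqn{\hat\pi^*} values.
#' @slot Vs replicate \eqn{\hat V^*} values (length 0 when not computed).
#' @slot sePi,seV sample standard deviations of the replicate estimates.
#' @slot seed master seed used to derive the per-replicate streams.
#' @export
setClass("SphmmBootstrap",
         representation(nBoot = "integer", pis = "numeric", Vs = "numeric",
                        sePi = "numeric", seV = "numeric", seed = "integer"))

setValidity("SphmmBootstrap", function(object) {
  if (length(object@pis) != object@nBoot)
    return("replicate list length does not match nBoot")
  if (object@nBoot >= 2L &&
      abs(object@sePi - sd(object@pis)) > 1e-12 * max(1, object@sePi))
    return("sePi is not the SD of the stored replicates")
  TRUE
})

setMethod("show", "SphmmBootstrap", function(object) {
  cat(sprintf("SphmmBootstrap: %d replicates (seed %d)\n",
              object@nBoot, object@seed))
  cat(sprintf("  se(pi-hat) = %.4g\n", object@sePi))
  if (length(object@Vs)) cat(sprintf("  se(V-hat)  = %.4g\n", object@seV))
})

#' @describeIn SphmmBootstrap-class bootstrap standard error of
#'   \eqn{\hat\pi}.
#' @param object a bootstrap result.
#' @export
sePi <- function(object) object@sePi

#' @describeIn SphmmBootstrap-class replicate \eqn{\hat\pi^*} values.
#' @export
bootPis <- function(object) object@pis

utils::globalVariables(".")
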