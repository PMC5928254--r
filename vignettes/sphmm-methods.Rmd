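---
title: "Estimating polygenic architecture from GWAS summary statistics"
author: "sphmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating polygenic architecture from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphmm)
```

## The model

Genome-wide association studies summarize each SNP $j$ by an estimated
log-odds ratio $y_j = \hat\beta_j$ of the derived allele and its sampling
variance $v_j$. For a panel of approximately independent (LD-pruned) SNPs,
`sphmm` models these as a two-group mixture,

$$f_j(y_j) = (1-\pi)\, f_{0j}(y_j) + \pi\, f_{1j}(y_j),$$

where $\pi$ is the prior probability that a SNP is disease-associated. The
null component uses the asymptotic normality of the estimator,
$f_{0j} = N(0, v_j)$. The non-null component is hierarchical: $y_j \mid
\beta_j \sim N(\beta_j, v_j)$ with the true effect $\beta_j$ drawn from an
*unspecified* effect-size distribution $g$. $g$ is represented
nonparametrically by probability masses $p_1,\dots,p_B$ on a fixed grid of
nonzero points; the default grid spans $[-0.3, 0.3]$ (odds ratios
0.74--1.35) in steps of 0.005, excluding zero, giving $B = 120$ points.
This "semi-parametric hierarchical mixture" keeps the convenient normal
likelihood at the SNP level while letting the data decide the shape of the
effect-size distribution — skewness between risk (positive) and protective
(negative) derived alleles included.

Everything lives on the natural-log odds-ratio scale; odds ratios appear
only in reports (`post_mean_OR = exp(post_mean)`).

## Estimation: the three-stage EM schedule

$(\pi, g)$ are estimated by maximum marginal likelihood with an EM
algorithm of the smoothing-and-roughening type: the nonparametric $g$ is
updated on its grid, and *early stopping is the smoothing device* — no
penalty is added to $g$, and iteration caps control how rough the estimate
is allowed to become. The schedule, reproduced by `sphmmFit()` with the
`fitConfig()` defaults:

1. **Candidate sweep.** With $g$ uniform, the EM (both parameters free) is
   run for 200 iterations from each candidate $\pi = 0.1, 0.2, \dots,
   0.9$; the run with the highest final log-likelihood supplies
   $\pi_{init}$ (its estimated $\pi$ after those iterations). Ties break
   toward the smaller candidate, the conservative choice for polygenicity.
2. **Warm-up of $g$.** With $g$ reset to uniform and $\pi$ frozen at
   $\pi_{init}$, only the masses are updated, stopping when the relative
   log-likelihood change drops below 0.005% or after 200 iterations. The
   monitored scalar here is a design choice: the conventional monitor is
   the relative change of $\pi$, but $\pi$ is frozen in this stage, so the
   likelihood is the only moving scalar; `fitConfig(stage2RelTol = 0)`
   recovers a pure iteration-cap rule.
3. **Final EM.** Full EM from $(\pi_{init}, g_{init})$, stopping when the
   relative change of $\pi$ in one iteration falls below 0.005% or at
   2000 iterations.

$\pi$ is updated unconstrained and clipped to $[10^{-12}, 1-10^{-12}]$ so
relative changes stay defined as it approaches a boundary. The E-step is
standard Bayes' rule over the null point and the $B$ grid points; the
M-step sets $\pi$ to the mean posterior non-null mass and the $p_b$ to
renormalized column sums of responsibilities. If all posterior mass is
null the masses are kept and $\pi$ is set to 0 with a warning.

### Numerical choices

The $m \times B$ Gaussian kernel matrix is computed once per dataset and
reused across all iterations (`eStep()`/`mStep()` are exact, uncached
views of the same arithmetic — a contract the tests enforce). Because
$v_j$ can be of order $10^{-4}$, tail densities underflow double
precision, so all rows are shifted in log space by their largest component
log-density before exponentiation; the log-likelihood adds the shifts
back, and responsibilities are invariant to them. The EM itself is
deterministic: identical data and configuration give bit-identical
results.

## Uncertainty

`parametricBootstrap()` redraws each dataset from the *fitted* model —
with probability $\hat\pi$ a SNP receives an effect drawn from $\hat g$,
else 0; then $y_j^* \sim N(\beta_j, v_j)$ with the observed $v_j$ — and
refits each replicate with the **full three-stage schedule**, not a warm
start, so the reported SEs include initialization variability. 100
replicates is the conventional count. Each replicate runs on a seed
derived from the master seed, making the result independent of execution
order. When a prevalence and allele frequencies are available, replicate
liability-scale totals $\hat V^*$ are computed with the observed
frequencies held fixed (frequencies and prevalence are treated as known,
not resampled).

## Posterior effect sizes

Under the fitted prior, `posteriorSummary()` returns each SNP's posterior
probability of association $1 - r_{0j}$ and posterior mean effect
$\sum_b b\, r_{jb}$ (the null contributes zero). These shrunken means are
inherently winner's-curse-adjusted, so `rankSnps()` simply thresholds
$|\text{post\_mean}|$ (default 0.05, about a 5% odds change) and sorts —
no separate selection-bias machinery. The threshold applies to the
posterior mean, not to a posterior tail probability, matching the
conventional "top SNPs with larger posterior means" reading.

## Liability-scale variance

To express a log-odds ratio as heritability, `liabilityVariance()` maps
$(\beta, p, K)$ — effect, derived allele frequency, disease prevalence —
to explained variance under the liability threshold model. Genotype
penetrances follow the additive logistic model $\phi_x = 1/(1 +
e^{-\alpha-\beta x})$, with $\alpha$ solved from the prevalence constraint
$K = \sum_x h_x \phi_x$ (Hardy–Weinberg $h_x$); the constraint is strictly
monotone in $\alpha$, and the solver (vectorized damped Newton with a
bisection fallback) guarantees a residual below $10^{-10}$. Genotype mean
liabilities come from $\Phi^{-1}(1-\phi_x) = T - \mu_x$; since one mean
liability is an arbitrary location, we anchor $T = \Phi^{-1}(1-K)$ — the
variance is invariant to this choice, which the test suite verifies by
comparing against an oracle anchored differently. The raw between-genotype
variance $v^* = \sum_x h_x(\mu_x - \mu_{all})^2$ is normalized to $v =
v^*/(1+v^*)$, the explained variance on the standard unit-variance
liability scale.

A SNP's point estimate is $\hat v_j = \hat\pi \sum_b \hat p_b\,
v(b, p_j, K)$, and `totalLiabilityVariance()` sums $\hat v_j$ over the
SNP set (SNPs without a frequency are skipped and counted). The prevalence
is supplied by the user from prior literature — estimating it is out of
scope. `familyHeritabilityFraction()` is plain reporting arithmetic,
$(\hat V + \text{excluded share}) / h^2_{family}$, with all three numbers
supplied by the caller.

## What the simulator emulates — and what it does not

`simulateSumstats()` generates the exact structure the model assumes: a
fraction `piTrue` of SNPs receive effects from a chosen distribution (the
validation default is $N(0, 0.03^2)$), the rest are null, and each SNP is
observed with case-control noise. Two mechanisms are provided:

* **asymptotic** (default): $v_j = 1/(2 n_{case} \tilde p \tilde q) +
  1/(2 n_{ctrl} p q)$ with the case-side frequency $\tilde p = p
  e^\beta/(1-p+pe^\beta)$ implied by the effect, and $y_j \sim N(\beta_j,
  v_j)$. This matches the large-sample behavior of a 2×2 allele-count
  Wald estimator.
* **genotype**: derived-allele counts are actually drawn from binomials in
  cases and controls and the Wald log-odds ratio and its $1/a + 1/b + 1/c
  + 1/d$ variance computed (0.5 added to all cells when any is zero).
  This is the ground-truth check of the asymptotic shortcut; the two
  modes agree in distribution at GWAS sample sizes.

Derived allele frequencies default to uniform on $(0.05, 0.95)$, a
common-variant panel; the choice is configurable. Disease prevalence does
not enter the generator — case-control sampling is conditional on status —
it matters only for the liability conversion. The simulator draws
**independent** SNPs: it does not emulate LD structure, frequency spectra
shaped by selection, stratification artifacts, or imputation noise.
Passing tests therefore certify the estimator under its own assumptions
(the validation design), not robustness to the full messiness of real
GWAS panels; LD pruning is the user's responsibility on real data, and
the pruning utilities exist for exactly that.

## Pruning and stratification

`pvaluePrune()` implements greedy clumping: repeatedly keep the remaining
SNP with the lowest *reference-GWAS* P-value and drop everything in LD
($r^2 > 0.1$ by default) with it. Using an external reference for the
P-values corrects the selection for the winner's curse in the analyzed
data; the package takes `p_ref` as given and does not manage cohort
pairing. Ties break lexicographically by SNP id, and SNPs absent from the
LD table count as unlinked. `randomPrune()` replaces the P-value order by
a seeded uniform-random order. Both return maximal independent sets of the
LD graph given their selection order, a property the tests verify with an
independent checker.

`dafBins()` assigns five equal-width, right-closed derived-allele-frequency
bins ("DAF $\le$ 0.2", ..., "DAF > 0.8"); `stratifiedFit()` fits each
stratum independently (floor of 100 SNPs, smaller strata are skipped with
a warning) and reports $\hat\pi$, the $\hat\pi \times \hat g$ curves and
mean per-SNP explained variance, whose ratio between strata is the fold
enrichment. Fitting unpruned strata is allowed (`pruned = FALSE`) but
noted, since the independence assumption is then relaxed.

## Worked example

```{r example}
sim <- simulateSumstats(m = 2000, piTrue = 0.1, effect = effectNormal(0.03),
                        nCase = 1e5, nControl = 1e5, seed = 1)
fit <- sphmmFit(sim$sumstats)
fit
report <- totalLiabilityVariance(sim$sumstats, fit, K = 0.01)
report
head(rankSnps(sim$sumstats, fit), 3)
```

```{r gplot, fig.width = 6, fig.height = 3.5}
plot(gridPoints(fit@prior), priorPi(fit) * priorMasses(fit), type = "h",
     xlab = expression(beta ~ "(log-odds ratio)"),
     ylab = expression(hat(pi) %*% hat(g)))
```

## Problem sizes and test design

The package's own validation (in `tests/` and `scripts/acceptance.R`)
runs the recovery experiment at $m = 20{,}000$ SNPs and 10 replicates —
enough for the Monte-Carlo error of the mean $\hat\pi$ to sit well inside
the $\pm 0.02$ acceptance band while keeping a full run in minutes on one
core. Oracle comparisons (exhaustive $(\pi, p_1)$ lattice search,
naive-summation likelihoods, from-scratch liability arithmetic) use small
instances where brute force is exact.

## Known limitations

* Estimates are of the *marginal* architecture of the pruned panel, not of
  underlying causal variants; with causal variants in LD, $\hat\pi \times
  m$ is a conservative count.
* No LD modeling: correlated SNPs violate the independence likelihood, so
  unpruned fits are approximations (empirically close, but approximate).
* The grid bounds truncate $|\beta| > 0.3$; diseases with larger
  per-allele effects need a wider grid (`fitConfig(gridLo=, gridHi=)`).
* $g$ has no smoothness guarantee beyond early stopping; mass can
  concentrate on few grid points in small samples.
* Bootstrap SEs inherit any bias of the point estimator; they measure
  sampling variability around the fitted model, not model misfit.
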