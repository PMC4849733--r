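---
title: "Median-based robust estimation for summary-data Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Median-based robust estimation for summary-data Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medianMR)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of an exposure $X$ on an outcome $Y$ from
observational data. A variant $G_j$ is a valid instrument if it is associated
with the exposure (IV1), independent of confounders (IV2), and affects the
outcome only through the exposure (IV3). With per-variant summary statistics
— the association of each variant with the exposure
($\hat\gamma_j$, SE $\sigma_{\gamma j}$) and with the outcome
($\hat\Gamma_j$, SE $\sigma_{Y j}$), estimated in two non-overlapping samples
— each valid variant identifies the causal effect through its ratio (Wald)
estimate $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$.

The standard combination is the inverse-variance weighted (IVW) mean,
$$\hat\beta_{IVW} = \frac{\sum_j w'_j \hat\beta_j}{\sum_j w'_j},
\qquad w'_j = \frac{\hat\gamma_j^2}{\sigma_{Yj}^2},$$
which is efficient when every variant is valid but inconsistent as soon as a
single variant has a pleiotropic (direct) effect $\alpha_j$ on the outcome:
its breakdown level is 0%. This package implements a family of median-based
estimators whose breakdown level is 50%, alongside IVW and MR-Egger
regression as comparators, so that agreement or disagreement across methods
with different assumptions can serve as a sensitivity analysis.

## The estimators

**Simple median.** The median of the ordered ratio estimates: the middle
estimate for odd $J$, the mean of the two middle estimates for even $J$.
Consistent when at least half the variants are valid, but inefficient when
per-variant precisions vary.

**Weighted median.** Standardize the weights, $w_j = w'_j / \sum_k w'_k$,
form cumulative sums $s_j = \sum_{k \le j} w_k$ over the ordered estimates,
and let $\hat\beta_j$ be the $p_j = 100\,(s_j - w_j/2)$-th percentile of an
empirical distribution, interpolating linearly between neighbouring
estimates. The weighted median is the 50th percentile of that distribution:
with $p_k \le 50 \le p_{k+1}$,
$$\hat\beta_{WM} = \hat\beta_k + (\hat\beta_{k+1} - \hat\beta_k)\,
  \frac{50 - p_k}{p_{k+1} - p_k}.$$
It is consistent when at least half the *weight* comes from valid variants.
Equal weights recover the simple median exactly.

```{r}
r <- ratio_estimates(make_fixture("fig2", seed = 3))
cdf <- build_weighted_cdf(r)
round(rbind(estimate = cdf$beta, percentile = cdf$p), 3)
weighted_median(cdf)
```

**Penalized weighted median.** Heterogeneity of the ratio estimates about
the IVW estimate is measured by Cochran's
$Q = \sum_j Q_j = \sum_j w'_j (\hat\beta_j - \hat\beta_{IVW})^2$; under
homogeneity each component $Q_j$ is approximately $\chi^2_1$. Writing $q_j$
for the one-sided upper $\chi^2_1$ P-value of $Q_j$, the penalized weights
are $w^*_j = w'_j \min(1,\, 20 q_j)$: variants with $q_j > 0.05$ are
untouched, outliers are severely down-weighted. The penalization is one-shot
— the IVW centre is not re-estimated afterwards — and feeds the same
weighted-median computation.

**MR-Egger regression.** Weighted least squares of $\hat\Gamma_j$ on
$\hat\gamma_j$ *with an intercept*, weights $\sigma_{Yj}^{-2}$, after
reorienting every variant so its exposure association is positive. The slope
is consistent even with 100% invalid variants provided pleiotropic effects
are independent of instrument strength (the InSIDE assumption); the
intercept estimates the average pleiotropic effect, and testing it against
zero is a test of directional pleiotropy. Without the intercept the slope
reduces to the IVW estimate exactly.

## Inference

IVW and MR-Egger have analytic standard errors. The medians do not, so the
package uses a parametric bootstrap: each replicate redraws
$\hat\gamma_j^* \sim N(\hat\gamma_j, \sigma_{\gamma j}^2)$ and
$\hat\Gamma_j^* \sim N(\hat\Gamma_j, \sigma_{Yj}^2)$ independently — the
two-sample sampling model — and recomputes the estimator, weights included.
The SE is the standard deviation of the replicates and the default 95% CI is
$\hat\beta \pm 1.959964\,\mathrm{SE}$, so that power and type-I error are
computed identically for every method; a percentile CI is available
(`ci_type = "percentile"`), as is perturbation of the outcome side only
(`perturb = "outcome"`), since the exact published bootstrap scheme is not
specified. Coverage of the normal-theory interval on all-valid data is
mildly conservative (about 97% in the test suite's 500-dataset experiment),
which is why the weighted median's type-I error sits below the nominal 5%
in the simulations.

## The simulation engine

`simulate_dataset()` generates individual-level data and reduces them to
summary statistics by per-variant simple regressions, exactly as a two-sample
GWAS analysis would. Per individual,
$$U = \textstyle\sum_{j\,inv} \phi_j G_j + \epsilon_U, \qquad
  X = \textstyle\sum_j \gamma_j G_j + U + \epsilon_X, \qquad
  Y = \beta X + \textstyle\sum_{j\,inv} \alpha_j G_j + U + \epsilon_Y,$$
with $G_j \sim Binomial(2, 0.3)$ and each variant invalid independently with
probability `p_invalid` (redrawn every replicate). The three scenarios are:
balanced direct pleiotropy ($\alpha_j \sim U(-a, a)$, InSIDE holds),
directional direct pleiotropy ($\alpha_j \sim U(0, a)$ — the balanced draw
folded positive, so the two scenarios are seed-comparable), and pleiotropy
via the confounder ($\phi_j \sim U(0, f)$, violating InSIDE and correlating
pleiotropy with instrument strength). Two-sample designs draw independent
cohorts for the exposure and outcome regressions; the one-sample design
reuses the same individuals, correlating the two error terms and inducing
weak-instrument bias.

### Calibrated defaults, and why

The published account of this design states the structure and the headline
operating characteristics but not the constants, so the defaults here are
*calibrated*, not transcribed, and documented as such:

* `gamma_range = c(0.03, 0.1024)` — instrument effects sized so that at
  $N = 10{,}000$, $J = 25$ the mean per-variant first-stage F statistic is
  $\approx 10.7$ (noncentrality 9.7 plus the F statistic's null offset of 1)
  and the exposure variance explained is $\approx 2.6\%$.
* `sd_outcome_error = 2.5` (with unit confounder and exposure noise) — sets
  the outcome noise so the IVW standard error at $N = 10{,}000$ is
  $\approx 0.11$, the scale of the reference grids; the outcome behaves like
  a disease-liability score rather than a second anthropometric trait.
* `pleiotropy_max = 0.2` — the joint best fit to the reference operating
  characteristics: scenario-2 IVW bias $\approx 0.12$ with clearly inflated
  rejection ($\approx 12\%$), while scenario-1 type-I error stays near 5–6%
  and the weighted median near 3–4%.
* `confounder_loading_max = 0.127` — sized analytically so scenario-3 mean F
  at `p_invalid = 0.1` is $\approx 13.5$, rising to $\approx 19$ at 0.3, a
  structural signature of the via-confounder path (invalid variants gain
  instrument strength through $U$).

### The IVW standard error inside the grid

`mr_ivw()` defaults to the fixed-effect meta-analysis SE
$\sqrt{1/\sum_j w'_j}$, with a multiplicative random-effects option
(`random_effects = TRUE`) that inflates it by the residual standard
deviation $\sqrt{Q/(J-1)}$ when that exceeds one. Inside `run_grid()` the
random-effects form is the default. The reason is structural: balanced
pleiotropy overdisperses the ratio estimates without biasing the IVW mean,
so the fixed-effect SE understates the estimator's sampling variability and
its type-I error grows mechanically with the pleiotropy magnitude — under
the fixed-effect SE no pleiotropy magnitude can simultaneously produce
near-nominal scenario-1 error and substantial scenario-2 inflation, whereas
the random-effects SE tracks the overdispersion and reproduces both
behaviours at once (its signature is an SE that stops shrinking like
$1/\sqrt{N}$ once between-variant spread dominates). Set
`ivw_random_effects = FALSE` to study the fixed-effect behaviour.

### What the generator does not emulate

Variants are unlinked (no LD), biallelic, and of equal frequency; the
outcome is continuous (a log-odds-scale disease outcome is represented only
through the noise scale, not a logistic likelihood); genetic effects on the
exposure are draws from a single uniform range rather than the long-tailed
architecture of real traits; allele harmonization errors, sample overlap,
selection of instruments within the analysis sample, and winner's-curse
effects are all absent. A green simulation test therefore establishes the
statistical behaviour of the estimators under the stated model, not their
robustness to data-engineering pathologies.

## Numerical choices

* Percentile anchors are computed from unstandardized weights as
  $100\,(S_j - w'_j/2)/S_J$ — algebraically identical to the standardized
  form but exact in floating point for equal weights, which makes
  `weighted_median()` with equal weights collapse to the closed-form simple
  median *exactly*.
* Ratio estimates are sorted ascending with `variant_id` as tie-break, so
  results are invariant to input row order.
* If the 50th percentile falls outside $[p_1, p_J]$ (possible only when a
  single variant dominates), the boundary estimate is returned; a variant
  carrying more than half the weight triggers a warning, since the 50%
  validity condition then reduces to trusting that one variant.
* The per-component P-values $q_j$ are floored at the smallest positive
  double: the $\chi^2_1$ upper tail underflows for extreme outliers, and the
  floor keeps penalized weights strictly positive (the variant's
  contribution is already negligible).
* MR-Egger inference defaults to an estimated residual variance (weighted
  RSS / $(J-2)$, not forced to 1) and normal quantiles, for comparability
  with the other methods; `ci_dist = "t"` and `dispersion = "unit"` cover
  the alternative conventions. With 25 instruments the normal-quantile
  choice leaves the Egger slope's type-I error slightly above 5%
  ($\approx 6\%$), matching its reference behaviour.
* Reproducibility: every replicate (bootstrap or simulation) draws from a
  substream seed derived deterministically from the master seed and the
  replicate counter, so results are bit-reproducible and independent of
  evaluation order; base R has no counter-based generator, so the substream
  seeds come from an LCG-style hash kept below $2^{31}$.

## Worked example

```{r}
d <- make_fixture("fig2", seed = 3, slope = 0.1)   # 6 valid, 4 invalid
fit <- mr_fit(d, n_boot = 1000, seed = 1)
summary(fit)
```

The four invalid variants pull the IVW estimate above the true slope 0.1,
while the median-based estimates stay near it; the MR-Egger intercept test
picks up the directional offset. `plot(fit)` draws the scatter of outcome
against exposure associations with the fitted slopes, and
`plot(fit, type = "funnel")` the instrument-strength funnel whose asymmetry
indicates directional pleiotropy.

## Known limitations

The weighted median's bootstrap SE is mildly conservative, so its tests are
slightly under-sized; the penalized weighted median can misbehave when many
invalid variants are mutually homogeneous (they survive penalization while
valid variants are penalized); all methods assume uncorrelated variants —
LD-aware extensions are out of scope — and none addresses selection bias or
harmonization, which are the caller's responsibility. The applied
lipid-fraction analysis requires third-party summary data that are not
redistributed with the package; the test suite documents the file layout it
expects if those data are supplied.
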