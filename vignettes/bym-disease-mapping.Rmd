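---
title: "Small-area mapping of poor fetal growth: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area mapping of poor fetal growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bymgrowth)
```

## The scientific problem

Poor fetal growth — a liveborn singleton whose birthweight falls under 80%
of the weight expected from its gestational duration, sex, maternal height
and parity (Proportion of Optimal Birth Weight, POBW, below 0.80) — varies
geographically within a city. The question this package is built around is
whether that variation is explained by area-level socioeconomic status
(SES), and how much spatially structured variation remains once SES is
accounted for. Births are aggregated to suburbs, and suburb-level case
counts are modelled with a binomial-logit regression whose linear predictor
can carry a fixed SES effect and two random effects in the style of the
Besag–York–Mollié convolution model.

## The four nested models

With $R_i$ cases among $N_i$ births in suburb $i$ and
$R_i \sim \mathrm{Binomial}(N_i, p_i)$:

1. **Null**: $\mathrm{logit}(p_i) = \beta_0$
2. **Random effects**: $\mathrm{logit}(p_i) = \beta_0 + u_i + v_i$
3. **Fixed effect**: $\mathrm{logit}(p_i) = \beta_0 + \beta_1 X_i$
4. **Full**: $\mathrm{logit}(p_i) = \beta_0 + \beta_1 X_i + u_i + v_i$

$X_i$ is the SES index standardized to mean 0, SD 1 *within the study
area* (population SD, divisor $n$; the index convention is not otherwise
pinned down, and the affine invariance of standardization makes the choice
harmless for $\beta_1$ per SD). $u$ is the spatially-correlated effect with
an intrinsic conditional autoregressive (ICAR) prior: conditionally,
$u_i \mid u_{-i} \sim N(\bar u_{\partial i}, \sigma_u^2 / n_i)$ with
$\bar u_{\partial i}$ the mean over the $n_i$ adjacent suburbs, i.e. the
joint improper density
$\propto \exp\{-\tfrac{1}{2\sigma_u^2}\sum_{i \sim j}(u_i - u_j)^2\}$.
$v_i \sim N(0, \sigma_v^2)$ is exchangeable. Priors are deliberately
diffuse: $N(0, 100^2)$ on $\beta_0, \beta_1$ and half-normal with scale
100 on both SDs (evaluated directly on $\sigma \ge 0$).

Adjacency is queen contiguity (shared boundaries *or vertices*). Where a
river severs contiguity, supplementary edges re-join bank-facing suburb
pairs whose footprint-to-footprint distance is under a threshold (1 km by
default, with lattice cells read as 1 km squares); boundary distance, not
centroid distance, is used, since the motivating rule is about suburbs
"less than 1 km apart".

## Fitting: Metropolis-within-Gibbs

The sampler (C++ via Rcpp, seeded through R's RNG so every run is
reproducible) uses single-site random-walk updates for $\beta_0$,
$\beta_1$ and each $u_i, v_i$, and log-scale random walks for
$\sigma_u, \sigma_v$. Proposal scales adapt toward a 0.44 acceptance rate
during burn-in only, so the retained chain is a fixed-kernel Markov chain.
The ICAR impropriety is handled by recentering $u$ to sum to zero per
connected component every sweep, with the removed mean absorbed into
$\beta_0$; island suburbs (no neighbours) have $u_i$ pinned at 0, matching
the degenerate conditional that the ICAR implies for them. This
transparent sampler was chosen over gradient-based or block samplers
because the models are low-dimensional per site, the binomial likelihood
is cheap, and auditability of each full conditional was judged worth more
than raw efficiency.

Desk-scale defaults are 60,000 iterations, 20,000 burn-in, thinning 10
(4,000 retained draws) — enough for stable DIC and credible intervals on
the problem sizes below; registry-scale settings ($10^6$ kept after
$10^6$ burn-in, thin 100) remain available through `mcmc_config()`.

Convergence is monitored with the Geweke diagnostic on $\beta_0$,
$\beta_1$, $\sigma_u$, $\sigma_v$ and the deviance (*which* scalars to
monitor is an open choice; these are the ones reported here). The
spectral density at zero is estimated from an AIC-selected AR fit. Any
$|z| > 3$ raises a warning carrying the diagnostics — never a silent pass.

## DIC and pD

$\bar D$ is the mean posterior deviance; the plug-in deviance is evaluated
at the posterior mean of each suburb's *linear predictor* (the
"stochastic parents" convention — pD is convention-dependent, so this is
fixed and documented); $p_D = \bar D - D(\hat\eta)$ and
$\mathrm{DIC} = \bar D + p_D$. Deviance omits the data-only binomial
coefficient, which cancels from $p_D$ and from every DIC difference. Under
this convention the null and fixed-effect models should show $p_D$ near
their free-parameter counts (1 and 2) on any data — a calibration the
acceptance suite checks — while the random-effect models show a
data-dependent effective dimension well below the nominal $2n + 3$.

## Effect summaries

* **IQOR** (interquartile odds ratio): $\exp(q_{75} - q_{25})$ of
  per-suburb posterior-mean effects on the log-odds scale. Quantiles use
  linear interpolation between order statistics (`quantile` type 7), fixed
  because at a few hundred suburbs the IQOR is sensitive to the rule. The
  SES "IQOR" uses the posterior-mean slope times each suburb's
  standardized index — the per-suburb *mean effect size* reading; the
  alternative (per-sample IQOR, then average) is deliberately not used.
* **Variance partition**: mean across retained samples of
  $\mathrm{var}(u)/(\mathrm{var}(u)+\mathrm{var}(v))$ using empirical
  cross-suburb variances of the sampled vectors. The hyperparameter ratio
  $\sigma_u^2/(\sigma_u^2+\sigma_v^2)$ is available behind
  `method = "hyper"`, but the empirical reading is the default because the
  ICAR $\sigma_u^2$ is a conditional variance and not comparable in scale
  to the marginal $\sigma_v^2$.
* **Exceedance**: per suburb, the posterior probability that $u_i + v_i >
  0$; suburbs above 0.90 are flagged. In the full model this comparison is
  automatically SES-adjusted because $\beta_1 X$ is not in the component.

## The synthetic registry

No public registry of this kind exists, so a generator provides data with
the statistical structure the analysis assumes:

* **Geography**: a rectangular lattice of unit cells standing in for
  suburb polygons (a 16 × 17 lattice gives 272 units, the scale of the
  267-suburb study area), optionally cut by a river that severs contiguity
  until supplementary edges restore crossings.
* **SES surface**: a Gaussian field with precision
  $(1-s)I + s(D - W)$ interpolating between iid noise ($s = 0$) and an
  ICAR-like field ($s \to 1$); higher smoothness $s$ raises Moran's I in
  expectation. Rescaled to an index-like raw scale (location 1000, spread
  80) and standardized downstream.
* **Counts**: $u$ drawn exactly from the constrained ICAR via the spectral
  decomposition of the graph Laplacian (zero modes excluded, so the
  sum-to-zero constraint holds by construction), $v$ iid normal, then
  binomial sampling. Suburb birth totals are Poisson around `mean_births`
  (floored at 1) — the birth-total distribution is a stand-in chosen for
  simplicity, not an inference about any registry.
* **Birth records**: eligible liveborn singletons of 33+ weeks whose POBW
  is normal around a suburb-specific centre chosen so
  $P(\mathrm{POBW} < 0.8)$ equals the suburb's generating probability,
  plus a small admixture of ineligible records. Expected birthweight is a
  simple documented function of gestation, sex, parity and maternal
  height; the SGA reference is a packaged *synthetic* sex-by-gestation
  10th-centile table. Neither reproduces published coefficients — only the
  classification mechanics matter. POBW missingness operates through a
  missing maternal height; an optional bias makes nulls more likely for
  smaller births, reproducing the direction in which missingness is
  informative (SGA more likely among null-POBW records).

Defaults emulate the study conditions: ~5% incidence
(`beta0 = qlogis(0.05)`), slope −0.22 per SD of SES, ~172 eligible births
per suburb per period, 1.5% missing POBW, and weak residual structure
(`sigma_u = sigma_v = 0.1`), consistent with a setting where SES carries
most of the between-suburb variation. What the generator does *not*
emulate: real suburb polygons and their very uneven sizes and populations,
within-suburb heterogeneity, secular trends inside a period, and any
non-SES environmental gradient. Passing tests therefore demonstrate that
the machinery recovers known structure under the model's own assumptions —
not that the model is correct for any particular registry.

## Spatial tests

Moran's I uses binary weights from the adjacency (the adjacency matrix the
models use is binary; row-standardization is available behind a flag) with
randomization inference — permutation by default, or the closed-form
randomization mean/variance normal approximation. Oden's population-
adjusted $I_{pop}$ is computed in the area-level closed form derived
exactly from its individual-level definition (every person a binary case
indicator; within-area pairs weight 1, between-area pairs the areas'
weight). A literal individual-expansion oracle (`oden_ipop_direct`) is
exported and the suite requires equality to $10^{-10}$; the finite-
population within-area terms mean exact invariance under doubling of
populations does not hold, only up to $O(1/n)$. Inference for $I_{pop}$
redistributes the observed case total multinomially with probabilities
proportional to population — a documented choice where the original
software's method is unspecified.

## Problem sizes and test design

The suites run at "desk scale", chosen once: calibration and recovery use
250 suburbs × 400 births (recovery: $\beta_1 = -0.25$, $\sigma_u = 0.3$,
$\sigma_v = 0.2$, 20 replicates, all three generating values required
inside their 95% credible intervals in at least 18); model-selection and
structural-finding checks use 144 suburbs × 300 births. The
"strong SES, weak residuals" regime for the structural check is
$\beta_1 = -0.25$ with $\sigma_u = \sigma_v = 0.1$. Breslow–Day oracle
instances use clearly homogeneous versus clearly heterogeneous strata
(common OR in {1, 1.5, 2} versus alternating 1 and 5, five strata of 300
per arm): the two tests are asymptotically equivalent, so instance
distributions concentrated near the decision boundary would measure
tie-breaking noise rather than implementation correctness.

## Degenerate inputs and tie-breaks

* Constant vectors error in `standardize_ses`, `morans_i`, `pearson_r`.
* Zero cells in a 2 × 2 table error unless the 0.5 continuity correction
  is requested; zero margins in a Breslow–Day stratum name the stratum.
* POBW and SGA thresholds are strict (`< 0.80`, `<` centile): a birth at
  exactly 80% optimal weight, or exactly at the 10th centile, is not a
  case.
* Exclusion rules apply in a fixed precedence (outside area → zero births
  → missing SES); a unit failing several rules is logged once under the
  first. The precedence is a reproducibility convention, not a claim about
  any particular registry's accounting.
* GAL files carry no edge provenance; reading marks every edge
  `contiguity`.
* Suburbs with zero expected counts in the goodness-of-fit test are
  dropped with a warning and the df reduced.

## Known limitations

The sampler is single-site and will mix slowly on very large graphs or
with very strong spatial dependence; the ICAR/iid decomposition is only
weakly identified at small counts, so $\sigma_u, \sigma_v$ intervals are
wide at desk scale (coverage, not precision, is what the recovery suite
checks). The two periods are fitted independently — there is no
spatio-temporal joint model, matching the analysis design this package
follows. Choropleth rendering is out of scope; per-suburb posterior
summaries export to GeoJSON/CSV for external mapping.
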