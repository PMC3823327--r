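---
title: "Interpolating areal disease prevalence by discrete process convolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating areal disease prevalence by discrete process convolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevconv)
```

## The estimation problem

Disease prevalence is often observed on a *source* partition of a region
(service areas of health providers) while estimates are wanted for a *target*
partition (residential neighbourhoods). The partitions are misaligned — no
nesting in either direction — so the link between them must run through
space itself: a latent relative-risk surface evaluated at the population
weighted centroids of both frameworks. `prevconv` implements a hierarchical
Bayesian model in which that surface, and a second surface carrying an
ecological covariate, are **discrete process convolutions**: kernel-weighted
sums of independent random effects placed on a sparse regular grid,

$$z(s) = \sum_{j=1}^{J} \kappa(\lVert s - u_j\rVert)\, w_j .$$

Compared with a full Gaussian-process (geostatistical) formulation, the
convolution form needs only $J$ latent effects rather than an
$(N+K)\times(N+K)$ covariance, scales comfortably to hundreds of areas, and
makes interpolation to *any* point — in particular to the centroids of both
frameworks simultaneously — a cheap linear operation.

## Model components

Three observation streams share the latent structure:

* **Prevalence counts** (source frame): $y_i \sim \mathrm{Po}(E_i\rho_i)$,
  $\log\rho_i = \beta_1 + \beta_2 x_{Li} + z_1(s_i) + e_i$, where $E_i$ is
  the expected count (population × region-wide rate) and $x_{Li}$ the
  covariate *interpolated* to the source centroid.
* **Hospitalisation counts** (target frame): $M_k \sim \mathrm{Po}(G_k\nu_k)$
  with $\log\nu_k = \gamma_1 + \gamma_2\rho_k$. The relative prevalence
  enters on its natural scale, not the log scale, so $\gamma_2$ measures the
  change in log admission risk per unit of relative prevalence. A positive
  $\gamma_2$ is a substantive expectation, not an imposed constraint.
* **Covariate observations** (target frame):
  $x_k \sim N(\eta_1 + z_2(t_k), \sigma_x^2)$. The same relation defines the
  deterministic interpolation $x_{Li} = \eta_1 + z_2(s_i)$ used in the
  prevalence regression: the covariate observation model and the latent
  covariate are two faces of one risk-factor process.

Latent target-frame prevalence counts add no information beyond $\rho_k$
itself and are therefore not sampled; they are available as a
posterior-predictive quantity if wanted.

Residuals on both frames are heteroscedastic,
$e \sim N(0, V)$, $\log V = \delta_1 + \delta_2 (E/\bar E)$. The offsets are
divided by their frame mean before entering this regression: raw expected
counts run into the hundreds, and a slope coefficient of interpretable
magnitude (order 0.1) on the raw scale would imply astronomically large
variances. With the scaling, $\delta_2$ is the log-variance change per
average-population unit. The divisor is configurable
(`residualVariance(..., offsetScale = )`).

### Kernels and processes

Three isotropic kernel families are provided, all standardised so that
$\kappa(0)=1$: normal $\exp(-d^2/2\alpha^2)$, exponential $\exp(-d/\eta)$
(more peaked and fatter-tailed: distant grid effects retain more weight), and
a Student-t power law $(1+d^2/(\nu\alpha^2))^{-(\nu+2)/2}$. Distances are
divided by the grid spacing before kernel evaluation, so the *standard*
kernels ($\alpha=\eta=1$) have scale equal to one grid interval. Kernel scale
and process variance are confounded if both are free — the variance of the
field is the product of the two — so identification follows the standard
route: the kernel is standardised and the grid-process variance is estimated.
No truncation radius is applied: every grid point contributes to every area,
which is affordable because $J$ stays in the tens.

Grid effects are either normal, $w_j \sim N(0, \sigma_w^2)$, or scaled
Student-t with 5 degrees of freedom, allowing occasional large local effects.
The four crossings of (normal | exponential kernel) × (normal | t₅ process)
are exposed as `modelVariant(1:4)`. The Student-t *kernel* has no fitted
variant; its shape parameter defaults to 5 and is configurable
(`KernelSpec("student_t", kernelDf = )`).

### Priors

Precisions (both grid processes and the covariate noise) carry
Gamma(0.001, 0.001) priors; regression coefficients carry N(0, 1000). The
phrase "scale 1 and index 0.001" in the disease-mapping literature is
ambiguous between Gamma(0.001, 0.001) and Gamma(1, 0.001); the conventional
diffuse reading Gamma(shape = 0.001, rate = 0.001) is the default and both
hyper-parameters are configurable through `PriorSpec()`. `coeffMean` accepts
either one shared mean or a length-7 vector (β₁, β₂, γ₁, γ₂, δ₁, δ₂, η₁), the
form used when informative priors centred on substantive values are needed —
for instance in the prior-predictive calibration check described below.

## Posterior computation

`runMcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler.
Blocks: each scalar coefficient; each grid effect $w_{1j}$, $w_{2j}$ singly;
the residual vectors in one vectorised sweep (given everything else the
per-area residuals are conditionally independent, so all sites propose and
accept in parallel); conjugate Gamma draws for the precisions of normal grid
processes and for $\sigma_x^{-2}$; random-walk steps on the log variance for
t processes. Proposal scales adapt during burn-in by a diminishing
Robbins–Monro recursion on the log scale (gain $t^{-0.6}$, target acceptance
0.35) and are frozen afterwards, so the retained draws come from a
fixed-kernel chain satisfying detailed balance.

Plain single-site updates mix poorly here for a structural reason: several
posterior directions are ridges. The intercept $\beta_1$ trades off against
the mean level of $w_1$ (a constant shift of all grid effects moves every
$z_1$ value by roughly the kernel row sum); $\delta$ and the process
variances track their own random effects rather than the data when those
effects are weakly identified (the classic centred-parameterisation
pathology); and $(\gamma_1,\gamma_2)$ and $(\beta_1,\beta_2)$ are nearly
collinear because the regressors ($\rho_k$ and the covariate) have nearly
constant means. Four families of extra Metropolis moves address this, each a
valid proposal on the joint posterior:

* **non-centred scale moves** — rescale the residuals (or grid effects)
  jointly with $\delta$ (or the process variance), holding the standardised
  effects fixed (interweaving);
* **level moves** — shift $\beta_1$ (or $\eta_1$) and counter-shift the
  corresponding grid-effect vector;
* **ridge moves** — slide the slope of a collinear pair while adjusting its
  intercept by the slope change times the mean regressor.

On the package's reduced fixture these moves take the structural PSRFs from
the 1.2–2.6 range down to below 1.1 at 2 chains × 5,000 iterations.

Determinism: per-chain seeds derive from the master seed by a fixed splitting
rule, every random input flows from configuration seeds, and identical
(data, spec, config, seed) reproduce draws bitwise.

Convergence is summarised by the classic multi-chain potential scale
reduction factor (`gelmanRubin()`): $\sqrt{((n-1)/n\,W + B/n)/W}$. Chains
with zero within- and between-variance (a degenerate but legal input) report
exactly 1. The pipeline's verdict uses the conventional 1.1 cutoff; the
criterion family fixes the statistic, not the threshold, so the cutoff is a
package choice.

## Model assessment and classification

Fit is reported per observation stream, not as a composite: the three
streams live on different scales and a single number would hide which data a
variant serves well. Poisson streams use the saturated deviance
$2\sum[y\log(y/\hat\mu) - (y-\hat\mu)]$ (zero at a perfect fit, with
$0\log 0 = 0$); the covariate stream uses $-2\times$ its Gaussian log
likelihood. The DIC plug-in is the posterior mean of the stream's *fitted
means* — not the deviance at parameter-wise posterior means, which is
ambiguous under the log link ($E[\exp] \ne \exp[E]$). `pD` may legitimately
come out negative and is reported as computed.

Classification of target areas uses the posterior draws directly:
exceedance probability $p_k = \Pr(\rho_k > 1 \mid y, M, x)$, hotspot flag
$p_k > 0.8$ (strictly; boundary ties are measure-zero but the convention is
documented), and cluster-centre probability
$C_k = E\left[J_k \cdot \tfrac{1}{L_k}\sum_{l\in A_k} J_l\right]$ with
$J_k = I(\rho_k > 1)$ — the exceedance indicator of the area weighted by the
fraction of its $L_k$ neighbours also exceeding. This form makes
$0 \le C_k \le p_k$ automatic, and explains the lower cluster threshold of
0.25: flagging requires the area itself *and* at least a fair share of
neighbours to exceed jointly, so attainable values are diluted relative to
$p_k$. A stricter all-neighbours variant is available
(`clusterCentreProbability(..., allNeighbours = TRUE)`). Areas with no
neighbours score 0 with a warning. Localities $A_k$ come from a supplied
adjacency file when available; synthetic geographies use symmetric
5-nearest-neighbour localities on centroids, a choice made because the
motivating data's neighbourhood definition (contiguity versus distance) is
not recorded.

The conversion of relative risks to percentage prevalence multiplies by a
user-supplied region-wide rate (`regionalRate`, default 0.046); the model
itself only identifies relative risk, so the rate is an input, not an
estimate.

## The synthetic-data generator

No real prevalence extract ships with the package, so `generateGeography()` /
`generateTruth()` / `simulateObservations()` produce data with the model's
exact statistical structure. The generator emulates: clustered target
centroids (a parent–offspring process — interpolation over uniform centroids
would be artificially easy), source centroids jittered from target locations
(service areas sit among the neighbourhoods they serve, without nesting), a
regular grid covering the region, smooth latent surfaces built by the same
kernel convolution the model assumes, Poisson counts with log-normal
over-dispersion, and a hospitalisation stream driven by prevalence.

Default conditions: 189 source areas, 562 target areas, 84 grid points at
2 km spacing over a 22 × 12 km region; populations of about 5,380 (source)
and 1,500 (target) residents, log-normally scattered (σ = 0.3 on the log
scale); region-wide prevalence rate 4.6%; structural coefficients
β = (−0.25, 0.31), γ = (−1.8, 0.38), δ = (−3.37, 0.03), η₁ = 0; grid-process
variances 0.03 (latent-field standard deviations near 0.3 on the log-risk
scale); covariate noise variance 0.01. The morbidity offset rate is 10 per
1,000 residents, chosen so that with γ₁ ≈ −1.8 the *realized* crude
admission rate lands around 2–3 per 1,000, a realistic level for asthma
admissions.

What the generator does **not** emulate: real geography (roads, rivers,
population rasters), age–sex structure, spatially correlated grid effects,
multiple morbidity indicators or covariates, and reporting artefacts in
provider registers. Passing tests therefore demonstrate that the machinery
recovers the truth *when the model is true* at desk scale; they do not
validate the substantive model against real data.

## Problem sizes used by the test suite

All checks are sized for a single CPU. The canonical fixtures are
`defaultFixture(scale = "reduced")` — 60/150 areas, 25 grid points (a 5 × 5
grid at 2 km spacing over an 8 × 8 km region) — and
`defaultFixture(scale = "study")` with the full 189/562/84 dimensions.
Parameter-recovery and convergence checks run 2 chains × 5,000 iterations on
the reduced fixture; calibration runs 60 generate→fit cycles on a 12/24-area
toy with 9 grid points, with ranks taken from 24 well-spaced thinned draws;
the model-discrimination check runs ten replicates of paired variant fits at
40/80 areas and 16 grid points; the study-scale fixture gets a short
smoke-length fit demonstrating the full dimensions run end to end.

## Numerical choices and degenerate inputs

* Metropolis log-ratios are computed from closed-form likelihood
  *differences* (factorials and Gaussian constants cancel), so the hot loop
  is free of density-function calls; caches of the linear predictors and
  fitted means are updated incrementally on acceptance.
* `kernelWeight` rejects negative or non-finite distances; grids must have
  distinct points and positive spacing; offsets must be strictly positive
  (an expected count of zero would make the relative risk unidentifiable).
* Chains must retain at least 100 draws each for diagnostics; the
  configuration constructor enforces this rather than letting the PSRF
  silently degrade.
* Classification thresholds compare strictly (`>`); the degenerate PSRF case
  (zero variance) is defined as 1; empty draw sets error rather than
  returning NaN.
* Adaptation gain $t^{-0.6}$ decays fast enough that scales settle well
  before the burn-in ends; acceptance-rate accounting uses the expected
  acceptance probability rather than realised accept indicators, which gives
  a lower-variance adaptation signal.

## Known limitations

* The y-stream DIC barely separates the normal-process and t₅-process
  variants on data generated at reduced scale — the two priors for a few
  dozen weakly identified grid effects are nearly equivalent predictively.
  Model choice among variants should weigh all three streams and the
  stability of the resulting classifications, not a single DIC column.
* The pollution effect β₂ is the most weakly identified structural
  coefficient at reduced scale (its information comes from spatial
  covariation between the interpolated covariate surface and prevalence),
  and it is the slowest-mixing parameter; report it from long runs.
* Residuals on the target frame are informed only through the
  hospitalisation counts; with small counts they remain close to their
  prior, and the heteroscedasticity parameters are correspondingly diffuse.
* Coordinates are assumed planar (km); no projection support.
* One reflexive indicator and one formative covariate; the data model would
  extend, but the implementation deliberately does not.

```{r example, eval = FALSE}
# end-to-end sketch (see the README for a run with captured output)
study <- defaultFixture(seed = 1)
fit <- runMcmc(study$source, study$target, study$geography$grid,
               ModelSpec(), chainConfig(nChains = 2, nIter = 5000, seed = 2))
gelmanRubin(fit)
dicReport(fit, study$source, study$target)
riskSummary(fit, study$target, regionalRate = 0.046)
```
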