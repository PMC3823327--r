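# prevconv

Bayesian spatial interpolation of disease prevalence between misaligned areal
frameworks, using discrete process convolution and collateral data.

## The problem

Chronic-disease prevalence registers are often kept by health-care providers
for the populations they serve (e.g., GP practice areas), while health
profiling needs prevalence for residential neighbourhoods. The two partitions
are not nested: a practice's patients are scattered over many neighbourhoods
and a neighbourhood's residents over many practices. `prevconv` interpolates
prevalence from the observed *source* frame to the *target* frame while
borrowing strength from two kinds of collateral data observed on the target
frame only:

* a **reflexive** morbidity indicator — hospitalisation counts, which reflect
  latent prevalence;
* a **formative** ecological covariate — an air-quality index, which helps
  explain prevalence and must itself be interpolated back to the source frame.

## The model

Observed prevalence counts `y_i` on the source frame and hospitalisation
counts `M_k` on the target frame are Poisson with offsets (expected counts)
`E_i`, `G_k`:

    y_i ~ Po(E_i ρ_i)        log ρ_i = β₁ + β₂ x_Li + z₁(s_i) + e_i
    M_k ~ Po(G_k ν_k)        log ν_k = γ₁ + γ₂ ρ_k
    x_k ~ N(μ_k, σ²_x)       μ_k = η₁ + z₂(t_k)

and on the target frame `log ρ_k = β₁ + β₂ x_k + z₁(t_k) + e_k`. The latent
fields `z₁` (prevalence) and `z₂` (risk factor) are **discrete process
convolutions**: kernel-weighted sums `z(s) = Σ_j κ(|s − u_j|) w_j` of random
effects on a sparse regular grid `u_1..u_J`. `x_Li = η₁ + z₂(s_i)` carries the
covariate to the source frame. Residuals are heteroscedastic,
`e ~ N(0, V)` with `log V = δ₁ + δ₂ E/Ē`, allowing over-dispersion that varies
with population size. Kernels (standardised to weight 1 at distance 0):
normal `exp(−d²/2α²)`, exponential `exp(−d/η)`, Student-t; grid processes:
normal or Student-t(5). The four crossings of (normal | exponential kernel) ×
(normal | t₅ process) are the standard comparison set (`modelVariant(1:4)`).

Estimation is adaptive Metropolis-within-Gibbs MCMC with conjugate Gibbs
steps for the precisions, Brooks–Gelman–Rubin convergence diagnostics,
stream-specific DIC for model comparison, and posterior classification of
target areas by exceedance probability `Pr(ρ_k > 1 | y, M, x)` (hotspots,
threshold 0.8) and cluster-centre probability `C_k` (joint exceedance with
neighbours, threshold 0.25).

## Worked example

A synthetic study at reduced scale (60 source areas, 150 target areas, 25
grid points at 2 km spacing) generated with the package's defaults, fitted
with variant 1 (normal kernel, normal process):

```r
library(prevconv)
study <- defaultFixture(seed = 1)
fit <- runMcmc(study$source, study$target, study$geography$grid,
               ModelSpec(), chainConfig(nChains = 2, nIter = 5000, seed = 2))

round(gelmanRubin(fit), 3)
#>  beta1  beta2 gamma1 gamma2 delta1 delta2   eta1
#>  1.007  1.105  1.000  1.000  1.014  1.013  1.012

round(colMeans(drawsMatrix(fit, c("beta1", "beta2", "gamma1", "gamma2"))), 3)
#>  beta1  beta2 gamma1 gamma2
#> -0.353  0.163 -1.822  0.338
```

The generating values were β = (−0.25, 0.31), γ = (−1.8, 0.38): the
intercepts and the reflexive effect γ₂ are recovered well; the pollution
effect β₂ is the most weakly identified quantity at this scale (it is also
the slowest-mixing parameter — its PSRF of 1.105 sits at the conventional 1.1
cutoff, and a longer run is advisable before reporting it).

```r
dicReport(fit, study$source, study$target, label = "variant1")
#>      model stream    Dbar     Dhat     pD    DIC
#> 1 variant1      y   59.55    7.368 52.182  111.7
#> 2 variant1      M  171.60  167.050  4.554  176.2
#> 3 variant1      x -257.38 -270.567 13.187 -244.2

rs <- riskSummary(fit, study$target, regionalRate = 0.046)
sum(rs$hotspot); sum(rs$cluster)
#> [1] 16
#> [1] 35

head(rs, 3)
#>   area_id exceedance_prob cluster_prob hotspot cluster prevalence_pct
#> 1   t_001          0.0044      0.00024   FALSE   FALSE           2.70
#> 2   t_002          0.5568      0.27103   FALSE    TRUE           4.87
#> 3   t_003          0.7588      0.57414   FALSE    TRUE           5.42
```

`rs$prevalence_pct` converts relative risks to percentage prevalence via the
region-wide rate (4.6%): area `t_003` has an estimated prevalence of 5.4%
with a 76% posterior probability of above-average risk, and is flagged as a
cluster centre because its neighbours tend to exceed together with it.

A command-line front end over the same functions is installed at
`inst/scripts/prevconv.R` (subcommands `simulate`, `fit`, `assess`,
`classify`, `compare`; exit code 3 flags a failed convergence verdict).

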