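# siamix

Bulk stable-isotope diet analysis for marine consumers: δ-notation
arithmetic, C:N-driven lipid normalization of δ13C, trophic-position
estimation, a Bayesian mass-balance mixing model with multi-configuration
runs and model averaging, Bayesian standard-ellipse isotopic-niche metrics,
and two-way ANOVA / Tukey HSD group comparisons — plus seeded synthetic-data
generators so the entire pipeline is testable from published group moments
alone.

The package is built around a worked case study: the diet of the giant
manta ray (*Manta birostris*) off mainland Ecuador, reconstructed from
muscle-tissue δ13C/δ15N of 75 animals, surface zooplankton from 35 net
tows, and a mesopelagic-fish source. Its headline question — how much of a
surface-feeding planktivore's diet actually comes from surface zooplankton
versus mesopelagic prey — is answered with a mixing model run under four
DTDF/normalization configurations.

## The models

**Lipid normalization** (per sample, then averaged):
δ13C_LN = δ13C_bulk + 7.95 (C:N − 3.8)/C:N, applied when a group's mean
C:N exceeds 3.5.

**Trophic position**:
TL = (δ15N_consumer − δ15N_baseline)/DTDF_N + 2.5, with baseline 7 ‰.

**Mass-balance mixing model**: for isotope j and diet proportions p on the
simplex,

    y_ij ~ Normal( Σ_k p_k (μ_kj + c_kj),  Σ_k p_k² (ω_kj² + τ_kj²) + ε_j² )

with Dirichlet(1) prior on p and uniform(0, 10 ‰) priors on the residual
SDs ε_j, sampled by adaptive Metropolis-within-Gibbs on a softmax
reparameterization (4 chains × 10,000 iterations by default; split-chain
R̂ and effective-size diagnostics reported, non-convergence flagged).

**Isotopic niche**: SEA = π √det(S) of the bivariate (δ13C, δ15N)
covariance, SEAc = SEA (n−1)/(n−2), Bayesian SEA via a closed-form
inverse-Wishart posterior, and seeded Monte-Carlo ellipse-overlap areas.

See `vignettes/stable-isotope-diet-analysis.Rmd` for assumptions,
parameter meanings and numerical choices.

## Worked example

```r
library(siamix)
inp <- manta_diet_inputs()     # published group moments and DTDF sets

# zooplankton: normalize per tow, then average
tows <- simulate_tows(tow_sim_spec(seed = 1))
needs_lipid_normalization(tows$c_to_n)           # TRUE  (mean C:N 4.3)
mean(lipid_normalize(tows$d13C, tows$c_to_n))    # -19.67 (bulk was -20.5)

# four mixing models on 75 consumers at the muscle-tissue moments
cons <- simulate_population(seed = 1)
fits <- run_model_suite(cons,
  surface_variants = list(normalized = inp$sources$surface_ln,
                          bulk = inp$sources$surface_bulk),
  mesopelagic = inp$sources$mesopelagic,
  dtdfs = list(inp$dtdfs$large_shark, inp$dtdfs$leopard_shark),
  mcmc = mcmc_control(seed = 1))
fits[["Model 1"]]
#> Mixing-model posterior (Model 1)
#>   surface zooplankton (LN)     0.21 +/- 0.07  [0.07, 0.36]
#>   mesopelagic sources          0.79 +/- 0.07  [0.64, 0.93]
#>   residual sd: d13C 0.91, d15N 2.01; max Rhat 1.001
average_models(fits)
#>                     source      mean        sd
#> 1 surface zooplankton (LN) 0.2686387 0.1379757
#> 2      mesopelagic sources 0.7313613 0.1379757
```

Under every configuration the mesopelagic source carries the majority of
the diet; averaged over the four models the split is ≈27% surface / 73%
mesopelagic — surface zooplankton, the prey mantas are seen feeding on, is
the minority share. The trophic-position formula places the population at

```r
trophic_position(mean(cons$d15N), trophic_position_params(7, 3.7, 2.5))
#> [1] 3.47
```

i.e. a secondary consumer. `run_full_analysis()` executes all stages
(group summaries, trophic positions, mixing suite, niche ellipses,
ANOVA/Tukey) on a sample table and writes CSV reports plus a
digest-carrying `manifest.json`; `inst/cli/siamix.R` exposes the same
stages as shell subcommands (`simulate`, `normalize`, `trophic`, `mix`,
`ellipse`, `anova`, `all`).

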