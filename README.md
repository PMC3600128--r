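# stoprace

Response inhibition — the capacity to cancel an initiated action — is one
of the best-studied candidate endophenotypes of ADHD: it is impaired in
affected individuals and their relatives, varies continuously in the
general population, and is heritable. `stoprace` packages the full
analysis chain for studying it in family cohorts with the stop-signal task
(SST): race-model simulation of task sessions, scoring of trial records
into per-participant statistics, performance validity filtering, family
mixed models relating SST outcomes to ADHD trait ratings, and sibling
variance-components estimation of heritability and genetic correlation.
A synthetic family-cohort generator with known ground truth makes every
stage testable without access to any real cohort.

It is written for quantitative researchers in developmental
neuropsychology and psychiatric genetics who want a transparent, tested
reference implementation of this pipeline, in tidyverse style: data frames
in, tibbles out, `tidy()`/`glance()` on fitted objects, `autoplot()` on
results.

## The models

**Race model and SSRT.** Each trial is a race between a go process with
ex-Gaussian finishing time and a stop process starting SSD ms later with
latency SSRT ~ N⁺(μ_s, σ_s); a response is emitted iff the go process
finishes first (within 3,000 ms). The delay follows a one-up/one-down
staircase (start 250 ms, step 50 ms) that tracks P(inhibit) ≈ 0.5. SSRT is
estimated by the integration method: with *n* ranked no-signal RTs and
inhibition rate *p*, SSRT = RT₍⌈(1−p)n⌉₎ − mean SSD.

**Trait models.** For outcome Y ∈ {SSRT, GoRT, GoRTSD},

log Y_ij = x_ij'β + u_i + ε_ij,  u_i ~ N(0, σ_f²), ε_ij ~ N(0, σ_e²),

with family random intercept u_i and forward-stepwise fixed effects (trait,
age, sex, then age², age×sex, age²×sex). Predicted-value grids at covariate
extremes are back-transformed by exponentiation; effect sizes standardise
cell differences by the single-observation SD.

**Variance components.** For full sibs, Cov(y) = σ_A²K + σ_E²I with
K = 0.5(I + J) within family; h² = σ_A²/(σ_A² + σ_E²). A per-family
Helmert rotation diagonalises the covariance, so the univariate ML problem
profiles to one dimension and the bivariate model — cross-trait covariance
ρ_g σ_A1 σ_A2 (kinship-weighted) + ρ_e σ_E1 σ_E2 — factorises into 2×2
blocks. The phenotypic correlation decomposes as
ρ_P = ρ_g √(h₁²h₂²) + ρ_e √((1−h₁²)(1−h₂²)).

## Worked example

```r
library(stoprace)

# simulate 500 participants through a standard session and score them
trials <- simulate_sst(500, seed = 1)
scores <- score_sst(trials) |> apply_validity_filters()
dplyr::select(scores, participant_id, go_accuracy, gort_mean,
              p_inhibit, mean_ssd, ssrt, valid)
#> 1 p0001  0.986  620.  0.5    317.  300. TRUE
#> 2 p0002  0.917  622.  0.5    250   369  TRUE
#> ...
mean(scores$p_inhibit)
#> [1] 0.505
```

The staircase holds the average inhibition rate at one half, so the
integration estimate is well defined for nearly everyone.

```r
# a synthetic sibling cohort with known heritabilities
cohort <- generate_cohort(cohort_spec(n_families = 1500), seed = 2)
univariate_h2(cohort, "latent_inh")
#> Heritability of latent_inh: h2 = 0.401 (SE 0.046),
#>   95% CI [0.312, 0.491], p = 1.35e-18
#>   3167 individuals in 1500 families; covariates: age, sex

bivariate_fit(cohort, "latent_inh", "latent_var")
#> Bivariate variance components for latent_inh and latent_var
#>   h2: 0.401 / 0.178
#>   rhog = 0.401 (SE 0.118), p[rhog = 0] = 9.24e-11
#>   rhoe = 0.227, implied rhop = 0.266
```

The generator configured h² = 0.31 for the inhibition liability and a
genetic correlation of 0.42 with the variability liability; at 1,500
families both are recovered within two standard errors, and the reported SE
shrinks toward 0.03 at the full 3,507-family scale.

```r
# predicted-value contrasts on the bundled reference grid
g <- sst_reference_grid()
cell_difference(g,
  list(measure = "ssrt", sex = "female", age = 6, trait = 54),
  list(measure = "ssrt", sex = "female", age = 6, trait = -54))
#> [1] 138
```

A 138 ms SSRT difference between trait extremes at age 6 — the worst-case
gradient in the reference grid, equivalent to a pooled effect size of about
1.48.

`run_pipeline()` chains all stages (generation, simulation, scoring,
filtering, group comparison, trait models, heritability) into one report
object; `inst/scripts/sst_pipeline.R` exposes the same stages as a command
line with `simulate`, `score`, `model`, `heritability` and `all`
subcommands.

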