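---
title: "Methods: race-model simulation, SST scoring and sibling heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-model simulation, SST scoring and sibling heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `stoprace`, the assumptions they
make, the tunable parameters that matter, and the design choices taken where
the design was genuinely open. The package studies response inhibition as a
candidate endophenotype of ADHD: it simulates and scores the stop-signal
task (SST), relates the resulting phenotypes to ADHD trait ratings with
family mixed models, and estimates how heritable those phenotypes are — and
how much genetic ground they share — from sibling resemblance.

## The horse-race model of stopping

A stop-signal trial is modelled as a race between two independent
processes. The *go* process starts at go-stimulus onset and finishes after
an ex-Gaussian latency, Normal(`go_mu`, `go_sigma`) + Exp(`go_tau`) ms.
The *stop* process starts `SSD` ms later (the stop-signal delay) and
finishes after a latency — the stop-signal reaction time, SSRT — drawn from
a normal truncated at zero (`ssrt_mean`, `ssrt_sd`). A response is emitted
iff the go process finishes first and within the 3,000 ms response window;
otherwise the trial is a successful stop. Independence of the two
finishing times is an assumption of the race model, not a finding; the
package enforces it by construction and the test suite verifies its
observable signature (go-trial RTs are distributionally unaffected by
interleaved stop trials).

The ex-Gaussian is the standard positively-skewed RT family; nothing in the
scoring depends on this choice. Defaults (`go_mu` 489, `go_sigma` 115,
`go_tau` 110) put the mean go RT at 599 ms with within-person SD 159 ms,
the scale reported for school-age community samples. The stop-latency
family is likewise unconstrained by the task description; a truncated
normal (default mean 280 ms, SD 50 ms) is the simplest positive-support
choice. Both are generator configuration, not claims about any real
population.

### The tracking staircase

The delay starts at 250 ms and moves one step (50 ms) up after every
successful stop and down after every failed one, clamped at a floor of
0 ms (no minimum delay is conventionally specified; a negative delay is
physically meaningless, and the floor is exposed as a parameter). This
one-up/one-down rule tracks the delay at which stopping succeeds half the
time.

The tracker is unbiased only once it has reached its equilibrium. Over a
session with `S` stop trials, the session-mean inhibition rate is
approximately `0.5 + (SSD_final - SSD_initial) / (2 * step * S)`, so
parameter sets whose equilibrium delay lies far from the 250 ms start show
a transient excess or deficit. With the default parameters the equilibrium
sits near 295 ms and the mean inhibition rate lands near 0.505; parameter
sets whose equilibrium is several hundred ms away would need more than the
24 experimental stop trials to converge. The tracking property test
therefore spans the study-like parameter regime (stop latencies 230–320 ms,
go means 440–600 ms), not arbitrary parameter corners.

## Scoring and validity

Per participant the package computes go accuracy (correct responses over
*all* go trials, so omissions count against accuracy), the mean and sample
SD of correct go RTs (GoRT, GoRTSD), the inhibition rate `p_inhibit`, the
mean delay over experimental stop trials, and the integration-method SSRT:
rank the responded no-signal RTs, take the RT at rank
`ceiling((1 - p_inhibit) * n)`, and subtract the mean delay. The rank
convention follows the logic that the slowest `p_inhibit` fraction of go
responses are the ones that would have been stopped; at `p_inhibit = 0.5`
the estimate converges on the classical mean-subtraction estimate (tested).
Failed-stop RTs are never ranked; wrong-key go responses are ranked (they
index go-process speed) but excluded from GoRT/GoRTSD. The estimate is
undefined at `p_inhibit` of 0 or 1 — such participants fail the validity
band anyway.

Validity filters mirror standard practice: go accuracy at least 66%, mean
go RT at least 100 ms (faster means guessing), inhibition rate inside
[0.20, 0.80], with a strict [0.40, 0.60] variant for sensitivity analyses;
sessions with fewer than the scheduled 96 experimental trials are flagged
incomplete. The practice block is simulated (the staircase runs through it,
so experimental blocks start from a settled delay) but never scored.

Stimulant medication shortens SSRT, so medicated participants are excluded
from primary analyses by default; the sensitivity path instead lengthens
their SSRT by 0.75 times the SD of SSRT among unmedicated valid
participants — the published effect of a moderate stimulant dose. The
cohort's own unmedicated SD anchors the correction because no external SD
is available to the package.

## Trait regressions

SST outcomes are modelled on the natural-log scale (their raw distributions
are right-skewed; log residuals are approximately normal, which the suite
checks by skewness on multiplicatively generated data) with a family
random intercept. Fixed effects enter by forward stepwise selection with
likelihood-ratio entry at `entry_alpha = 0.05` (no conventional criterion
exists; 0.05 matches the entry test's nominal level). Higher-order terms —
`age^2`, `age:sex`, `age^2:sex` — are assessed only after their constituent
main effects enter. GoRTSD models control log GoRT because latency and
variability are strongly correlated and their ratio has intractable
residuals. Subscale analyses (inattention, hyperactivity-impulsivity) reuse
the same machinery by passing a different trait column.

Predicted-value grids put the random effect at zero and back-transform by
plain exponentiation — the predicted median on the ms scale; no smearing
correction is applied because the grid is descriptive, not a cost
prediction. The 95% band uses the linear-predictor SE; the
single-observation SD adds the family and residual variances on the log
scale and maps through the log-normal. Grids at trait scores ±54 typically
extrapolate a little beyond the observed trait range; the package warns
rather than errors, since the extreme-cell layout is the point of the
table.

Effect sizes standardise a difference of two predicted cells. The default
divides by the pooled single-observation SD, `sqrt((sd1^2 + sd2^2)/2)` —
consistent with calling the inputs "standard deviations of a single
observation". A "printed" mode dividing by `sqrt(|sd1^2 - sd2^2|)` is
retained for fidelity to a formula that circulates with a minus sign under
the root; it degenerates when cells have similar dispersion and then errors
with a pointer to the pooled mode. Neither mode silently corrects the
other.

## Sibling variance components

For full siblings the expected additive-genetic relationship matrix `K`
has 1 on the diagonal and 0.5 between sibs. The phenotype model is
`y = X b + g + e` with `Cov(y) = sA^2 K + sE^2 I` and
`h2 = sA^2 / (sA^2 + sE^2)` — the genetic share of the phenotypic variance
that remains after covariates. Because `K` is compound-symmetric within a
family, a per-family Helmert rotation diagonalises the covariance: the
family mean carries relationship eigenvalue `(n+1)/2`, each of the `n-1`
sib contrasts carries `1/2`. Covariate effects and the total variance then
have closed-form generalised-least-squares solutions given `h2`, so the
univariate ML problem is a one-dimensional maximisation of the profile
likelihood over `h2` in [0, 1] — fast, and free of the local-optimum and
boundary pathologies of unstructured optimisation. The SE comes from the
curvature of the profile log-likelihood; the test of `h2 = 0` uses the
boundary 1/2:1/2 mixture of chi-square(0) and chi-square(1) (the standard
convention for a variance component on its boundary); the confidence
interval is the asymptotic normal interval clamped to [0, 1].

The bivariate model adds a genetic correlation `rhog` and an environmental
correlation `rhoe`: cross-trait covariance `rhog sA1 sA2 + rhoe sE1 sE2`
within a person and `0.5 rhog sA1 sA2` between sibs. The same rotation
reduces the likelihood to independent 2×2 blocks, one per eigenvalue, so
each evaluation costs a handful of 2×2 solves regardless of cohort size.
Optimisation runs on `(h2_1, h2_2, log sP1^2, log sP2^2, rhog, rhoe)` with
box constraints and three starts (the empirical residual correlation,
a high-`rhog` start, and a zero-`rhog` start) to guard against local
optima. `rhog` is tested against zero by a plain 1-df likelihood ratio
(it is interior to [-1, 1]); its SE comes from the observed information and
is reported as `NA` at the ±1 boundary, where the quadratic approximation
fails. If either trait's heritability collapses to the zero boundary,
`rhog` is unidentifiable and reported as such. The fitted parameters
reproduce the decomposition
`rhop = rhog*sqrt(h1^2)*sqrt(h2^2) + rhoe*sqrt(1-h1^2)*sqrt(1-h2^2)`
identically, and the suite asserts the identity numerically.

Households and shared environment are deliberately omitted: with
sibling-only pedigrees a common-environment component is confounded with
additive variance, and twin evidence attributes familial resemblance on
these measures largely to genes. Interfamilial correlation is therefore
read as genetic — an interpretive assumption, stated rather than tested.
Singleton families are retained; they carry no kinship signal but inform
covariate effects and the total variance. Covariates enter the mean model
simultaneously with variance estimation (not residualised in a prior
pass); both the age+sex and age+sex+ethnicity covariate conventions are
expressible by passing the covariate vector, since published tables differ
on which set they adjust for.

## The synthetic cohort

The generator is the package's study population. Families (default 3,507)
draw sizes 2–5 with weights 3081:387:35:4, ages uniform on 6–18, sexes at
49.9% male. Four latent traits — ADHD liability, inhibition, latency,
variability — get additive-genetic structure by giving each individual
`sqrt(0.5)` of a family factor plus `sqrt(0.5)` of an individual factor,
so the sibling genetic correlation is exactly 0.5; defaults set
heritabilities 0.38/0.31/0.26/0.28 and a genetic-correlation structure in
which inhibition shares risk with the ADHD liability (0.18) and with
variability (0.42), and latency with variability (0.71). Environmental
correlations are small and positive except a moderate latency–variability
link. These values reproduce the pattern reported for large sibling
cohorts and are the generator's *conditions*, not estimates.

SWAN-style ratings discretise a shifted normal per item onto the reversed
7-point scale (-3..+3), nine inattention and nine hyperactivity-impulsivity
items; totals are bounded in [-54, 54] and equal the subscale sum on every
draw. The internal latent scale is shrunk so the *total* SD hits its
target (default 16.3 around mean -5.8) despite item noise and rounding;
item noise still attenuates the measured total's heritability slightly
below the latent 0.38 (by ~6% of itself), which is the realistic direction
of error for a rating scale. The generator matches moments only — no claim
is made about the shape of real SWAN distributions.

Race parameters come from a fixed linear calibration of the three
performance latents (scaled by 16.3 into trait-equivalent units): at age 6
the SSRT gradient from trait -54 to +54 is 138 ms, the GoRT gradient 30 ms
and the GoRTSD gradient 51 ms, all shallower at age 18, all declining with
age, boys slightly faster — the gradient pattern of the reference
predicted-value grid shipped with the package. `trait_slope` and
`demo_slope` multipliers scale these gradients (zero gives every individual
identical baseline parameters). Medicated children (2.6%) get SSRT
parameters shortened by 0.75 population SDs so the correction path has
something to correct. A configurable fraction of invalid performers —
guessers (sub-100 ms responses, high error rates), quitters (half their go
trials omitted) and non-stoppers (stop latency far beyond the go
distribution) — is injected with probability increasing for younger,
higher-trait boys, so exclusion accounting reproduces the familiar
demographic skew of excluded cases. Interrupted sessions truncate at a
random trial.

What the generator does *not* emulate: age-correlated sibships (sib ages
are independent), rating-informant effects, socioeconomic or ethnicity
structure (no performance effects are generated for them), non-sibling
relatives, and any form of gene–environment correlation or interaction.
Passing recovery tests therefore shows the estimators are correct under
the additive model they assume — not that real cohorts satisfy that model.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: all-singleton pedigrees abort
(h2 unidentifiable); participants with no responded go trial are
unscorable; `p_inhibit` at 0 or 1 makes SSRT undefined rather than
infinite; rank indices clamp to [1, n]; the SSD floor clamps at 0; ties in
the go-RT ranking resolve by stable sort order. The likelihood guards
against non-positive-definite 2×2 blocks by returning a large penalty, and
finite-difference probes just outside the box are clamped back in.

Test and script problem sizes were chosen so each check has the power it
needs and no more: 2,000 simulated participants bound the tracking rate to
±0.03; 10,000 participants bound the end-to-end SSRT recovery to ±15 ms;
heritability recovery runs at the full 3,507-family scale, where the
profiled likelihood makes a univariate fit essentially instant and a
bivariate fit sub-second; oracle comparisons use 5–7-member toy pedigrees
where a dense grid search is exact. The pipeline's default report on a few
hundred families completes in seconds.

## Known limitations

The integration estimator carries a small negative bias (a few ms at
default parameters) from delay-tracking variability — visible in the
end-to-end recovery check and well inside its tolerance, but worth
remembering when comparing absolute SSRT levels across parameter regimes.
Profile-likelihood SEs and the normal CI are asymptotic; at a few hundred
families the CI under-covers slightly near the boundaries. The stepwise
procedure inherits the usual caveats of forward selection (selection
uncertainty is not propagated into the reported SEs). And the sibling
design cannot separate shared environment from additive genetics; the
reported `h2` is an upper bound under that confounding.
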