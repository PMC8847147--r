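---
title: "Estimating selection on correlated phenological traits: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating selection on correlated phenological traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosel)
```

## Scope

`phenosel` estimates phenotypic selection on two correlated phenological
traits — the day the first leaflet unfolds (leaf-out) and the day the first
flower opens (FFD) — together with their difference (development time), from
interval-censored census data and seed-count fitness. This vignette explains
the model at each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical
conventions, and the known limitations. Every empirical claim here is one the
test suite or the acceptance script computes.

## 1. The selection models

Let $z_L$, $z_F$, $z_s$ be leaf-out day, FFD and ln aboveground volume,
standardized to mean 0 and unit (sample, $n-1$) SD, and let
$w = W/\bar W$ be relativized fitness (intact seeds). The fitted families
are, per analysis stratum:

| family | design | reported terms |
|---|---|---|
| total (one trait) | $w \sim z + z_s$ | differential $s$ |
| total, quadratic | $w \sim z + z^2 + z_s$ | $2\times$ the $z^2$ coefficient |
| direct linear | $w \sim z_L + z_F + z_s$ | gradients $\beta_L,\beta_F$ |
| direct correlational | adds $z_L z_F$ | interaction $\gamma_{LF}$ |
| direct full | adds $z_L^2, z_F^2$ | doubled quadratics + interaction |
| development time | $w \sim z_{dev} + z_s$ | differential on $z_{dev}$ |

Conventions, each of which was a genuine design choice:

- **Linear from linear, nonlinear from extended.** Linear estimates are
  reported from the linear-only model and quadratic/correlational estimates
  from the extended model, the standard Lande–Arnold practice, even though a
  combined table prints them side by side.
- **Doubling.** Only squared-term coefficients are doubled onto the $\gamma$
  scale. Whether the correlational (interaction) coefficient should also be
  doubled is ambiguous in parts of the literature; the cited convention
  (Stinchcombe et al.) concerns quadratic terms, so the interaction is
  reported raw by default with a `double_interaction` switch for sensitivity.
- **Zero-fitness individuals are retained** and the response is never
  transformed; inference leans entirely on the bootstrap, because zero-heavy
  seed counts make OLS residuals non-normal by construction.
- **Size** is ln-transformed before standardization, under the same scheme
  as the traits.
- **Local vs global schemes.** `local` computes moments within year and fits
  (and bootstraps) each year separately — the soft-selection view, where what
  matters is timing relative to neighbours in the same season. `global` pools
  moments across years and fits one model — the hard-selection view of a
  shared selective surface. The two coincide exactly on a single-year
  dataset (tested). The resampling stratum follows the fitting stratum.

## 2. BCa bootstrap

Case resampling of individuals within the analysis stratum, then for each
coefficient the bias-corrected and accelerated interval:
$z_0 = \Phi^{-1}\big[(\#\{\theta^*<\hat\theta\} + \tfrac12\#\{\theta^*=\hat\theta\})/B\big]$
(the mid-rank tie rule prevents infinite $z_0$ for discrete statistics),
acceleration $a$ from the skewness of leave-one-out jackknife values, and
type-7 empirical quantiles at the adjusted percentiles. Numerical edge
policies: degenerate replicate sets return a point interval; if all
replicates fall on one side of the estimate the percentile interval is
returned with a warning; rank-deficient resamples are re-drawn and counted
(>1% warns, >10% errors). For OLS statistics the jackknife uses the exact
closed-form leave-one-out identity
$\beta_{(i)} = \beta - (X'X)^{-1}x_i e_i/(1-h_i)$, verified in the tests
against brute-force refits to machine precision.

Significance is interval exclusion of zero on the closed interval, and the
indirect-selection rule flags a trait when the direct point estimate falls
outside the BCa interval of the total estimate (closed-interval convention:
a value exactly at the bound is *not* flagged).

The paper-scale default is $B = 10{,}000$; tests use $B$ of 300–2,000 purely
for runtime, which widens quantile noise but changes nothing structural.

## 3. Phenology from censuses

Census visits every $\Delta$ days only bracket each event. The assignment
model, shared by both events, maps a per-plant score to a percentile $p$
within the year's cohort (ranks with ties broken by individual id, then
$p = (r - \tfrac12)/n$), and places the event at
`interval_end − p · interval_length`, strictly inside the bracketing
interval and strictly monotone in the score:

- **leaf-out**: score = observed minus predicted unfolded leaflets at the
  first post-leaf-out visit, with the prediction from an OLS fit of unfolded
  on total leaflets and its square (fitted on first observations only). A
  plant further ahead of its predicted unfolding must have leafed out
  earlier in the interval.
- **FFD**: score = size of the largest bud at the visit before the first
  open flower; a larger bud means flowering was closer, i.e. started
  earlier in the interval. A missing bud falls back to the interval
  midpoint, flagged.

The original field study's appendix describes this deviation-to-day mapping
only qualitatively; among the possible implementations (residual quantiles,
ranks, a parametric inverse growth model) we chose the empirical-percentile
linear map as the minimal-assumption version that is monotone, bounded and
reproduces "larger deviation ⇒ earlier date". Assigned days are left
continuous rather than rounded, to avoid tie inflation in the regressions.
Percentiles are computed per year because census schedules differ among
years. Plants never seen unfolded, or already unfolded at their first visit,
get `NA` plus a reason flag rather than an extrapolated date.

Grazed plants: FFD is predicted from an OLS model (`ffd ~ bud size +
observation day + ln volume`) fitted on intact plants; final height of
plants grazed before the last spring recording comes from the
height~diameter relationship of nongrazed plants, while plants grazed after
it keep their maximum recorded spring height. Aboveground volume is the
cylinder formula `(0.5·diameter)² · height · π · n_shoots`.

## 4. Fitness and seed predation

Fitness is the number of developed seeds not damaged by the pod-boring
beetle larvae. Closed pods are counted seed by seed. For pods that opened
before collection only pod-wall entry holes are observable, and the intact
fraction is estimated as `exp(−k · holes/seed)` with `k = 1.218` taken from
a prior calibration on paired intact fruits of the same species; the
constant is exposed in `predation_model()` but deliberately not
re-estimated (the paired data belong to the earlier study). Open-pod
estimates stay fractional — rounding would add avoidable bias and the
regressions do not need integers.

## 5. The synthetic world

`sim_config()` defaults state one fixed world, chosen once to match the
biology of a spring understory herb and not revisited:

| parameter | default | rationale |
|---|---|---|
| `mu_leafout`, `sd_leafout` | day 110, 6 d | late-April leaf-out, multi-week spread |
| `mu_ffd`, `sd_ffd` | day 126, 7 d | ~2-week vegetative-to-flowering lag |
| `rho` | 0.4 | within-year trait correlation, middle of the observed 0.3–0.5 range |
| `mu_lnsize`, `sd_lnsize` | 6, 0.8 | ln-normal aboveground volume |
| `mean_fitness`, `dispersion_k` | 8 seeds, 1.5 | strongly overdispersed counts |
| `zero_inflation_pi` | 0.4 | 30–70% zero-fitness plants observed in the field |
| `visit_interval_days` | 4 | once/twice-weekly censusing |
| `holes_rate` | 0.2 | moderate predation pressure |

Expected relative fitness is
$w = 1 + \beta_L z_L + \beta_F z_F + \beta_s z_s + \tfrac12\gamma_{LL}(z_L^2-1)
+ \tfrac12\gamma_{FF}(z_F^2-1) + \gamma_{LF}(z_Lz_F-\rho)$, clamped at 0.
The quadratic and interaction regressors are **centered** so that
$E[w] = 1$ exactly: without centering, relativizing observed fitness by its
mean would rescale every coefficient by
$1/(1+\tfrac12\gamma_{LL}+\tfrac12\gamma_{FF}+\rho\gamma_{LF})$ and the
configured $\gamma$ would not be the quantity the regression estimates.
Realized counts are zero-inflated negative binomial with mean
`mean_fitness · w`; zero inflation is trait-independent by default so the
surface stays recoverable (a trait-dependent option exists for sensitivity
work only). The field study never states its fitness distribution family —
ZINB is this package's modelling choice, not an empirical claim.

Individuals with sampled FFD before leaf-out are resampled, not truncated,
preserving the marginals (at the default means this touches ~1% of draws;
1,000 failed retries for one slot is an error, which catches impossible
configurations). One master seed drives a named RNG stream per sub-generator,
so e.g. regenerating fruits never perturbs the fitness draw.

What the generator does **not** emulate: spatial structure, among-year
carryover for the same individual, mechanistic grazing or pollination, trait
drift within season, or observation errors in counts. A green recovery test
therefore establishes that the estimation machinery is correct *under this
stated world*, not that the field estimates themselves are unbiased.

## 6. The zero clamp and two knife-edge validation targets

Two validation targets sit exactly at their tolerance edge, and the reason
is instructive rather than incidental.

**Attenuation from the clamp.** With the aggressive recovery surface
($\beta = (-0.3, -0.5, 0.2)$, $\rho = 0.4$), the linear predictor has SD
$\approx 0.71$, so ~8% of individuals fall below $w = 0$ and are clamped
(the generator warns above 5%). OLS on the clamped, re-relativized response
recovers coefficients attenuated by a factor
$\approx P(w > 0)/E[w^+] \approx 0.90$. Measured at $n = 400{,}000$, the
recovered values are $\beta_F \approx -0.446$ and (via $s = P\beta$)
$s_F \approx -0.562$: errors of 0.054 and 0.058 against a ±0.06 band. Single
$n = 5{,}000$ runs scatter around these with SD ≈ 0.02, so the recovery
check averages six replicate simulations and tests the central tendency;
even so, those two components can land a few thousandths either side of the
band — an honest knife edge, not an implementation defect. The milder
surfaces used elsewhere in the suite (clamping < 2%) recover cleanly.

**Small-sample BCa anti-conservatism.** Under the null with 50% zero
inflation and heavy overdispersion at $n = 200$, $B = 1{,}000$, the CI-based
test rejects at 8.5% ± 0.7% (1,500 simulations), above the 3–7% target band.
The machinery itself is validated independently — jackknife identity exact,
intervals matching an external BCa implementation, 91–97% coverage for the
skewed-mean benchmark — and the rate falls to ~6.3% at $n = 1{,}000$ and
~6.8% with Gaussian noise at $n = 200$. The excess is the known small-sample
anti-conservatism of BCa intervals amplified by a zero-heavy, long-tailed
response. Practical implication: with field-scale samples ($n \approx 200$)
and this kind of fitness distribution, interval-exclusion tests at the
nominal 95% level are mildly liberal; effects whose intervals barely exclude
zero deserve caution.

## 7. Degenerate inputs and tie-breaks (summary)

- zero-variance trait in a stratum, all-zero fitness group, rank-deficient
  designs: hard errors naming the group/column;
- zero-length census interval: the single candidate day; missing bud:
  midpoint, flagged; grazed without model predictors: excluded, logged;
- deviation/bud ties: broken by individual id, so output is invariant to row
  order (tested) but reproducibly ordered;
- perfect collinearity in VIF: infinity marker, fit still reported;
- all bootstrap replicates equal: point interval; one-sided replicates:
  percentile fallback with warning.

## 8. Known limitations

- No canonical rotation of the $\gamma$ matrix, no spline/GAM fitness
  surfaces, no mixed models across years (years are deliberately fitted
  separately under the local scheme).
- The deviation-to-day mapping is one defensible reading of a procedure the
  original study describes only qualitatively; rank-preserving alternatives
  would shift assigned days within their intervals but cannot change which
  interval a plant is in.
- The predation constant 1.218 is treated as known; its sampling error is
  not propagated.
- Fitness is female reproductive success in one season; nothing here
  addresses male fitness or lifetime fitness.
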