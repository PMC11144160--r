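---
title: "Models and design choices in winterscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in winterscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterscape)
```

`winterscape` chains three pieces of statistical machinery — probabilistic
assignment to origin on isoscapes, phenotype mixed models, and
proportional-hazards return models — and validates the whole chain against
a synthetic-data generator that plants the effects the models are meant to
find. This vignette documents the models, their assumptions, the tunable
parameters, and the places where a design had to be chosen among
defensible alternatives.

## 1. Assignment to origin

### The model

A feather grown on the wintering grounds carries the local deuterium and
carbon signature. Given co-registered expected-value surfaces
$\mu_H(c), \mu_C(c)$ (a precipitation isoscape passed through the
calibration $\delta^2H_f = -6.77 + 1.42\,\delta^2H_p$, and a plant carbon
isoscape shifted by the $+2$ ‰ diet-to-consumer discrimination), the
likelihood of a sample $y = (y_H, y_C)$ at cell $c$ is the bivariate
normal density with diagonal covariance
$\mathrm{diag}(\sigma_H^2, \sigma_C^2)$. The diagonal form encodes the
assumption that the two isoscapes are governed by independent
biogeoclimatic processes; a correlation parameter `rho` is exposed for
sensitivity analyses and defaults to 0. Normalizing over the unmasked grid
(an implicit uniform spatial prior) gives the posterior origin surface.
Nitrogen is deliberately excluded from assignment: it has no usable
spatial prediction surface because of agricultural inputs, so the
generator treats it as an individual-level (aspatial) trait.

Numerically, densities are computed in log space and normalized after
subtracting the maximum, so fine grids and distant cells cannot underflow.
Setting a sigma to `Inf` drops that isotope from the likelihood, giving
single-isotope assignment.

### The odds-ratio region

The binary potential-origin map keeps the smallest set of
highest-probability cells whose cumulative mass reaches the threshold
(default $2/3$, the conservative "66.7 %" odds ratio). Two details the
threshold rule does not determine by itself:

* **Ties.** All cells tied with the last included probability are
  included. This makes the rule deterministic and (slightly) conservative;
  the achieved mass is recorded alongside the map.
* **Exact boundary.** The comparison uses a $10^{-12}$ slack so that an
  exactly uniform posterior of $k$ cells includes $\lceil 2k/3 \rceil$
  cells before tie expansion rather than falling prey to floating-point
  rounding.

The region is a credible set under the uniform-prior model, so when the
working sigmas equal the generative ones its frequentist coverage of the
true origin is close to the nominal mass (slightly above, because of the
discrete overshoot and the tie rule). Inflating the working sigmas makes
it conservative, deflating them anticonservative — `coverage_calibration()`
measures this directly and the test suite checks all three regimes.

### Sigma defaults

No published value exists for the per-isotope assignment SDs, so they are
configuration, not constants: surfaces carry their own sigma, functions
accept overrides, and when nothing is specified the package falls back to
$\sigma_H = 12$ ‰ (a typical feather-calibration residual) and
$\sigma_C = 1.5$ ‰. The generator attaches the SDs implied by its own
noise model ($\sqrt{12^2 + 2^2}$ ‰ for deuterium: calibration residual
plus measurement error; $0.1$ ‰ for carbon), which is what makes the
coverage experiment correctly specified.

### Grouping and counting

Blackness groups are low $< 33\,\%$, moderate $33$–$66\,\%$ (both
boundaries included), high $> 66\,\%$. Counting is per individual-record:
an individual sampled in several years contributes one binary map per
record, which matches group sizes defined over records rather than over
birds.

## 2. Phenotype models

* **Repeatability.** $R = V_{id}/(V_{id}+V_{res})$ from a REML
  random-intercept fit; confidence interval by parametric bootstrap
  (simulate from the fitted model, refit, percentile interval, default
  1000 resamples with a required seed); p-value from a likelihood-ratio
  test against $V_{id}=0$ halved for the boundary. $R$ is invariant to
  affine transformation of the response, which the tests check.
* **Blackness model.** `blackness ~ d2H + d13C + d15N + age + (1 | id)`,
  REML, age coded old-reference so the reported coefficient is the young
  effect. Degrees of freedom and SEs use Kenward-Roger when `pbkrtest` is
  installed, Satterthwaite otherwise; the method actually used is recorded
  in the fit metadata, as is a singular-fit flag. Year is deliberately not
  a term: the roster is constructed to cover the full coloration range
  every year, so year explains no blackness variance by design.
* **Dispersion check.** Regress $\delta^2H_f$ on blackness, then the
  absolute residuals on blackness again; the stage-two slope measures
  whether habitat-rainfall variability changes along the coloration
  gradient. Under homoscedasticity its type-I error is nominal (tested).
* **Between-year change.** Within-individual consecutive-year deltas of
  blackness regressed on deltas of $\delta^2H_f$, controlling for the age
  class at the first capture of each pair (which carries the
  young-to-old darkening). Refused below four pairs — fewer leave no
  residual degrees of freedom worth reporting.
* **Isotope-climate associations.** Yearly mean isotope against yearly
  index, one simple regression per isotope-index pair, flagged
  exploratory: eight points per regression is a screen, not an inference.

## 3. Return models

The outcome is binary (returned to the breeding site next spring or not),
but the field fits it as a survival model. The construction implemented —
the only one consistent with a binary response — is unit follow-up time
with event = returned, all events tied at $t = 1$, Breslow tie handling,
fixed effects predictor + environment + interaction + age at first
capture, gaussian frailty on individual. Twelve such models (4 predictors
× 3 indices) form the battery; no multiplicity adjustment is applied, and
failed fits are flagged rather than dropped so the battery always has 12
rows.

Because all events share one risk set, the Breslow partial likelihood
shrinks coefficients towards zero when the event fraction is substantial
(measured: roughly four-fold at a 35 % return rate). The package therefore
also offers the equivalent discrete-time formulation — a binomial model
with complementary log-log link, optionally with a random intercept — which
is the exactly specified likelihood for a single-interval
proportional-hazards process. The two routes must agree in sign, with the
Cox estimate no larger in magnitude; coefficient-recovery validation uses
the cloglog route. Isotope values are carried forward as proxies for
conditions in later winters, which leans on the high carbon/nitrogen
repeatability and is exactly the assumption the repeatability module
quantifies.

Risk curves transform a fit into relative risk
$\exp\{(\beta_x + \beta_{xe}e)(x - x_{ref})\}$ across the predictor range
at the 10/50/90 % quantiles of the observed environmental series, age at
its reference level. Risk is 1 at the reference value at every
environmental level, environmental main effects cancel, and with a
sufficiently negative interaction the slope reverses sign between the low
and high quantiles — the signature carry-over pattern.

## 4. The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions the package validates against.

### What it emulates

* **Isoscapes** (`make_isoscapes`): planar gradients — deuterium
  west-to-east over $[-60, -10]$ ‰, carbon south-to-north over
  $[-28, -13]$ ‰, deliberately non-collinear so dual-isotope assignment is
  identifiable — plus gaussian-smoothed noise (amplitudes 1.5/0.4 ‰,
  length scale 3 cells) and a 5 % smooth-blob mask. Zero noise gives the
  exact plane; everything is deterministic given the seed.
* **Roster** (`make_roster`): eight years with 28–31 males each, 240
  records, 209 individuals of which 31 appear in two consecutive years
  (age advancing young → old). New individuals draw a *latent* blackness
  uniformly on the 0–100 % grid in 5 % steps, emulating deliberate
  balanced sampling of the coloration range each year.
* **Origins** (`assign_true_origins`): the latent score is mapped through
  the inverse of the planted blackness-deuterium line and rescaled into a
  ±24 ‰ feather-deuterium band around the surface center; cells matching
  the target within 3 ‰ are candidates. Returning individuals re-draw
  among cells matching their previous origin's carbon value within 1 ‰,
  with fresh deuterium jitter (SD 10 ‰) — this is what makes carbon highly
  repeatable across years while deuterium is not, reproducing the observed
  repeatability contrast.
* **Feather values** (`sample_feather_values`): deuterium = calibrated
  surface value + calibration residual (SD 12 ‰) + measurement error
  (SD 2 ‰); carbon = discriminated plant value + measurement error
  (SD 0.1 ‰); nitrogen = individual baseline (between-SD 1 ‰) +
  within-year (0.5 ‰) + measurement (0.1 ‰) noise, giving repeatability
  near 0.8 with no spatial surface.
* **Observed blackness**: drawn from the planted mixed model given the
  *observed* deuterium — mean $= \beta_0 - 0.50\,\delta^2H_f -
  19.30\,[\text{young}]$, ring variance 365.8, residual variance 314.8 —
  then snapped to the 5 % grid. The intercept is set so blackness centers
  at 50 %.
* **Environment** (`make_env_series`): NAO $\sim N(-0.31, 1.87^2)$ per
  winter; rainfall $= 55.3 - 5.7\,\mathrm{NAO} + N(0, 4^2)$ mm (negative
  coupling: positive NAO means drier West African winters; these values
  reproduce the observed 10/50/90 % quantiles of both series); NDVI
  positively coupled to rainfall and clamped to $[-1, 1]$.
* **Returns** (`simulate_returns`): complementary log-log hazard with
  centered-product interactions $\delta^2H\times$NAO $=-0.04$,
  $\delta^2H\times$rain $=0.004$, blackness$\times$NAO $=0.007$, an age
  effect, optional gaussian frailty (default variance 0 — the study
  offers no information on extra-covariate individual heterogeneity), and
  a baseline giving a ~30 % return rate, inside the plausible band for
  breeding-site fidelity. Centered products leave the fitted interaction
  coefficients — the quantities of interest — untouched while keeping the
  linear predictor bounded.

### The bounded-response residual construction

Planting a ring variance of 365.8 and residual variance of 314.8 on a
response confined to $[0, 100]$ is the delicate part: drawing gaussian
effects and clamping would attenuate the planted age effect by roughly
10 %, far beyond what parameter-recovery validation tolerates. Instead,
ring and residual effects are drawn from scaled beta distributions with
*exact* mean zero and the target variance, whose support is constructed
per individual and per record to respect the percentage scale (the
variance is shrunk in the rare cases where the support cannot carry it).
Conditional means are therefore exact, no clamping ever occurs, and the
mixed model recovers the planted coefficients without bias. The price is
that residual shapes become skewed, and near the extremes of the scale
strongly bimodal — a visible artificiality of the generator that does not
affect first- or second-moment recovery.

### Causal order

The intuitive generative story — "draw blackness, then place origins" —
is implemented with blackness split into a latent placement score (drawn
first, uniform) and the observed phenotype (drawn last, from the planted
regression given observed isotopes). Drawing observed blackness first and
origins from it would make the blackness model an error-in-predictor
regression — the calibration scatter in $\delta^2H_f$ would attenuate the
recovered slope by construction. The latent/observed split keeps both the
balanced-roster property and exact recovery.

### What the generator does not emulate

Real African geography and real isoscape structure (published surfaces
have nonlinear gradients and spatially varying uncertainty); phenotype
frequencies of the source population (the roster is balanced by design);
multi-year return histories (returns are single-interval); emigration
versus mortality (neither can the field data); and any isotope-melanin
physiology. Passing recovery tests therefore demonstrates that the
*models* are implemented correctly and are calibrated for data satisfying
their assumptions — not that real feathers satisfy those assumptions.

## 5. Validation design

* **Oracle equivalence.** Posterior surfaces and odds regions are checked
  cell-for-cell ($<10^{-12}$) against an independent brute-force
  implementation with explicit loops on grids up to 20×20.
* **Coverage.** 1000 simulated samples with known uniform origins: the
  odds region covers the truth at its nominal 2/3 rate within three
  binomial SEs under matched sigmas, above it at 10× inflated sigmas,
  below at 10× deflated.
* **Phenotype recovery.** 300 replicates of the default 240-record study
  (replicate seeds widely spaced): the mean recovered hydrogen slope and
  age effect sit within two Monte-Carlo SEs of the planted $-0.50$ and
  $-19.30$.
* **Return recovery.** Each hazard interaction is planted alone and
  recovered through the cloglog route with the frailty term off, matching
  the generating model. Planting all three at once would make single-pair
  recovery ill-posed: the NAO-rain coupling funnels the rain interaction
  into the NAO one (the $\delta^2H\times$NAO fit would absorb
  $-5.7 \times 0.004 \approx -0.023$). The primary check runs 200
  replicates of 7200 records; this scale was chosen by a power analysis of
  the maximum-likelihood estimator's O(1/n) small-sample inflation
  (measured at ~1 % of the coefficient at 1200 records), so that the
  estimator's own finite-sample bias sits below Monte-Carlo resolution.
  The null battery keeps type-I error at its nominal 5 %.
* **Repeatability.** Exact-repeat data give $R = 1$; 200 replicates at a
  planted intraclass correlation of 0.7 (200 individuals × 2
  observations) recover it within 0.02.

## 6. Known limitations

* ESRI ASCII grids are the raster interchange format; they require square
  cells and carry no CRS metadata (coordinates are documented as
  cell-center lon/lat degrees, row 1 northernmost).
* `align_and_mask` resamples nearest-neighbour onto the first grid —
  appropriate for cell-wise assignment, wrong for gradient-based uses.
* The Cox route's Breslow attenuation under the all-tied construction is
  intrinsic; interaction *tests* remain valid, but effect sizes from the
  battery should be read on the cloglog route when magnitudes matter.
* The bootstrap CI for repeatability is percentile-based and can be
  shorter than nominal at variance boundaries ($R$ near 0 or 1).
* The exploratory isotope-climate regressions use yearly means (n = years)
  and are labelled accordingly; they are plumbing, not inference.
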