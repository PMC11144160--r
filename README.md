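# winterscape

Where did a migratory songbird spend the winter, and did that winter decide
whether it came back? `winterscape` implements the full inference chain that
links the breeding plumage of male pied flycatchers (*Ficedula hypoleuca*)
to their African winter moult origins and to their probability of returning
to the breeding grounds, using stable isotopes measured in winter-grown
feathers. It is aimed at movement ecologists working with isoscape-based
assignment and carry-over-effect models, and it ships a synthetic-data
generator that reproduces the statistical structure of such a study so that
every stage of the chain can be exercised and validated without any field
data.

## What it computes

**Assignment to origin.** A feather's δ²H_f and δ¹³C_f values are compared
against two co-registered isoscapes: a growing-season precipitation δ²H
surface converted to feather values with the known-origin songbird
calibration

    δ²H_f = −6.77 + 1.42 · δ²H_p

and a plant δ¹³C surface shifted by the +2 ‰ diet-to-consumer
discrimination. For each raster cell the likelihood is a multivariate
normal density with diagonal covariance (σ_H, σ_C per isotope),
normalized over the unmasked grid into a posterior origin surface
P(cell | δ²H_f, δ¹³C_f). The conservative 2:1 odds ratio binarizes the
posterior: the smallest highest-probability set of cells holding ≥ 66.7 %
of the mass is coded 1 (potential origin), everything else 0. Binary maps
are summed within low (< 33 %), moderate (33–66 %) and high (> 66 %)
plumage-blackness groups.

**Phenotype models.** Within-individual repeatability (intraclass
correlation from a REML random-intercept model, parametric-bootstrap CI,
boundary-corrected likelihood-ratio test); the linear mixed model
`blackness ~ δ²H_f + δ¹³C_f + δ¹⁵N_f + age + (1 | ring)` with
Kenward-Roger small-sample inference; a two-stage residual-dispersion
check; a between-year change model on repeated individuals; and
exploratory yearly isotope-climate associations.

**Return models.** A battery of 12 mixed-effects proportional-hazards fits
(unit follow-up time, event = returned, Breslow ties, gaussian frailty on
individual): each of δ²H_f, δ¹³C_f, δ¹⁵N_f and blackness crossed with the
winter NAO index, NDVI and rainfall, keeping the predictor × environment
interaction as the quantity of interest, plus relative risk-score curves
across the predictor range at the 10/50/90 % environmental quantiles. An
equivalent discrete-time formulation (binomial mixed model with
complementary log-log link) is available as a cross-check and for
coefficient-recovery validation.

**Synthetic data.** `simulate_dataset()` generates smooth gradient-plus-
correlated-noise isoscapes with masked cells, a multi-year roster with
repeated individuals, blackness-dependent true origins, feather values with
calibration and measurement noise, NAO/NDVI/rainfall series with the
negative NAO-rain coupling, and binary returns from a complementary
log-log hazard model — all deterministic given one seed, with every planted
coefficient recoverable by the fitting functions above.

## Worked example

```r
library(winterscape)

cfg <- sim_config(seed = 11)       # the default study design, 240 records
sim <- simulate_dataset(cfg)
sim
#> winterscape_sim: 240 records, 209 individuals (31 repeated), 9 winters
#>   return rate: 0.404

# isoscape transforms and dual-isotope assignment
params   <- calibration_params()
feather  <- calibrate_h(sim$isoscapes$h, params)
consumer <- discriminate_c(sim$isoscapes$c, params)
surfaces <- align_and_mask(list(feather, consumer))
res <- assign_all(sim$samples, surfaces[[1]], surfaces[[2]])
table(res$summary$group)
#>      low moderate     high
#>       72      103       65
res$count_surfaces$high
#> count_surface [high]: n = 65 maps, cell counts 0 to 4

# blackness ~ isotopes + age mixed model
fit_blackness_lmm(sim$samples)
#> blackness ~ d2H + d13C + d15N + age + (1|id)
#>         term estimate       se statistic    df         p
#>  (Intercept)  52.7018 17.60011    2.9944 220.0 3.065e-03
#>          d2H  -0.3845  0.09263   -4.1513 232.9 4.639e-05
#>         d13C  -0.1115  0.45936   -0.2427 210.6 8.085e-01
#>         d15N  -2.4345  1.68630   -1.4437 224.5 1.502e-01
#>     ageyoung -18.7586  3.30370   -5.6781 182.1 5.300e-08
#> random effects (variance): id = 346.812, residual = 348.268

# carbon repeatability across years
repeatability(sim$samples$d13C, sim$samples$id, n_boot = 200, seed = 1)
#> repeatability R = 0.989 (95% CI [0.98, 0.99], p = 8.82e-26)

# return battery (deuterium rows shown)
bat <- run_battery(sim$returns)
bat[bat$predictor == "d2H", c("predictor", "env", "estimate", "se", "z", "p")]
#>   predictor     env estimate       se     z        p
#> 1       d2H     nao -0.02356 0.003784 -6.23 4.76e-10
#> 5       d2H    ndvi  0.46829 0.106024  4.42 1.00e-05
#> 9       d2H rain_mm  0.00484 0.000765  6.32 2.60e-10
```

Reading the output: blackness declines with feather δ²H (here
−0.38 % per ‰ on one simulated replicate of the planted −0.50; the
replicate-mean recovery is part of the test suite) and young males are
~19 % browner. Carbon is highly repeatable within individuals — birds
revisit isotopically similar habitats — while the negative δ²H × NAO and
positive δ²H × rain interactions say that birds from wetter (low-δ²H)
winter habitats return at higher rates after dry (high-NAO, low-rain)
winters, and vice versa.

The whole chain, from simulation to the battery, also runs as one call:

```r
run_all(list(simulate = list(seed = 11)), outdir = "winterscape-run")
```

which writes the isoscapes (`.asc`), all tables (CSV), risk curves and a
JSON run manifest under `winterscape-run/`.

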