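# cropsens

Global sensitivity analysis, ranking-stability statistics and evaluation
metrics for crop growth models, built around winter rapeseed
(*Brassica napus*) and the 35 cultivar/ecotype/soil coefficients of the
CROPGRO-Canola parameter set.

## What it does, for whom

Before a process-based crop model can be calibrated in a new region with
limited field data, a modeller needs to know **which** of its many input
coefficients actually drive the outputs of interest — days to anthesis
(ADAP), days to maturity (MDAP), yield (HWAM), above-ground biomass
(CWAM), maximum LAI (LAIX) — and whether that importance is stable across
sites and years. `cropsens` provides the full statistical pipeline:

- **EFAST** (extended Fourier Amplitude Sensitivity Test): search-curve
  sampling `x_j(s) = l_j + (u_j - l_j)(1/2 + arcsin(sin(ω_j s + φ_j))/π)`
  and spectral variance decomposition into first-order and total-order
  Sobol indices,

  `S_i = V_i / V(Y)`,  `S_Ti = [V(Y) − V_−i] / V(Y)`,

  with a Saltelli-style Monte-Carlo pick-freeze estimator (`sobol_mc()`)
  as an independent cross-check.
- **Top-down concordance**: savage scores `S_i = Σ_{k=r_i..n} 1/k` and the
  top-down concordance coefficient
  `TDCC = [Σ_i (Σ_j S_ij)² − m²n] / [m²(n − Σ_i 1/i)]`, tested against
  `χ²_{n−1}` via `T = m(n−1)·TDCC`.
- **Evaluation statistics**: RMSE, nRMSE (% of observed mean), mean error
  (simulated − observed), relative ME, Willmott's index of agreement `d`,
  days-after-planting conversion, and a grid-search calibration objective.
- **Weather tools**: FAO-56 solar geometry, the Angstrom–Prescott equation
  `Rs = (a + b·n/N)·Ra` (a = 0.2, b = 0.5), a seeded generator that turns
  seasonal summaries (mean temperature, rain total, radiation total) into
  daily series, and CSV / DSSAT-dialect weather I/O.
- **A surrogate rapeseed model** (`simulate_season()`): a deterministic
  daily phenology–canopy–water–biomass model exposing all 35 coefficients
  with a designed causal structure, so the pipeline runs without an
  external simulator. Packaged fixtures carry the parameter ranges, site
  and management tables, a layered soil profile and five seasons of
  observed phenology/yield/biomass.

## Worked example

```r
library(cropsens)

# a Wuhan-like season from seasonal summary targets
w <- synth_weather(latitude = 30.47, start = "2018-09-28", days = 240,
                   tmean_c = 17.4, rain_mm = 530.6, srad_mj = 2162.4, seed = 3)

# EFAST over all 35 parameters of the surrogate (4515 model runs)
fit <- efast(canola_model(w), canola_parameters(), Ns = 129, seed = 1)
fit
#> EFAST sensitivity analysis: 35 factors, 5 output(s), 4515 model runs
#>   ADAP: top factors EM-FL (STi=0.700), OPTBI (STi=0.276), SLOBI (STi=0.100)
#>   MDAP: top factors EM-FL (STi=0.640), OPTBI (STi=0.201), CSDL (STi=0.140)
#>   HWAM: top factors EM-FL (STi=0.644), OPTBI (STi=0.380), TRIFL (STi=0.284)
#>   CWAM: top factors OPTBI (STi=0.541), EM-FL (STi=0.510), TRIFL (STi=0.380)
#>   LAIX: top factors TRIFL (STi=0.546), SIZLF (STi=0.252), RHGHT (STi=0.152)
```

Flowering time (ADAP) is dominated by the emergence-to-flowering duration
EM-FL and by the cold-response coefficients OPTBI/SLOBI; leaf area and
biomass are led by the main-stem leaf appearance rate TRIFL — the
qualitative pattern a modeller would use to pick calibration targets.

```r
# ranking stability across replicates (here: two identical replicates)
tdcc(rank_sensitivity(list(fit, fit), "ADAP"))
#> Top-down concordance: TDCC = 1.000 over 2 replicates of 35 factors
#>   T = 68.00 ~ chi-squared(34), p = 0.000474

# evaluation statistics: observed anthesis at 150 and 149 days after
# planting, simulated 3 and 2 days late
fit_statistics(c(150, 149), c(153, 151))
#> N = 2 | RMSE = 2.55 | nRMSE = 1.71% | ME = 2.50 | rME = 1.67% | d = 0.35
```

The full multi-site, multi-year design (weather synthesis → EFAST →
ranking → temporal/spatial/pooled TDCC) runs through
`run_study(study_config(...))`; see the vignette
`vignettes/crop-model-sensitivity.Rmd` for the model equations, design
choices and limitations.

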