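# roadfusion

Hybrid near-road air-quality data fusion, RAMP bias correction, and
exposure-equity analysis at census-block resolution.

## The problem

Coarse chemical-transport models (CTMs) report 12-km cell averages and
smear out the sharp near-road gradients of traffic-related pollutants —
PM2.5 and NO2 decay to background within ~150–200 m of a major road. The
people living inside that corridor (disproportionately Minority
populations) have their exposure misclassified by grid-scale fields.
Dispersion models resolve the gradient but miss secondary pollutants, and
both model families carry spatially varying, concentration-dependent bias.

`roadfusion` is for exposure scientists and health-impact analysts who want
the full chain — fusion, bias correction, mortality burden, equity metrics
— as tested, reusable functions, exercisable end-to-end on a built-in
synthetic world.

## What it computes

**Hybrid fusion** at a block centroid $p$ in coarse cell $G(p)$:

$$\mathrm{HYB}(p) = \big[(C_{tot} - R_{gavg})\ \text{interp.}\big] + R_{cbc}(p),$$

the coarse total minus the cell-averaged on-road field (removing double
counting), bilinearly interpolated to the centroid, plus the fine-scale
on-road estimate; a negative interpolated remainder is zeroed out and the
on-road term used alone.

**RAMP correction** (Regionalized Air quality Model Performance): per cell,
daily (model, observation) pairs from the nearest monitors are stratified
into 10 decile bins of predicted value; the mean observed value per bin
defines a piecewise-linear calibration curve, safeguarded centre-out —
anchored at the grand observed mean $\lambda_{1,M}$ — to be monotone, so
correction preserves the ordering of estimates within a cell.

**Health impact**: attributable deaths
$\mathrm{Pop} \times f_{25+} \times r \times (1 - e^{-\beta C})$ with
$\beta = \ln(\mathrm{RR})/10$ (PM2.5 RR 1.0129 [1.0109, 1.0150], NO2 HR
1.04 [1.02, 1.06] per 10 µg/m³), CI bounds by excess-risk slope-ratio
scaling, county/distance aggregation and two-model excess/net accounting.

**Exposure inequity**: the EIR — Minority over White population-weighted
exposure — nationally, per county/tract/block group (distribution summary),
and in 10-m distance-from-road bins.

## Worked example

```r
library(roadfusion)

# 4x4 grid of 12-km cells, 12 roads, 40 monitors, 5,000 blocks, 365 days
res <- run_pipeline(study_config(), seed = 1)

res$evaluation[, c("model", "rmse", "r2_pearson")]
#>      model  rmse r2_pearson
#> 1     cmaq 4.413      0.569
#> 2      hyb 4.666      0.784
#> 3 ramp_hyb 0.495      0.871

res$equity$national$eir
#> [1] 1.021

res$health$cmaq_vs_ramp$summary
#>   quantity central lower upper
#> 1 excess_a   8.225 6.949 9.563
#> 2 excess_b   0.000 0.000 0.000
#> 3      net   8.225 6.949 9.563
```

Reading the output: at the 40 monitors, fusion lifts R² from 0.57 to 0.78
(it restores the near-road gradient the coarse field averages away), and
the RAMP correction drops RMSE from 4.7 to 0.5 while lifting R² to 0.87
(it removes the coarse model's regionally varying nonlinear bias). The
synthetic world's biased coarse model overestimates concentrations, so it
attributes 8.2 more premature deaths than the corrected field — the
excess/net accounting splits such differences by sign across counties. The
national EIR of 1.02 reflects the generator's near-road Minority
enrichment (`theta = 1`); with `theta = 0` it is 1 within sampling noise.

Write all stage tables to disk with `run_pipeline(cfg, seed, out_dir =
"out")`, or use the thin CLI in `inst/scripts/roadfusion.R`
(`simulate`, `run-all`, `config --defaults`).

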