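# wheatAGB

Crop height and above-ground biomass (AGB) estimation for winter wheat
from UAV-derived data: 3-D canopy point clouds on the structural side,
five-band (B, G, R, red-edge, NIR) reflectance on the spectral side.

Plot-scale AGB is the variable agronomists need for fertilizer and yield
decisions, but spectral predictors saturate as the canopy closes: indices
stop responding at high biomass, and models systematically under-predict
the heaviest plots. This package implements the workflow that diagnoses
and mitigates that problem by fusing canopy *structure* with canopy
*spectra*:

* **Accumulated incremental height (AIH).** For a height-sorted normalized
  point cloud, AIH(X) is the height at which the running sum of point
  heights reaches X% of the total summed height — a mass-weighted
  percentile. Crop height is estimated as `AIH(95) − AIH(1)` (canopy top
  minus ground baseline). The conventional alternative, the **CHM-mean**
  method, averages the canopy height model CHM = DSM − DEM over 0.5 m
  cells (DSM/DEM rasterized by ordinary kriging or IDW).
* **18 vegetation indices** (NDVI, OSAVI, EVI2, kNDVI, red-edge indices,
  RGB indices, …) computed per pixel or per plot with zonal aggregation.
* **Random-forest feature screening**: impurity importances normalized to
  percentages; features under 1% are dropped (training split only).
* **A five-algorithm benchmark** — random forest (RFR), XGBoost, gradient
  boosted trees (GBRT), support vector regression (SVR), ridge regression
  (RR) — over three feature sets (AIH-only, VIs-only, VIs+AIH) per growth
  stage, with grid-searched hyperparameters under 5-fold CV, a 7:3
  train/test split, and test-set R², RMSE, nRMSE = RMSE/x̄·100 plus a
  saturation diagnostic (mean signed residual over the top 20% of measured
  AGB).

Field campaigns of this kind are rarely shareable, so the package includes
a **synthetic-field generator** — 6 nitrogen treatments × 30 plots of
1.4 m × 4 m sampled at jointing, heading and grain filling, with
stage-calibrated trait distributions, canopy + bare-ground point clouds
whose tops encode the true height, and reflectances with a saturating
response to AGB — so the whole pipeline runs against known ground truth.
See `vignettes/wheatagb-methods.Rmd` for the models, parameter defaults
and design choices.

## Worked example

```r
library(wheatAGB)

cfg    <- field_config(seed = 1)                  # study-default experiment
field  <- simulate_field(cfg, stages = "filling") # 180 plots + point clouds
heights <- field_heights(field)                   # AIH features, CH, CHM mean

d <- merge(heights, field$truth, by = c("plot_id", "stage"))
sprintf("AIH 95%%: RMSE %.1f cm, bias %+.1f cm",
        100 * sqrt(mean((d$CH - d$true_height)^2)),
        100 * mean(d$CH - d$true_height))
#> "AIH 95%: RMSE 0.9 cm, bias -0.9 cm"
sprintf("CHM mean: RMSE %.1f cm, bias %+.1f cm",
        100 * sqrt(mean((d$chm_mean - d$true_height)^2)),
        100 * mean(d$chm_mean - d$true_height))
#> "CHM mean: RMSE 3.3 cm, bias +3.3 cm"

vi       <- vi_table(field$reflectance)           # the 18 indices per plot
features <- merge(heights[, !(names(heights) %in% "chm_mean")], vi,
                  by = c("plot_id", "stage"))
bench <- agb_benchmark(features, field$truth,
                       models = c("RFR", "RR"), seed = 1)
print(bench)
#> AGB estimation benchmark (held-out test metrics)
#>
#> == stage: filling ==
#>  model R2 AIH R2 VIs R2 VIs+AIH
#>    RFR  0.314  0.625      0.733
#>     RR  0.384  0.734      0.809
```

The numbers tell the saturation story: at grain filling, spectral indices
alone reach only R² ≈ 0.6–0.7 on held-out plots and under-predict the
heaviest ones (`bench$saturation` is positive), structural AIH features
alone are weaker still, and the combination recovers the loss. The AIH
height estimator tracks the true canopy height to about a centimetre,
while the cell-max/cell-min construction of the CHM biases the mean method
a few centimetres high.

The same workflow runs from one configuration object (or YAML file):

```r
report <- run_pipeline(run_config(seed = 42, out_dir = "run"))
```

which writes every intermediate table (plots, truth, reflectance, heights,
indices, features, benchmark, height-method comparison) as deterministic
CSV plus a JSON run report. A thin command-line wrapper is installed at
`inst/scripts/agb-pipeline.R`.

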