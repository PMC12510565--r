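# hazecast

Regional PM2.5 forecasting and pollution-event classification for
multi-city agglomerations.

Haze pollution in large urban agglomerations is a *regional*
phenomenon: under stagnant winter weather, a polluted air mass spans
several adjacent prefecture-level cities at once, fed by local
emissions and inter-city transport. `hazecast` provides, in one R
package:

* **Multi-city hourly panels** as `HourlyPanel` objects (a
  `SummarizedExperiment`: rows = cities, columns = hours, one assay
  per variable), with CSV ingestion (long and wide dialects), gap
  imputation (adjacent-mean for short pollutant gaps, cubic splines
  otherwise), per-series min-max normalization fitted on the training
  period, sliding-window supervision and chronological 7:1:2
  splitting.
* **A three-stream multi-output neural forecaster.** For a target
  city, an LSTM consumes its PM2.5 history `Xh` (temporal
  dependencies), a feed-forward network consumes its exogenous
  variables `Xe` (co-pollutants SO2/NO2/CO/PM10/O3 and surface
  meteorology), and a multi-scale convolutional pyramid consumes the
  regional all-city PM2.5 matrix `Xt` (cities as channels, convolution
  along time; each level pairs a direct branch with a pooled parallel
  branch, `MF^k = X^k + X^k_norm`). The streams are linearly projected,
  fused, and mapped through a sigmoid to one forecast per city. The
  loss is the multi-output mean squared error
  `MOLF = (NM)^-1 Σ_i Σ_j (y_ij - ŷ_ij)²`, minimised by minibatch
  Adam. Backpropagation (through time, convolutions and pooling) is
  analytic, implemented with compiled RcppArmadillo kernels, and
  verified against finite differences in the test suite.
* **Evaluation**: R², MAE and RMSE in µg/m³ (per city and pooled
  regional), the persistence baseline, a kernel-size x window-length
  tuning grid, and ten-fold cross-validation (random or blocked).
* **Regional pollution events**: daily 24-h city means graded on the
  national AQI PM2.5 breakpoints (75/115/150/250 µg/m³), a
  contiguity gate requiring a connected cluster of ≥ 5 polluted cities
  on a shared-border adjacency graph, and a mild/moderate/severe
  decision tree with annual and seasonal tallies.
* **A seeded synthetic region generator** (`simulateRegion`,
  `makeFixture16City`): 16 Chengdu-Chongqing-like cities with
  diurnal/seasonal cycles, AR(1) anomalies, lagged inter-city
  transport, covariate coupling, right-skewed innovations, observation
  noise, injected winter episodes and missingness — so every test and
  demonstration runs without downloading anything.

## Worked example

```r
library(hazecast)

panel <- makeFixture16City(nDays = 120, seed = 2023)   # 16 cities, hourly
panel
#> HourlyPanel: 16 cities x 2880 hours x 11 variables
#>   time: 2023-01-01 .. 2023-04-30 23:00:00
#>   variables: PM25, SO2, NO2, CO, PM10, O3, temp, rh, pressure, rain, wind
#>   missing cells: 0

## regional pollution days
events <- classifyRegion(panel)
countEvents(events, 2023)
#>                         Class Year Spring Summer Autumn Winter
#> 1     Mild regional pollution    4      0      0      0      4
#> 2 Moderate regional pollution    1      0      0      0      1
#> 3   Severe regional pollution    2      0      0      0      2

## one-hour-ahead forecasting for all 16 cities at once
panelN  <- applyMinMax(panel, scaler <- fitMinMax(panel))
ws      <- makeWindows(panelN, targetCity = "Chengdu", W = 24)
sp      <- chronologicalSplit(ws)
mc      <- modelConfig(W = 24, M = 16, E = length(ws@exoVars),
                       lstmHidden = 32, dnnLayers = c(32, 32),
                       channels = 16, fusionDim = 32)
fit     <- trainModel(initParams(mc), mc, sp$train, sp$val,
                      trainConfig(learningRate = 3e-3, batchSize = 30,
                                  maxEpochs = 40, lrDecay = 0.97,
                                  averageFrom = 0.3, inputNoiseSd = 0.02))
pred    <- predictConcentrations(fit$params, mc, sp$test, scaler)
obs     <- invertMinMax(sp$test@Y, scaler, sp$test@cities)
round(evaluateForecast(as.vector(obs), as.vector(pred)), 3)
#>     r2    mae   rmse
#>  0.488  8.792 11.310
round(evaluateForecast(as.vector(obs),
                       as.vector(persistenceForecast(sp$test, scaler))), 3)
#>     r2    mae   rmse
#>  0.700  6.577  8.657
```

The event table says the simulated winter contained four mild, one
moderate and two severe regional pollution days — days on which at
least five *connected* cities exceeded the 24-h PM2.5 grade required
by each class. The forecast metrics are reported in µg/m³ after
inverting the normalization. On this deliberately short 120-day panel
the model trains on winter and is tested on spring — a regime it never
saw — so the naive last-value (persistence) baseline still wins;
one-hour-ahead PM2.5 is dominated by its own persistence, and beating
it requires a training period that covers the test regime. The
vignette discusses this at length, and `scripts/acceptance.R` runs the
full 400-day study (three seeds, persistence and pyramid-ablated
comparators).

A thin command-line front end over the same functions lives at
`inst/cli/hazecast.R` (subcommands `simulate`, `train`, `predict`,
`evaluate`, `tune`, `classify`, `report`).

See the methods vignette
(`vignettes/regional-pm25-forecasting.Rmd`) for the model equations,
the event-definition reading, the generator design and the package's
numerical choices.

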