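# pangotherm

Heterothermy analysis of free-ranging Temminck's pangolin (*Smutsia
temminckii*) body temperature in a semi-arid environment.

Pangolins are myrmecophagous: ants supply their energy and most of their
water. This package implements the complete analysis chain for a biologging
study of how food scarcity reshapes their thermoregulation: ingesting 5-min
core body-temperature logger records (water-bath calibration over 26–42 °C,
±1 min/month clock-drift correction), computing 24-h summaries (minimum,
maximum, mean, amplitude = max − min over midnight-to-midnight windows),
inferring burrow emergence and return from abrupt body-temperature *notches*
(≥ 0.5 °C in < 1 h) merged with camera-trap observations, and fitting the
statistical core:

- **Piecewise (linear-spline) random-intercept mixed models** for each 24-h
  metric, with photoperiod, monthly prey abundance split at a breakpoint
  (slopes below/above a knot *k* via `b1 = min(x, k)`, `b2 = max(x − k, 0)`),
  the matching black-globe temperature metric, and — for the 24-h maximum
  only — the time of burrow emergence restricted to 04:00–23:55;
- **AIC breakpoint search** over integer knots 0–18 ants/trap (all fits by
  maximum likelihood; lowest AIC wins, ties to the smallest knot);
- **cluster-robust (sandwich) standard errors** by animal where
  heteroskedasticity is detected, plus Cook's D / VIF / normality
  diagnostics;
- a **negative binomial season × year model** for pitfall-trap ant counts
  (30 transects × 10 tubes) with transect-level clustering.

The field data are not publicly deposited, so the package ships a calibrated
synthetic-data generator (`generator_params()`, `simulate_dataset()`) whose
defaults reproduce the study system's reported structure — the published
coefficient tables as generating models, prey means of 11.4 ants/trap in the dry
year and 8.2 in winter, ~92 % of body-temperature samples inside 34–36 °C, a
+0.35 °C year contrast in the 24-h minimum and a 0.80 °C winter–summer
amplitude contrast. Every analysis here runs end-to-end on that generator.

## Worked example

Simulate two weeks of data, summarise, detect activity, and fit the 24-h
minimum model at its breakpoint:

```r
library(pangotherm)

ds  <- simulate_dataset(generator_params(), seed = 1,
                        start = "2016-06-01", end = "2016-06-14")
daily <- do.call(rbind, lapply(ds$traces, daily_tb_summary))
head(daily[, c("animal_id", "date", "tb_min", "tb_max", "tb_amplitude")], 3)
#>   animal_id       date   tb_min   tb_max tb_amplitude
#> 1       P01 2016-06-01 32.32708 35.28315     2.956072
#> 2       P01 2016-06-02 32.69121 36.26461     3.573401
#> 3       P01 2016-06-03 32.33049 35.97049     3.640001
```

Winter days under scarce prey: nightly minima near 32.3–32.7 °C
(heterothermy), maxima near 35–36 °C, daily amplitudes around 3 °C —
against a summer norm of tight 34–36 °C regulation. The full two-year pipeline
(`run_pipeline(pipeline_config(mode = "simulate", seed = 1))`) fits all
three models; its recovery of the 24-h minimum generating model over 20
replicate datasets looks like this (`recovery_study(..., "tb_min")`):

```
         term generating mean_estimate        mc_se coverage
  Photoperiod       0.09   0.088700543 0.0014419315     1.00
   prey_below       0.10   0.099286793 0.0006919575     0.85
   prey_above       0.00   0.000132961 0.0001328395     0.95
        globe       0.02   0.020247372 0.0002120135     1.00
modal selected knot: 9 (recovered in 95% of replicates)
```

i.e. each coefficient is recovered within two Monte-Carlo standard errors
of its generating value, and the AIC search finds the 9 ants/trap breakpoint
below which prey abundance drags the nightly minimum down by 0.10 °C per
ant/trap.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (`01_simulate.R` → `05_recovery.R`), writing their tables under
`results/`.

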