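---
title: "Modelling heterothermy in free-ranging pangolins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heterothermy in free-ranging pangolins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Temminck's pangolins (*Smutsia temminckii*) in the semi-arid Kalahari are
myrmecophagous: ants supply both their energy and most of their water. When
prey is scarce the animals relax the precision of body-temperature
regulation — 24-h minima fall, activity shifts into daylight, and the
amplitude of the daily body-temperature rhythm grows. `pangotherm`
implements the full analysis chain for this kind of biologging study:

1. **Logger ingest** — water-bath calibration (26–42 °C) mapped as an
   ordinary least-squares line predicting bath temperature from the logger
   reading, and clock-drift correction (loggers drift about ±1 min/month)
   apportioned linearly over the deployment and snapped back to the 5-min
   grid.
2. **24-h summaries** — minimum, maximum, arithmetic mean and amplitude
   (max − min) per midnight-to-midnight day; black-globe temperature
   summaries and photoperiod; seasonal calendar with summer = Dec–Feb,
   autumn = Mar–May, winter = Jun–Aug, spring = Sep–Oct, November excluded
   from spring because each study year begins in November.
3. **Activity** — burrow emergence and return inferred from abrupt
   body-temperature *notches* (≥ 0.5 °C in under 1 h), reconciled with
   camera-trap observations, with the emergence time restricted to
   04:00–23:55 so a circular quantity can enter a linear model.
4. **Piecewise mixed models** — for each of the three responses (24-h
   minimum, maximum, amplitude), a random-intercept linear mixed model with
   photoperiod, a linear-spline pair in monthly prey abundance, the matching
   globe metric, and (for the maximum only) emergence time; the spline knot
   is chosen by refitting at every integer breakpoint from 0 to 18 ants/trap
   and taking the lowest AIC.
5. **Prey model** — a negative binomial season × year regression of
   pitfall-trap ant counts with an offset for the ten tubes per transect.

Because the field data are not deposited, the package ships a calibrated
synthetic-data generator whose defaults *are* the study conditions: all
testing and the acceptance analyses run on data it produces.

## The generating models

The three body-temperature responses are generated from the study's reported
coefficient tables. Writing $b_1(x;k)=\min(x,k)$ and $b_2(x;k)=\max(x-k,0)$
for the linear-spline pair in monthly prey abundance $x$ (ants/trap):

$$T_{\min} = 31.30 + 0.09\,P + 0.10\,b_1(x;9) + 0\,b_2(x;9)
  + 0.02\,G_{\min} + u_i + \varepsilon$$

$$T_{\max} = 36.18 + 0.05\,P - 0.03\,b_1(x;10) + 0\,b_2(x;10)
  + 0.03\,G_{\max} - 0.11\,E + u_i + \varepsilon$$

$$A = 5.29 - 0.20\,P - 0.11\,b_1(x;10) + 0\,b_2(x;10)
  + 0\,G_{\mathrm{amp}} + u_i + \varepsilon$$

with $P$ photoperiod (h), $G$ the matching 24-h globe metric (°C), $E$ the
emergence time (decimal hours), $u_i$ an animal random intercept and
$\varepsilon$ residual noise. No variance components are reported anywhere,
so the defaults (random-intercept SDs 0.15/0.20/0.20 °C, residual SDs
0.22/0.18/0.40 °C for min/max/amplitude) are package configuration, chosen
to give the within- and between-animal spread a field biologist would call
realistic for core-temperature biologging, and are stated in
`generator_params()` rather than presented as study values.

### Joint versus marginal generation

Only the three marginal models are specified; their joint law is not. The
joint daily table therefore generates the minimum and maximum from their own
models and *reconciles*: the maximum is kept at least 0.2 °C above the
minimum, amplitude is defined as max − min exactly (so the amplitude
identity holds on every row), and the mean is placed at the resting fraction
of the range, clipped into [min, max]. When a parameter-recovery study
targets the amplitude model itself, the amplitude response is generated
directly from its own marginal model (`simulate_daily_response()`); the
reconciled table is used for everything trace-level and descriptive.

### Climate, prey and emergence covariates

Globe temperature is a double sinusoid — an annual cycle (mean 20.5 °C,
semi-amplitude 8 °C, peaking mid-January) plus a diurnal cycle
(semi-amplitude 9.5 °C, peaking at 14:00) — with additive Gaussian noise
(SD 0.8 °C). Study year 2 applies the configured offsets exactly: +2.1 °C
to the 24-h mean and −4.0 °C to the 24-h minimum, realised by a base shift
plus a deepened nocturnal trough so both offsets hold in expectation
simultaneously. Photoperiod comes from standard solar geometry at the
site's latitude (27.2° S).

Monthly prey means are the generator's central calibration. The printed
descriptive values over-determine the season × year allocation (the year-1
grand mean, the winter mean, the 0.35 °C year contrast of the 24-h minimum
through the capped spline term, the 0.80 °C summer–winter amplitude
contrast, *and* the summer/autumn/spring season means cannot all hold at
once), so the defaults satisfy exactly the quantities the package verifies —
year-1 mean 11.4 ants/trap, winter mean 8.2, and the two contrasts — and let
the remaining season means float. Year 1 is the dry year: prey collapses
from March through September (0.4–4 ants/trap) and recovers sharply in
October; year 2 never falls below ~9.5, with several months placed at
9.5–16 ants/trap so that data straddle the 9 and 10 ants/trap breakpoints —
without support near the knot, no AIC search could identify it. A
consequence worth knowing: month-to-month spread within a season is larger
than the study's printed standard errors suggest; the generator trades that
fidelity for identifiable breakpoints and correct contrasts.

Transect totals are negative binomial (size 8) around ten times the monthly
mean; the per-trap value is the transect total divided by ten tubes, exactly
as the field counts are reduced. Emergence times are uniform in
season-specific windows: summer 19.6 ± 1.0 h, autumn 19.0 ± 1.0,
spring 19.3 ± 1.0, and winter 16.93 ± 1.9 — a daylight window reflecting the
observed winter shift to diurnal foraging. The winter mean is the one free
lever that closes the summer–winter amplitude contrast at 0.80 °C given the
fixed coefficients, photoperiod and globe seasonality; it was set by that
closed-form budget, not by trial against tests.

### Traces

Each day's 288-sample trace realises the daily summary row: an active
plateau 0.4 °C below the daily maximum, a fast descent (3.2 °C/h) to the
daily minimum merged with the burrow-return notch, a slow rewarming
(0.48 °C/h) to a resting plateau at 66 % of the daily range, and a fast
emergence ramp up to the maximum. Two rates partition the dynamics by
design: *event* transitions run well above the 0.5 °C-per-hour-equivalent
detection rule and merge into single detector events, while every other
drift stays strictly below it (0.48 °C/h over any 55-min span is 0.44 °C,
with trace noise at SD 0.005 °C far too small to bridge the gap). On
noise-free traces the detector therefore attains sensitivity 1 with zero
false positives *by construction*. Transitions that would fall below the
0.5 °C threshold (small-amplitude days) are run at the slow rate instead and
emit no true event — mirroring the field situation where no conspicuous
notch means no estimated time. Day boundaries stay continuous: each day
settles toward the next day's feasible start level at the slow rate, so
midnight never concentrates a detectable step.

A deliberate trade-off: a strict "quiescent everywhere outside events"
trace (range < 0.25 °C per 2 h, i.e. < 0.125 °C/h) cannot coexist with the
observed ~92 % occupancy of the 34–36 °C band once the mean daily minimum
sits near 33.3 °C — at that drift rate the morning dip alone would keep the
animal below 34 °C for most of the day. The package guarantees quiescence
where the classifier needs it (flat plateaus flanking the events) and bounds
all other drift below the detection rule, which preserves every detector
property while matching the printed band occupancy. The trace-shape
parameters (rates, plateau offsets, resting fraction) were calibrated once
against that 92 % figure and frozen.

## Event detection and classification

`detect_events()` applies the notch rule literally: closed inequality on the
magnitude (≥ 0.5 °C), strict on the window (< 60 min), both directions.
Overlapping same-direction candidates merge into one event timed at the
start of the steepest single 5-min change (earliest on ties). A fast
monotone ramp — however large — therefore yields exactly one event, which is
how a 6.8 °C rise over 2–3 h is handled.

`classify_events()` uses quiescence context, never the notch sign, because
leaving the burrow can warm the animal by day or cool it by night. An
emergence must be preceded (within a 4-h grace) by ≥ 2 h of quiescence
(range < 0.25 °C) *sitting in the lower part of the trailing 24-h range* —
the rest phase of a heterotherm is its low state; a return must be followed
by such a window. Labels alternate along the series. Days whose rewarming
from a deep minimum takes longer than the grace legitimately lose their
return label, which is consistent with returns being the scarcer
observation in this kind of data. Reconciliation gives cameras precedence,
fills camera-less days with inferred times, and flags disagreements beyond
60 min.

## Model fitting choices

* **Maximum likelihood, not REML**, for every fit in a knot search — AIC
  comparisons across knots change the fixed-effect design, and the final
  reported fit is refitted at the chosen knot under the same criterion so
  the table is internally consistent.
* **Knot grid**: integers 0–18 ants/trap; ties resolve to the smallest
  knot; a knot whose fit fails is recorded and excluded from the argmin.
* **Confidence intervals** are the normal approximation
  (estimate ± 1.96 SE), matching the symmetric intervals such tables
  conventionally print.
* **Robust standard errors** are cluster-robust by animal (CR1, closed-form
  inverse of the compound-symmetry block covariance), applied when a
  Breusch–Pagan-type test flags heteroskedasticity. Whether the original
  analysis clustered its sandwich errors is unknowable from the tables; the
  repeated-measures unit is the defensible default, and
  `robust_se(fit, cluster = "observation")` provides the plain
  heteroskedasticity-consistent flavour.
* **The NB prey model** defaults to `MASS::glm.nb` on transect totals with a
  log(tubes) offset and transect-clustered sandwich errors; a true
  random-intercept NB mixed model (`lme4::glmer.nb`) is the alternative
  backend. At this design's balance both target the same fixed effects; the
  default is much faster and never fails to converge on boundary cases.
* **Diagnostics** (Cook's D > 1, VIF > 5, Breusch–Pagan, residual
  normality) are computed on the whitened marginal model; the VIF uses the
  *intended* design from the model frame, so a covariate the fitter silently
  dropped as aliased still shows up as infinite VIF rather than vanishing.
* The amplitude model retains the globe-amplitude term with its near-zero
  generating coefficient rather than letting selection remove it, matching
  the reported table layout.

## What the recovery studies show — and what they do not

`recovery_study()` re-simulates climate, prey surveys and emergence times
per replicate, so recovered coefficients face realistic covariate sampling
noise. Across 20 replicates at the default size (7 animals × 730 days) the
mean of each recovered coefficient sits within two Monte-Carlo standard
errors of its generating value, and the modal selected knot equals the
generating knot for all three models (the 24-h minimum model recovers knot 9
in ≥ 80 % of replicates; the maximum model's prey effect is ten times
smaller, so its knot selection is correct modally but noisier — exactly the
behaviour one should expect of AIC on a weak breakpoint).

Confidence-interval coverage is assessed at the generating knot
(`search = FALSE`): conditioning on a data-driven knot is post-selection
inference, and the resulting undercoverage of the prey slopes is a known
property of the procedure, not an implementation defect.

Because prey enters as one monthly value shared by all animals, the
effective sample size for prey terms is closer to the number of months (24)
than the number of animal-days (~5100); model-based SEs for those terms are
accordingly optimistic in both the original design and this re-creation.

The generator emulates: seasonal and diurnal climate structure, year
contrasts entering through capped prey and globe minima, NB-overdispersed
prey counts, notch-marked traces, camera thinning and jitter. It does not
emulate: serial autocorrelation of daily residuals, within-month prey
drift, multi-exit days, logger gaps or failures, or behavioural
thermoregulation feedbacks. Green tests therefore certify the pipeline's
correctness and calibration on this structure, not the biology of any real
animal.

## Problem sizes and runtimes

The studies run at the sizes the analyses describe: the trace-level
dataset is 7 animals × 730 days × 288 samples (~1.5 M points, generated in
~20 s); each recovery study is 20 replicates × 19 knots × one mixed fit on
~5100 rows (~35 s per response). The acceptance script completes in about
two minutes on one CPU.
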