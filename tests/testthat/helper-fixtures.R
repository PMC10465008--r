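# shared fixture builders; everything is generated in code at test time

# a tb_series on the regular 5-min grid from a numeric vector
make_series <- function(values, start = "2016-06-01 00:00:00",
                        animal_id = "T01", calibrated = TRUE,
                        corrected = TRUE) {
  ts <- as.POSIXct(start, tz = "UTC") + seq_along(values) * 300 - 300
  tb_series(animal_id, ts, values, calibration_applied = calibrated,
            drift_corrected = corrected)
}

# flat baseline with one linear ramp of `delta` degC over `dur_min` minutes
ramp_series <- function(delta, dur_min, baseline = 34, pre_h = 6, post_h = 6,
                        start = "2016-06-01 00:00:00") {
  n_pre <- pre_h * 12
  n_ramp <- dur_min / 5
  n_post <- post_h * 12
  v <- c(rep(baseline, n_pre),
         baseline + delta * seq_len(n_ramp) / n_ramp,
         rep(baseline + delta, n_post))
  make_series(v, start = start)
}

# brute-force oracle for the notch rule: does any pair of samples violate
# |dT| >= threshold within strictly less than `window` minutes?
brute_notch <- function(series, threshold = 0.5, window = 60) {
  df <- series$samples
  n <- nrow(df)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dt <- as.numeric(difftime(df$timestamp[j], df$timestamp[i],
                                units = "mins"))
      if (dt >= window) break
      if (abs(df$tb_c[j] - df$tb_c[i]) >= threshold) hits <- hits + 1L
    }
  }
  hits
}

# small fast generator configuration for unit tests
tiny_params <- function(...) generator_params(n_animals = 3, ...)

# direct piecewise evaluation used as the spline-basis oracle
piecewise_eval <- function(x, knot, b_lo, b_hi, intercept = 0) {
  ifelse(x <= knot, intercept + b_lo * x,
         intercept + b_lo * knot + b_hi * (x - knot))
}
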