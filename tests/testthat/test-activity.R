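test_that("the notch rule is closed on magnitude and strict on the window", {
  # 0.6 degC over 40 min qualifies exactly once
  s1 <- ramp_series(0.6, 40)
  ev1 <- detect_events(s1)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$direction, 1)
  expect_gte(abs(ev1$delta_tb), 0.5)

  # 0.4 degC over 30 min stays below threshold
  expect_equal(nrow(detect_events(ramp_series(0.4, 30))), 0)

  # 0.5 degC over exactly 60 min fails the strict window
  s3 <- ramp_series(0.5, 60)
  expect_equal(nrow(detect_events(s3)), 0)
  expect_equal(brute_notch(s3), 0)
  # ... but the same change over 55 min qualifies (and the oracle agrees)
  s4 <- ramp_series(0.5, 55)
  expect_equal(nrow(detect_events(s4)), 1)
  expect_gt(brute_notch(s4), 0)

  # falls are detected symmetrically
  expect_equal(detect_events(ramp_series(-0.7, 30))$direction, -1)
})

test_that("the detector is invariant to adding a constant to the trace", {
  s <- ramp_series(0.8, 35)
  shifted <- make_series(s$samples$tb_c + 5)
  a <- detect_events(s); b <- detect_events(shifted)
  expect_equal(a$timestamp, b$timestamp)
  expect_equal(a$delta_tb, b$delta_tb)
})

test_that("classification labels emergence and return from quiescence context", {
  # low rest plateau, rise at hour 8, high active plateau, fall at hour 16
  v <- c(rep(34.0, 8 * 12),
         34.0 + 0.8 * seq_len(6) / 6,
         rep(34.8, 8 * 12 - 6),
         34.8 - 0.8 * seq_len(6) / 6,
         rep(34.0, 8 * 12 - 6))
  s <- make_series(v)
  cand <- detect_events(s)
  expect_equal(nrow(cand), 2)
  cls <- classify_events(cand, s)
  expect_equal(cls$kind, c("emergence", "return"))

  # single notch with quiescence on both sides is an emergence only
  s2 <- ramp_series(0.8, 30)
  cls2 <- classify_events(detect_events(s2), s2)
  expect_equal(cls2$kind, "emergence")

  # no quiescence anywhere: nothing is labelled
  set.seed(42)
  noisy <- make_series(34 + cumsum(stats::rnorm(288, 0, 0.12)))
  cls3 <- classify_events(detect_events(noisy), noisy)
  expect_equal(nrow(cls3), 0)
})

test_that("event counts never exceed candidate counts", {
  p <- tiny_params()
  ds <- simulate_dataset(p, seed = 3, start = "2016-06-01", end = "2016-06-21")
  for (a in names(ds$traces)) {
    cand <- detect_events(ds$traces[[a]])
    cls <- classify_events(cand, ds$traces[[a]])
    expect_lte(nrow(cls), nrow(cand))
  }
})

test_that("reconciliation gives cameras precedence and fills gaps", {
  mk <- function(day, hour, kind, src = NULL) {
    data.frame(animal_id = "P01",
               timestamp = as.POSIXct(sprintf("2016-06-%02d %02d:00:00", day,
                                              hour), tz = "UTC"),
               kind = kind, source = src %||% "tb_inferred")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  cam <- mk(1, 19, "emergence", "camera")
  inf <- rbind(mk(1, 19, "emergence"), mk(2, 20, "emergence"))
  inf$timestamp[1] <- inf$timestamp[1] + 20 * 60  # 20 min disagreement
  rec <- reconcile_sources(cam, inf)
  expect_equal(nrow(rec), 2)
  day1 <- rec[rec$date == as.Date("2016-06-01"), ]
  expect_equal(day1$source, "camera")
  expect_equal(day1$timestamp, cam$timestamp)   # camera time kept
  expect_false(day1$conflict)
  day2 <- rec[rec$date == as.Date("2016-06-02"), ]
  expect_equal(day2$source, "tb_inferred")      # inferred fills the gap
  # large disagreements still resolve to camera but are flagged
  inf2 <- mk(1, 22, "emergence")
  rec2 <- reconcile_sources(cam, inf2)
  expect_equal(rec2$source, "camera")
  expect_true(rec2$conflict)
  # reconciliation never invents times absent from both sources
  expect_true(all(rec$timestamp %in% c(cam$timestamp, inf$timestamp)))
})

test_that("the emergence covariate is restricted to the linear 04:00-23:55 window", {
  ev <- data.frame(
    animal_id = "P01",
    timestamp = as.POSIXct(c("2016-06-01 01:00:00", "2016-06-02 04:00:00",
                             "2016-06-03 17:30:00"), tz = "UTC"),
    kind = "emergence")
  expect_message(out <- emergence_covariate(ev), "dropped 1")
  expect_equal(nrow(out), 2)
  expect_equal(out$emergence_h, c(4.0, 17.5))
})

test_that("camera validation reports exact and distributional agreement", {
  # one event per animal-day, well away from midnight so date keys are stable
  ev <- data.frame(animal_id = "P01",
                   timestamp = as.POSIXct("2016-06-01 12:00:00", tz = "UTC") +
                     seq_len(500) * 86400,
                   kind = rep(c("emergence", "return"), 250))
  same <- validate_against_camera(ev, ev)
  expect_equal(same$median_abs_dt_min, 0)
  expect_equal(unname(same$within), rep(1, 3))

  off <- transform(ev, timestamp = timestamp + 15 * 60)
  expect_equal(validate_against_camera(off, ev)$median_abs_dt_min, 15)

  # Gaussian camera jitter: median |dt| is the half-normal median
  ev$event_id <- seq_len(nrow(ev))
  cam <- simulate_camera_observations(ev, 1, 10, 17)
  v <- validate_against_camera(ev, cam)
  half_normal_median <- 10 * stats::qnorm(0.75)
  mc_se <- 1 / (2 * (2 * stats::dnorm(stats::qnorm(0.75)) / 10) * sqrt(500))
  expect_lt(abs(v$median_abs_dt_min - half_normal_median), 2 * mc_se)

  expect_warning(v2 <- validate_against_camera(ev, transform(ev, kind = "x")),
                 "no overlapping")
  expect_equal(v2$n_pairs, 0L)
})
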