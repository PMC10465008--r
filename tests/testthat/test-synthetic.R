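test_that("generator parameters validate their invariants", {
  p <- generator_params()
  expect_s3_class(p, "generator_params")
  expect_error(generator_params(prey = list(dispersion = -1)), "dispersion")
  expect_error(generator_params(tb_min_model = list(knot = 25)), "knot")
  expect_error(generator_params(camera = list(detection_prob = 2)),
               "detection_prob")
  # defaults carry the reported coefficient tables
  expect_equal(p$tb_min_model$intercept, 31.30)
  expect_equal(p$tb_max_model$emergence, -0.11)
  expect_equal(p$tb_amp_model$photoperiod, -0.20)
})

test_that("climate simulation is seasonal, deterministic and validated", {
  p <- generator_params()
  expect_error(simulate_climate(p, "2016-02-01", "2016-01-01", 1), "empty")

  a <- simulate_climate(p, "2015-11-01", "2016-03-01", 7)
  b <- simulate_climate(p, "2015-11-01", "2016-03-01", 7)
  expect_identical(a$globe, b$globe)

  # degenerate sinusoid: no noise, no diurnal cycle -> zero daily amplitude
  p0 <- generator_params(climate = list(noise_sd = 0, diurnal_semiamp = 0,
                                        year2_min_offset = 0,
                                        year2_mean_offset = 0))
  flat <- simulate_climate(p0, "2016-01-01", "2016-01-03", 1)
  dd <- daily_globe_summary(flat$globe, flat$sun)
  expect_true(all(dd$globe_amplitude < 0.6))  # annual drift only

  # winter colder than summer over the full two study years
  cl <- simulate_climate(p, "2015-11-01", "2017-10-31", 3)
  dd2 <- daily_globe_summary(cl$globe, cl$sun)
  se <- assign_season(dd2$date)
  expect_lt(mean(dd2$globe_mean[se == "winter"]),
            mean(dd2$globe_mean[se == "summer"]))
  # photoperiod varies smoothly with day of year
  expect_lt(max(abs(diff(dd2$photoperiod))), 0.05)
})

test_that("prey simulation matches its negative binomial law", {
  p <- generator_params()
  expect_error(simulate_prey(p, "2031-01", 1), "no prey mean")

  # Poisson limit: dispersion -> infinity makes variance track the mean
  ppois <- generator_params(prey = list(
    monthly_means = c("2016-07" = 8.2), dispersion = 1e9, n_transects = 3000))
  d <- simulate_prey(ppois, "2016-07", 11)
  expect_equal(stats::var(d$total) / mean(d$total), 1, tolerance = 0.1)

  # moderate dispersion is over-dispersed
  pod <- generator_params(prey = list(monthly_means = c("2016-07" = 8.2),
                                      dispersion = 5, n_transects = 2000))
  d2 <- simulate_prey(pod, "2016-07", 11)
  expect_gt(stats::var(d2$total), mean(d2$total))

  # year-1 grand mean calibration against the reported 11.4 ants/trap
  months <- month_seq("2015-11-01", "2016-10-31")
  d3 <- simulate_prey(p, months, 13, n_reps = 28)  # 10 080 trap draws
  n_traps <- nrow(d3) * p$prey$tubes_per_transect
  expect_gte(n_traps, 10000)
  tm <- tapply(d3$ants_per_trap, paste(d3$month, d3$rep, d3$transect), mean)
  mc_se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(d3$ants_per_trap) - 11.4), 2 * max(mc_se, 0.05))
})

test_that("daily responses equal the linear predictor when noise-free", {
  p0 <- generator_params(variances = list(
    re_sd = c(tb_min = 0, tb_max = 0, tb_amplitude = 0),
    resid_sd = c(tb_min = 0, tb_max = 0, tb_amplitude = 0), mean_sd = 0))
  cov <- data.frame(animal_id = "P01", date = as.Date("2016-07-01"),
                    photoperiod = c(0, 0, 10), prey = c(0, 9, 18),
                    globe_min = 0, globe_max = 0, globe_amplitude = 0,
                    emergence_h = 0)
  d <- simulate_daily_response(p0, "tb_min", cov, 1)
  # intercept at the covariate origin; +0.9 for prey 0 -> 9; 0 for 9 -> 18
  expect_equal(d$tb_min[1], 31.30)
  expect_equal(d$tb_min[2] - d$tb_min[1], 0.10 * 9)
  expect_equal(d$tb_min[3] - d$tb_min[2] - 0.09 * 10, 0)

  dmax <- simulate_daily_response(p0, "tb_max", cov, 1)
  expect_equal(dmax$tb_max[1], 36.18)
  damp <- simulate_daily_response(p0, "tb_amplitude", cov, 1)
  expect_equal(damp$tb_amplitude[1], 5.29)
})

test_that("the joint daily table is internally consistent", {
  p <- tiny_params()
  ds <- simulate_dataset(p, seed = 2, start = "2016-06-01", end = "2016-07-31",
                         traces = FALSE)
  d <- ds$daily
  expect_true(all(d$tb_min <= d$tb_mean & d$tb_mean <= d$tb_max))
  expect_equal(d$tb_amplitude, d$tb_max - d$tb_min)
  # missing covariate days are dropped with a message
  cd <- ds$climate_daily[-3, ]
  expect_message(
    daily_covariates(cd, ds$prey_monthly,
                     data.frame(animal_id = "P01", date = ds$climate_daily$date,
                                emergence_h = 19, return_h = 2.5)),
    "dropped")
})

test_that("trace construction honours its contract", {
  p <- generator_params(trace = list(noise_sd = 0))
  flat_row <- data.frame(animal_id = "P01", date = as.Date("2016-07-01"),
                         tb_min = 34, tb_max = 34)
  res <- simulate_tb_trace(flat_row, NULL, p, 1)
  expect_equal(nrow(res$trace), 288)
  expect_equal(res$trace$tb_c, rep(34, 288))

  row <- data.frame(animal_id = "P01", date = as.Date("2016-07-10"),
                    tb_min = 30.2, tb_max = 37.0)
  ev <- data.frame(kind = c("return", "emergence"), time_h = c(2.5, 17))
  res2 <- simulate_tb_trace(row, ev, p, 1)
  d2 <- daily_tb_summary(data.frame(res2$trace, animal_id = "P01"))
  expect_equal(d2$tb_amplitude, 6.8, tolerance = 0.1)
  expect_equal(d2$tb_min, 30.2, tolerance = 0.1)
  expect_equal(d2$tb_max, 37.0, tolerance = 0.1)
  # realised notches respect the rule: at least 0.5 degC within the hour
  expect_true(all(abs(res2$events$delta_tb) >= 0.5))

  expect_error(simulate_tb_trace(row, data.frame(kind = c("return", "emergence"),
                                                 time_h = c(16, 17)), p, 1),
               "closer than 2 h")

  # a single clean emergence notch (+0.6 degC) is found near its true time
  row3 <- data.frame(animal_id = "P01", date = as.Date("2016-07-11"),
                     tb_min = 33.8, tb_max = 35.6)
  res3 <- simulate_tb_trace(row3, data.frame(kind = "emergence", time_h = 19),
                            p, 1)
  expect_equal(res3$events$kind, "emergence")
  expect_gt(res3$events$delta_tb, 0.6)
  cand <- detect_events(data.frame(res3$trace, animal_id = "P01"))
  expect_equal(nrow(cand), 1)
  t_found <- as.numeric(format(cand$timestamp, "%H")) +
    as.numeric(format(cand$timestamp, "%M")) / 60
  expect_lt(abs(t_found - 19), 10 / 60 + 1e-9)
})

test_that("camera observation model thins and jitters true events", {
  ev <- data.frame(event_id = 1:1000, animal_id = "P01",
                   timestamp = as.POSIXct("2016-06-01", tz = "UTC") +
                     seq_len(1000) * 7200,
                   kind = "emergence")
  all_seen <- simulate_camera_observations(ev, 1, 0, 3)
  expect_equal(all_seen$timestamp, ev$timestamp)
  expect_equal(nrow(simulate_camera_observations(ev, 0, 5, 3)), 0)
  half <- simulate_camera_observations(ev, 0.5, 5, 3)
  expect_lt(abs(nrow(half) - 500), 2 * sqrt(1000 * 0.25))
  expect_true(all(half$event_id %in% ev$event_id))
  expect_error(simulate_camera_observations(ev, 1.4, 0, 1), "detection_prob")
})

test_that("the full dataset is reproducible bit-for-bit under a fixed seed", {
  p <- tiny_params()
  a <- simulate_dataset(p, seed = 9, start = "2016-06-01", end = "2016-06-14")
  b <- simulate_dataset(p, seed = 9, start = "2016-06-01", end = "2016-06-14")
  expect_identical(a$daily, b$daily)
  expect_identical(a$prey_survey, b$prey_survey)
  expect_identical(lapply(a$traces, `[[`, "samples"),
                   lapply(b$traces, `[[`, "samples"))
  expect_identical(a$camera, b$camera)
})

test_that("daily summaries recomputed from traces match the generated table", {
  p <- tiny_params()
  ds <- simulate_dataset(p, seed = 4, start = "2016-06-01", end = "2016-07-15")
  rt <- do.call(rbind, lapply(ds$traces, daily_tb_summary))
  m <- merge(ds$daily, rt, by = c("animal_id", "date"))
  expect_equal(nrow(m), nrow(ds$daily))
  expect_lt(max(abs(m$tb_min.x - m$tb_min.y)), 0.1)
  expect_lt(max(abs(m$tb_max.x - m$tb_max.y)), 0.1)
  expect_lt(max(abs(m$tb_amplitude.x - m$tb_amplitude.y)), 0.2)
})
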