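test_that("the linear-spline basis matches direct piecewise evaluation", {
  expect_equal(unname(lspline_basis(5, 9)), matrix(c(5, 0), 1))
  expect_equal(unname(lspline_basis(12, 9)), matrix(c(9, 3), 1))
  expect_equal(unname(lspline_basis(9, 9)), matrix(c(9, 0), 1))

  # oracle equivalence on 1000 random (x, knot, slope) configurations
  set.seed(101)
  for (i in 1:5) {
    knot <- stats::runif(1, 0, 18)
    b_lo <- stats::rnorm(1); b_hi <- stats::rnorm(1); a <- stats::rnorm(1)
    x <- stats::runif(200, -2, 25)
    B <- lspline_basis(x, knot)
    pred <- a + B %*% c(b_lo, b_hi)
    expect_equal(as.vector(pred), piecewise_eval(x, knot, b_lo, b_hi, a))
  }
  # continuity at the knot
  eps <- 1e-9
  B2 <- lspline_basis(c(9 - eps, 9, 9 + eps), 9)
  pred <- B2 %*% c(0.1, -0.3)
  expect_lt(max(abs(diff(pred))), 1e-8)
})

make_daily <- function(n_animals = 4, n_days = 120, resid = 0.2, re = 0.15,
                       seed = 1, beta = c(int = 31.3, pp = 0.09, b1 = 0.1,
                                          b2 = 0, gl = 0.02), knot = 9) {
  set.seed(seed)
  prey_levels <- c(0.5, 2, 4, 6, 8, 9.5, 11, 14, 17, 3)
  d <- expand.grid(animal_id = sprintf("A%02d", seq_len(n_animals)),
                   day = seq_len(n_days), stringsAsFactors = FALSE)
  d$photoperiod <- 10.3 + 3.4 * sin(2 * pi * d$day / 365)
  d$prey <- prey_levels[((d$day - 1) %/% 12) %% length(prey_levels) + 1]
  d$globe_min <- 10 + 8 * sin(2 * pi * d$day / 365 + 0.3)
  d$globe_max <- d$globe_min + 19
  d$globe_amplitude <- 19
  d$emergence_h <- 17 + (d$day %% 5)
  re_draw <- stats::rnorm(n_animals, 0, re)
  names(re_draw) <- sprintf("A%02d", seq_len(n_animals))
  B <- lspline_basis(d$prey, knot)
  d$tb_min <- beta["int"] + beta["pp"] * d$photoperiod + beta["b1"] * B[, 1] +
    beta["b2"] * B[, 2] + beta["gl"] * d$globe_min + re_draw[d$animal_id] +
    stats::rnorm(nrow(d), 0, resid)
  d
}

test_that("a single animal degenerates to ordinary least squares", {
  d <- make_daily(n_animals = 1, re = 0)
  fit <- fit_mixed(model_spec("tb_min"), d, 9)
  B <- lspline_basis(d$prey, 9)
  ols <- stats::lm(tb_min ~ photoperiod + B[, 1] + B[, 2] + globe_min, data = d)
  expect_equal(fit$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$n_groups, 1)
})

test_that("noiseless data are interpolated exactly and AIC obeys its identity", {
  d <- make_daily(resid = 0, re = 0)
  fit <- suppressMessages(fit_mixed(model_spec("tb_min"), d, 9))
  expect_equal(fit$coefficients$estimate,
               c(31.3, 0.09, 0.1, 0, 0.02), tolerance = 1e-6)

  # zero animal variance is flagged as singular, not fatal
  ds <- make_daily(resid = 0.2, re = 0)
  expect_true(suppressMessages(fit_mixed(model_spec("tb_min"), ds, 9))$singular)

  d2 <- make_daily()
  fit2 <- fit_mixed(model_spec("tb_min"), d2, 9)
  expect_equal(fit2$AIC, 2 * fit2$n_par - 2 * fit2$logLik)
  expect_equal(fit2$n_par, 5 + 2)  # fixed effects + RE variance + residual
  expect_equal(fit2$AIC, stats::AIC(fit2$fit))
})

test_that("breakpoint search recovers the generating knot and breaks ties low", {
  d <- make_daily(n_days = 240, resid = 0.15, seed = 3)
  bs <- breakpoint_search(model_spec("tb_min"), d, grid = 5:13)
  expect_equal(bs$best_knot, 9)
  expect_equal(bs$aic_table$knot, 5:13)
  expect_true(all(bs$aic_table$status == "ok"))

  # all prey values below every candidate knot: identical fits, exact AIC tie
  d2 <- make_daily(seed = 4)
  d2$prey <- d2$prey / 10   # everything below 2
  B <- lspline_basis(d2$prey, 9)
  bs2 <- breakpoint_search(model_spec("tb_min"), d2, grid = c(6, 7, 8))
  expect_equal(diff(range(bs2$aic_table$AIC)), 0, tolerance = 1e-6)
  expect_equal(bs2$best_knot, 6)
})

test_that("cluster-robust errors change SEs, never estimates", {
  d <- make_daily(n_animals = 6, n_days = 100, seed = 5)
  fit <- fit_mixed(model_spec("tb_min"), d, 9)
  rob <- robust_se(fit)
  expect_equal(rob$coefficients$estimate, fit$coefficients$estimate)
  expect_false(any(is.na(rob$coefficients$robust_se)))
  # balanced homoskedastic data: robust and model SEs agree broadly
  ratio <- rob$coefficients$robust_se / fit$coefficients$se
  expect_true(all(ratio[2:5] > 0.5 & ratio[2:5] < 2))

  d1 <- make_daily(n_animals = 1, re = 0)
  f1 <- fit_mixed(model_spec("tb_min"), d1, 9)
  expect_error(robust_se(f1), "single cluster")
})

test_that("robust SEs exceed model SEs under variance tied to a covariate", {
  # classic sandwich behaviour, checked with per-observation clusters on a
  # design whose covariates are mutually independent
  wins <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 400
    d <- data.frame(animal_id = "A01",
                    photoperiod = stats::runif(n, 10, 14),
                    prey = sample(c(0.5, 3, 6, 9.5, 12, 16), n, TRUE),
                    globe_min = stats::runif(n, 0, 20))
    d$globe_max <- d$globe_min + 19; d$globe_amplitude <- 19
    d$tb_min <- 31 + 0.09 * d$photoperiod +
      stats::rnorm(n, 0, 0.02 + 0.3 * abs(d$photoperiod - 12))
    fit <- fit_mixed(model_spec("tb_min"), d, 9)
    rob <- robust_se(fit, cluster = "observation")
    i <- which(fit$coefficients$term == "Photoperiod")
    wins <- wins + (rob$coefficients$robust_se[i] > fit$coefficients$se[i])
  }
  expect_gte(wins, 8)
})

test_that("negative binomial prey model recovers structure and means", {
  p <- generator_params()
  sv <- simulate_prey(p, month_seq("2015-11-01", "2017-10-31"), 21)
  nb <- fit_nb_counts(sv)
  expect_true(all(c("estimate", "robust_se") %in% names(nb$coefficients)))
  expect_gt(nb$theta, 0)
  # year-1 marginal mean against the reported 11.4 ants/trap; the Monte-Carlo
  # SE treats months as the sampling unit
  y1 <- month_seq("2015-11-01", "2016-10-31")
  mm <- tapply(sv$ants_per_trap[sv$month %in% y1], sv$month[sv$month %in% y1],
               mean)
  mc_se <- stats::sd(mm) / sqrt(length(mm))
  expect_lt(abs(nb$marginal_means$study_year[["1"]] - 11.4), 2 * mc_se)

  # Poisson-simulated counts show no over-dispersion
  pp <- generator_params(prey = list(monthly_means = c("2016-07" = 8),
                                     dispersion = 1e9, n_transects = 200))
  svp <- simulate_prey(pp, "2016-07", 3)
  nbp <- fit_nb_counts(svp)
  expect_lt(abs(nbp$overdispersion - 1), 0.35)

  expect_error(fit_nb_counts(transform(sv, total = 0)), "all counts are zero")
  expect_error(fit_nb_counts(sv[sv$transect == 1, ]), "2 transects")
})

test_that("diagnostics flag collinearity and locate injected outliers", {
  d <- make_daily(n_animals = 4, n_days = 100, seed = 8)
  fit <- fit_mixed(model_spec("tb_min"), d, 9)
  dg <- run_diagnostics(fit)
  expect_false(dg$cooks_flag)
  expect_true(is.finite(dg$max_vif))
  expect_named(dg$vif)

  # photoperiod and globe orthogonal to everything: their VIFs stay at 1
  d2 <- d
  n <- nrow(d2)
  d2$photoperiod <- rep(c(-1, 1), length.out = n)
  d2$prey <- rep(c(1, 40, 61), length.out = n)
  d2$globe_min <- rep(c(-1, 1, 1, -1), length.out = n)
  fit2 <- fit_mixed(model_spec("tb_min"), d2, 9)
  dg2 <- run_diagnostics(fit2)
  expect_lt(max(dg2$vif[c("photoperiod", "globe_min")]), 1.1)

  # duplicated covariate: VIF explodes and is flagged
  d3 <- d
  d3$globe_min <- d3$photoperiod
  fit3 <- fit_mixed(model_spec("tb_min"), d3, 9)
  dg3 <- suppressWarnings(run_diagnostics(fit3))
  expect_true(dg3$vif_flag)
  expect_gt(dg3$max_vif, 1e3)

  # a gross injected outlier attains the maximum Cook's distance
  d4 <- make_daily(n_animals = 4, n_days = 60, seed = 9)
  clean <- run_diagnostics(fit_mixed(model_spec("tb_min"), d4, 9))
  d4$tb_min[77] <- d4$tb_min[77] + 6
  fit4 <- fit_mixed(model_spec("tb_min"), d4, 9)
  dg4 <- run_diagnostics(fit4)
  expect_equal(unname(dg4$which_max_cooks), 77)
  expect_gt(dg4$max_cooks_d, 5 * clean$max_cooks_d)
})

test_that("95% CIs cover the generating coefficients in at least 17/20
          replicates when fitting at the generating breakpoint", {
  rec <- recovery_study(generator_params(), "tb_max", n_reps = 20, seed = 2,
                        search = FALSE)
  expect_true(all(rec$summary$coverage >= 17 / 20))
})

test_that("model specs enforce the emergence-term rule and the knot range", {
  expect_true(model_spec("tb_max")$emergence)
  expect_false(model_spec("tb_min")$emergence)
  expect_false(model_spec("tb_amplitude")$emergence)
  expect_error(model_spec("tb_min", knot_grid = -1:5), "0, 18")
  expect_error(model_spec("tb_min", knot_grid = 10:25), "0, 18")
})
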