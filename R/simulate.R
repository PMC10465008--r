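#' Simulate a 30-min black globe temperature series
#'
#' Globe temperature is a double sinusoid: an annual cycle peaking in
#' mid-January plus a diurnal cycle peaking at 14:00, with additive Gaussian
#' noise. Study year 2 receives the configured offsets to the 24-h mean and
#' minimum; the minimum offset is realised by deepening the nocturnal trough,
#' so both offsets hold exactly in expectation.
#'
#' @param params \code{\link{generator_params}}.
#' @param start,end Dates delimiting the series (inclusive).
#' @param seed integer seed.
#' @return list: \code{globe} (data.frame \code{timestamp}, \code{globe_c} at
#'   30-min steps) and \code{sun} (see \code{\link{sun_table}}).
#' @export
simulate_climate <- function(params, start, end, seed) {
  start <- as.Date(start); end <- as.Date(end)
  if (!is.finite(as.numeric(seed))) stop_invalid("seed must be an integer")
  if (end < start) stop_invalid("empty date range")
  cl <- params$climate
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:30:00"), tz = "UTC"), by = 1800)
  doy <- as.integer(format(ts, "%j"))
  hour <- as.integer(format(ts, "%H")) + as.integer(format(ts, "%M")) / 60
  base <- cl$mean + cl$annual_amplitude *
    cos(2 * pi * (doy - cl$peak_doy) / 365.25)
  diurnal <- cos(2 * pi * (hour - 14) / 24)
  g <- base + cl$diurnal_semiamp * diurnal
  # year-2 offsets: trough deepening keeps the configured min and mean exact
  extra <- (cl$year2_mean_offset - cl$year2_min_offset) / (1 - 1 / pi)
  b2 <- cl$year2_min_offset + extra
  y2 <- assign_study_year(as.Date(format(ts, "%Y-%m-%d"))) == "2"
  g[y2] <- g[y2] + b2 - extra * pmax(-diurnal[y2], 0)
  g <- g + with_seed(substream_seed(seed, "climate"),
                     stats::rnorm(length(g), 0, cl$noise_sd))
  list(globe = data.frame(timestamp = ts, globe_c = g),
       sun = sun_table(seq(start, end, by = "day"), cl$latitude))
}

#' Simulate monthly pitfall-trap surveys
#'
#' Each transect-month total is a negative binomial draw around ten times the
#' month's true mean ants/trap (ten tubes per transect); the per-trap value is
#' the transect total divided by the number of tubes, mirroring how the field
#' counts are reduced.
#'
#' @param params \code{\link{generator_params}}.
#' @param months character vector of "YYYY-MM" labels; each must appear in
#'   \code{params$prey$monthly_means}.
#' @param seed integer seed.
#' @param n_reps replicate surveys per month (replicates share the month's
#'   true mean; used for large calibration runs).
#' @return data.frame: \code{month}, \code{rep}, \code{transect},
#'   \code{total}, \code{ants_per_trap}.
#' @export
simulate_prey <- function(params, months, seed, n_reps = 1) {
  pr <- params$prey
  if (length(months) < 1) stop_invalid("need at least one month")
  mu <- pr$monthly_means[months]
  if (anyNA(mu))
    stop_invalid("no prey mean configured for month(s): %s",
                 paste(months[is.na(mu)], collapse = ", "))
  if (any(mu <= 0)) stop_invalid("prey means must be > 0")
  grid <- expand.grid(transect = seq_len(pr$n_transects),
                      rep = seq_len(n_reps), month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu_row <- pr$monthly_means[grid$month] * pr$tubes_per_transect
  tot <- with_seed(substream_seed(seed, "prey"),
                   stats::rnbinom(nrow(grid), mu = mu_row,
                                  size = pr$dispersion))
  data.frame(month = grid$month, rep = grid$rep, transect = grid$transect,
             total = tot, ants_per_trap = tot / pr$tubes_per_transect)
}

#' Simulate burrow emergence (and return) times
#'
#' Emergence is uniform within a season-specific window; the winter window
#' sits in daylight, reflecting the observed winter shift to diurnal activity.
#' Return falls in the configured early-morning window of the same day.
#'
#' @param params \code{\link{generator_params}}.
#' @param dates Date vector of study days.
#' @param seed integer seed.
#' @return data.frame: \code{animal_id}, \code{date}, \code{emergence_h},
#'   \code{return_h} (decimal hours).
#' @export
simulate_emergence_times <- function(params, dates, seed) {
  dates <- as.Date(dates)
  animals <- sprintf("P%02d", seq_len(params$n_animals))
  grid <- expand.grid(date = dates, animal_id = animals,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  season <- assign_season(grid$date)
  season[season == "excluded-Nov"] <- "spring"  # November behaves like spring
  m <- params$emergence$mean[season]
  h <- params$emergence$halfwidth[season]
  rw <- params$emergence$return_window
  with_seed(substream_seed(seed, "emergence"), {
    grid$emergence_h <- stats::runif(nrow(grid), m - h, m + h)
    grid$return_h <- stats::runif(nrow(grid), rw[1], rw[2])
  })
  grid[, c("animal_id", "date", "emergence_h", "return_h")]
}

# linear predictors of the three generating models, given a covariate frame
model_lp <- function(params, model, cov) {
  mm <- params[[model]]
  globe_col <- switch(model, tb_min_model = "globe_min",
                      tb_max_model = "globe_max", tb_amp_model = "globe_amplitude")
  b <- lspline_basis(cov$prey, mm$knot)
  lp <- mm$intercept + mm$photoperiod * cov$photoperiod +
    mm$prey_below * b[, 1] + mm$prey_above * b[, 2] +
    mm$globe * cov[[globe_col]]
  if (model == "tb_max_model") lp <- lp + mm$emergence * cov$emergence_h
  lp
}

#' Assemble the per animal-day covariate frame
#'
#' Joins daily climate summaries, photoperiod, the monthly prey value
#' (broadcast to every day of its month, on the stated assumption that prey
#' abundance is constant within a month) and per animal-day emergence times.
#' Days missing any covariate are dropped with a message.
#'
#' @param climate_daily output of \code{\link{daily_globe_summary}}.
#' @param prey_monthly data.frame \code{month}, \code{prey_mean}.
#' @param emergence data.frame \code{animal_id}, \code{date},
#'   \code{emergence_h} (optionally \code{return_h}).
#' @return data.frame keyed by \code{animal_id} and \code{date}.
#' @export
daily_covariates <- function(climate_daily, prey_monthly, emergence) {
  cov <- merge(emergence, climate_daily, by = "date", all.x = TRUE)
  cov$prey <- prey_monthly$prey_mean[match(month_label(cov$date),
                                           prey_monthly$month)]
  keep <- stats::complete.cases(cov[, c("photoperiod", "prey", "globe_min",
                                        "globe_max", "globe_amplitude",
                                        "emergence_h")])
  if (any(!keep))
    message(sprintf("daily_covariates: dropped %d day(s) with missing covariates",
                    sum(!keep)))
  cov <- cov[keep, ]
  cov[order(cov$animal_id, cov$date), ]
}

#' Simulate one body-temperature response from its generating model
#'
#' Draws a single daily response (24-h minimum, maximum or amplitude) as its
#' model's linear predictor plus an animal random intercept plus residual
#' noise. This is the generating law the parameter-recovery studies target.
#'
#' @param params \code{\link{generator_params}}.
#' @param response one of \code{"tb_min"}, \code{"tb_max"},
#'   \code{"tb_amplitude"}.
#' @param cov covariate frame from \code{\link{daily_covariates}}.
#' @param seed integer seed.
#' @return \code{cov} with the response column appended.
#' @export
simulate_daily_response <- function(params, response, cov, seed) {
  response <- match.arg(response, c("tb_min", "tb_max", "tb_amplitude"))
  model <- c(tb_min = "tb_min_model", tb_max = "tb_max_model",
             tb_amplitude = "tb_amp_model")[[response]]
  animals <- sort(unique(cov$animal_id))
  with_seed(substream_seed(seed, paste0("daily-", response)), {
    re <- stats::rnorm(length(animals), 0, params$variances$re_sd[[response]])
    names(re) <- animals
    cov[[response]] <- model_lp(params, model, cov) + re[cov$animal_id] +
      stats::rnorm(nrow(cov), 0, params$variances$resid_sd[[response]])
  })
  cov
}

#' Simulate the joint daily body-temperature table
#'
#' The 24-h minimum and maximum are generated from their respective models and
#' then reconciled: the maximum is kept at least 0.2 degC above the minimum,
#' the amplitude is defined as maximum minus minimum, and the mean is placed
#' at the resting fraction of the range with a small jitter, clipped into
#' [min, max]. Season and study-year labels are attached.
#'
#' @inheritParams simulate_daily_response
#' @return data.frame with covariates and \code{tb_min}, \code{tb_max},
#'   \code{tb_mean}, \code{tb_amplitude} per animal-day.
#' @export
simulate_daily_tb <- function(params, cov, seed) {
  out <- simulate_daily_response(params, "tb_min", cov, seed)
  out <- simulate_daily_response(params, "tb_max", out, seed)
  out$tb_max <- pmax(out$tb_max, out$tb_min + 0.2)
  out$tb_amplitude <- out$tb_max - out$tb_min
  mid <- out$tb_min + params$trace$rest_fraction * out$tb_amplitude
  noise <- with_seed(substream_seed(seed, "daily-mean"),
                     stats::rnorm(nrow(out), 0, params$variances$mean_sd))
  out$tb_mean <- pmin(pmax(mid + noise, out$tb_min), out$tb_max)
  out$season <- assign_season(out$date)
  out$study_year <- assign_study_year(out$date)
  out
}
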