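#' Simulate one day's 5-min body-temperature trace
#'
#' Builds a 288-sample trace consistent with the day's summary row: an active
#' plateau just below the daily maximum, a fast descent to the daily minimum
#' merged with the burrow-return notch, a slow rewarming to a resting plateau,
#' and a fast emergence ramp up to the daily maximum. Fast ramps run at the
#' configured event rate (well above the notch-rule threshold) while all other
#' drifts stay below 0.5 degC/h, so the event detector recovers exactly the
#' generated events and nothing else on a noise-free trace.
#'
#' @param daily_row one row of the daily table (needs \code{tb_min},
#'   \code{tb_max}, \code{date}).
#' @param events data.frame of the day's events with \code{kind}
#'   (\code{"emergence"}/\code{"return"}) and \code{time_h} (decimal hours);
#'   may be empty. Events closer than 2 h are rejected: the quiescence that
#'   separates them could not be guaranteed.
#' @param params \code{\link{generator_params}}.
#' @param seed integer seed.
#' @param start_level trace level at midnight (for continuity across days);
#'   defaults to the day's own active plateau.
#' @param end_target level to steer toward by the end of the day (the next
#'   day's feasible start), reached only as far as the slow drift rate
#'   allows; default is the day's own active plateau.
#' @return list: \code{trace} (data.frame \code{timestamp}, \code{tb_c}) and
#'   \code{events} (the realised events with \code{delta_tb} and \code{span}
#'   in minutes; only notches of at least the detectability threshold are
#'   kept as true events).
#' @export
simulate_tb_trace <- function(daily_row, events, params, seed,
                              start_level = NULL, end_target = NULL) {
  m <- daily_row$tb_min; M <- daily_row$tb_max
  if (m > M) stop_invalid("daily min exceeds max")
  tr <- params$trace
  t_h <- seq(0, 24 - 1 / 12, by = 1 / 12)
  if (!is.null(events) && nrow(events) >= 2) {
    if (min(diff(sort(events$time_h))) < 2)
      stop_invalid("events closer than 2 h on %s", daily_row$date)
  }
  if (!is.null(events) && nrow(events) > 0 &&
      (any(events$time_h < 0) || any(events$time_h >= 24)))
    stop_invalid("event times must lie within the day")

  amp <- M - m
  realised <- list()
  if (amp < 0.01) {
    level <- rep(m, length(t_h))
  } else {
    P_a <- M - min(tr$plateau_offset, amp / 2)
    P_r <- m + tr$rest_fraction * amp
    E <- if (!is.null(events)) events$time_h[events$kind == "emergence"][1] else NA
    R <- if (!is.null(events)) events$time_h[events$kind == "return"][1] else NA
    # carried-over midnight level, kept inside the day's own range
    lvl0 <- if (is.null(start_level)) P_a else
      min(max(start_level, m + 0.005), M)
    pts_t <- 0; pts_v <- lvl0
    if (is.na(E) && is.na(R)) {
      # quiet day: slow excursion only, all slopes below the notch rule
      mid <- (m + M) / 2
      pts_t <- c(0, 5, min(5 + amp / tr$rise_rate, 20), 22, 24)
      pts_v <- c(mid, m, M, mid, mid)
    } else {
      has_return <- !is.na(R)
      R <- if (is.na(R)) 2.5 else R
      # drift from the carried-over midnight level toward the active plateau,
      # rate-limited so the pre-return drift never trips the notch rule
      gap <- P_a - lvl0
      lvl_R <- lvl0 + sign(gap) * min(abs(gap), 0.4 * max(R - 0.2, 0.1))
      if (abs(lvl_R - lvl0) > 1e-9) {
        pts_t <- c(pts_t, abs(lvl_R - lvl0) / 0.4)
        pts_v <- c(pts_v, lvl_R)
      }
      pts_t <- c(pts_t, R); pts_v <- c(pts_v, lvl_R)
      # the descent is the return notch only when a return event exists and
      # clears the threshold; otherwise it must stay below the detector's
      # rule everywhere, so it runs at the slow rate and emits no true event
      eventful <- has_return && (lvl_R - m >= tr$notch_min)
      d_r <- (lvl_R - m) / if (eventful) tr$event_rate else tr$rise_rate
      pts_t <- c(pts_t, R + d_r); pts_v <- c(pts_v, m)
      if (eventful)
        realised$return <- c(time_h = R, delta = -(lvl_R - m), span = d_r * 60)
      t_rise_end <- R + d_r + (P_r - m) / tr$rise_rate
      if (is.na(E)) {
        pts_t <- c(pts_t, t_rise_end, 24); pts_v <- c(pts_v, P_r, P_r)
      } else {
        if (t_rise_end > E - 0.1) {  # not enough night: lower the rest level
          P_r <- m + tr$rise_rate * max(E - 0.1 - (R + d_r), 0)
          t_rise_end <- R + d_r + (P_r - m) / tr$rise_rate
        }
        pts_t <- c(pts_t, t_rise_end, E); pts_v <- c(pts_v, P_r, P_r)
        notch_e <- M - P_r
        rise_rate_e <- if (notch_e >= tr$notch_min) tr$event_rate else
          tr$rise_rate
        d_e <- notch_e / rise_rate_e
        peak_end <- min(E + d_e + 1 / 6, 24)
        # settle toward the next day's feasible start, but only as far as the
        # slow rate allows, so the day boundary never concentrates a
        # detectable drop
        target <- if (is.null(end_target)) P_a else min(P_a, end_target)
        settle_amt <- min(max(M - target, 0),
                          tr$rise_rate * max(24 - peak_end, 0))
        pts_t <- c(pts_t, E + d_e, peak_end, 24)
        pts_v <- c(pts_v, M, M, M - settle_amt)
        if (notch_e >= tr$notch_min)
          realised$emergence <- c(time_h = E, delta = notch_e, span = d_e * 60)
      }
    }
    o <- !duplicated(pts_t)
    level <- stats::approx(pts_t[o], pts_v[o], xout = t_h, rule = 2)$y
  }
  noise <- with_seed(substream_seed(seed, paste0("trace-", daily_row$date, "-",
                                                 daily_row$animal_id %||% "x")),
                     stats::rnorm(length(t_h), 0, tr$noise_sd))
  ev <- do.call(rbind, lapply(names(realised), function(k) {
    e <- realised[[k]]
    data.frame(kind = k, time_h = unname(e["time_h"]),
               delta_tb = unname(e["delta"]), span = unname(e["span"]))
  }))
  if (!is.null(ev)) ev <- ev[abs(ev$delta_tb) >= tr$notch_min, , drop = FALSE]
  list(trace = data.frame(
         timestamp = as.POSIXct(paste(daily_row$date, "00:00:00"),
                                tz = "UTC") + t_h * 3600,
         tb_c = level + noise),
       events = ev,
       end_level = level[length(level)])
}

#' Simulate multi-day traces for every animal
#'
#' Chains \code{\link{simulate_tb_trace}} across days with level continuity at
#' midnight, collecting the realised (true) events.
#'
#' @param daily daily table from \code{\link{simulate_daily_tb}} (needs
#'   \code{emergence_h} and \code{return_h} columns).
#' @param params \code{\link{generator_params}}.
#' @param seed integer seed.
#' @return list: \code{traces} (named list of \code{tb_series}, one per
#'   animal) and \code{events} (data.frame \code{animal_id},
#'   \code{timestamp}, \code{kind}, \code{delta_tb}, \code{span}).
#' @export
simulate_traces <- function(daily, params, seed) {
  traces <- list(); all_events <- list()
  for (a in sort(unique(daily$animal_id))) {
    da <- daily[daily$animal_id == a, ]
    da <- da[order(da$date), ]
    lvl <- NULL; segs <- vector("list", nrow(da)); evs <- list()
    for (i in seq_len(nrow(da))) {
      row <- da[i, ]
      events <- data.frame(kind = c("return", "emergence"),
                           time_h = c(row$return_h, row$emergence_h))
      end_target <- if (i < nrow(da)) da$tb_max[i + 1] - 0.05 else NULL
      res <- simulate_tb_trace(row, events, params, seed, start_level = lvl,
                               end_target = end_target)
      segs[[i]] <- res$trace
      lvl <- res$end_level
      if (!is.null(res$events) && nrow(res$events)) {
        res$events$animal_id <- a
        res$events$timestamp <- as.POSIXct(paste(row$date, "00:00:00"),
                                           tz = "UTC") + res$events$time_h * 3600
        evs[[length(evs) + 1]] <- res$events
      }
    }
    df <- do.call(rbind, segs)
    traces[[a]] <- tb_series(a, df$timestamp, df$tb_c,
                             calibration_applied = TRUE, drift_corrected = TRUE)
    if (length(evs)) all_events[[a]] <- do.call(rbind, evs)
  }
  ev <- do.call(rbind, all_events)
  rownames(ev) <- NULL
  ev$event_id <- seq_len(nrow(ev))
  list(traces = traces,
       events = ev[, c("event_id", "animal_id", "timestamp", "kind",
                       "delta_tb", "span")])
}

#' Thin and jitter true events into camera observations
#'
#' Cameras miss events (Bernoulli thinning) and record times with Gaussian
#' jitter; observed events keep their identity link to the true list.
#'
#' @param events true event table (needs \code{timestamp}; an \code{event_id}
#'   column is preserved).
#' @param detection_prob probability a camera records an event.
#' @param jitter_sd SD of the recorded-time error, minutes.
#' @param seed integer seed.
#' @return The observed subset with jittered \code{timestamp}.
#' @export
simulate_camera_observations <- function(events, detection_prob, jitter_sd,
                                         seed) {
  if (detection_prob < 0 || detection_prob > 1)
    stop_invalid("detection_prob must lie in [0, 1]")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  with_seed(substream_seed(seed, "camera"), {
    keep <- stats::runif(nrow(events)) < detection_prob
    out <- events[keep, , drop = FALSE]
    out$timestamp <- out$timestamp +
      stats::rnorm(nrow(out), 0, jitter_sd * 60)
  })
  out$source <- rep("camera", nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate the full coupled dataset
#'
#' Runs every generator stage under named substreams of one master seed:
#' climate and sun table, monthly prey surveys, emergence/return times, the
#' joint daily body-temperature table, 5-min traces with true events, and the
#' camera-observed subset.
#'
#' @param params \code{\link{generator_params}}.
#' @param seed master integer seed.
#' @param start,end simulation window (defaults: the two study years).
#' @param traces generate 5-min traces (the slowest stage); set \code{FALSE}
#'   for daily-table-only studies.
#' @return list of class \code{"synthetic_dataset"}.
#' @export
simulate_dataset <- function(params = generator_params(), seed = 1,
                             start = study_calendar()$start,
                             end = study_calendar()$end, traces = TRUE) {
  clim <- simulate_climate(params, start, end, seed)
  climate_daily <- daily_globe_summary(clim$globe, clim$sun)
  survey <- simulate_prey(params, month_seq(start, end), seed)
  prey_monthly <- prey_per_trap(survey)$monthly
  emerg <- simulate_emergence_times(params, seq(as.Date(start), as.Date(end),
                                                by = "day"), seed)
  cov <- daily_covariates(climate_daily, prey_monthly, emerg)
  daily <- simulate_daily_tb(params, cov, seed)
  out <- list(params = params, seed = seed,
              climate = clim$globe, sun = clim$sun,
              climate_daily = climate_daily,
              prey_survey = survey, prey_monthly = prey_monthly,
              daily = daily)
  if (traces) {
    tr <- simulate_traces(daily, params, seed)
    out$traces <- tr$traces
    out$events <- tr$events
    out$camera <- simulate_camera_observations(
      tr$events, params$camera$detection_prob, params$camera$jitter_sd, seed)
  }
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Emits the canonical file layout: climate, sun table, prey survey, daily
#' table, one trace CSV per animal, the event lists and a JSON sidecar with
#' the generator parameters and seed.
#'
#' @param ds a \code{synthetic_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset_csv <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  clim <- ds$climate
  clim$timestamp <- format(clim$timestamp, "%Y-%m-%dT%H:%M:%S")
  w(clim, "climate.csv")
  sun <- ds$sun
  sun$sunrise <- format(sun$sunrise, "%Y-%m-%dT%H:%M:%S")
  sun$sunset <- format(sun$sunset, "%Y-%m-%dT%H:%M:%S")
  w(sun, "sun.csv")
  w(ds$prey_survey, "prey_survey.csv")
  w(ds$daily, "daily_tb.csv")
  if (!is.null(ds$traces))
    for (a in names(ds$traces))
      write_logger_csv(ds$traces[[a]], file.path(dir, paste0("trace_", a, ".csv")))
  fmt_ev <- function(ev) {
    ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
    ev
  }
  if (!is.null(ds$events)) w(fmt_ev(ds$events), "events_true.csv")
  if (!is.null(ds$camera)) w(fmt_ev(ds$camera), "events_camera.csv")
  sidecar <- ds$params
  class(sidecar) <- NULL
  jsonlite::write_json(list(seed = ds$seed, params = sidecar),
                       file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
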