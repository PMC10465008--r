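#' Assign the seasonal label of a date
#'
#' Seasons follow the southern-hemisphere calendar used for all seasonal
#' summaries: summer December-February, autumn March-May, winter June-August,
#' spring September-October. November is labelled \code{"excluded-Nov"}: each
#' study year starts in November, which would split spring across two years,
#' so November never enters springtime summaries.
#'
#' @param date Date vector (or coercible).
#' @return Character vector of season labels.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  out <- rep("excluded-Nov", length(m))
  out[m %in% c(12, 1, 2)] <- "summer"
  out[m %in% 3:5] <- "autumn"
  out[m %in% 6:8] <- "winter"
  out[m %in% 9:10] <- "spring"
  out
}

#' Assign the study year of a date
#'
#' Year 1 runs November 2015 - October 2016 and year 2 November 2016 -
#' October 2017 (inclusive month ranges); anything else is \code{"outside"}.
#'
#' @param date Date vector.
#' @param year_starts Dates on which each study year begins.
#' @return Character vector: \code{"1"}, \code{"2"} or \code{"outside"}.
#' @export
assign_study_year <- function(date, year_starts = study_calendar()$year_starts) {
  date <- as.Date(date)
  year_starts <- sort(as.Date(year_starts))
  out <- rep("outside", length(date))
  for (i in seq_along(year_starts)) {
    lo <- year_starts[i]
    hi <- seq(lo, by = "12 months", length.out = 2)[2] - 1
    out[date >= lo & date <= hi] <- as.character(i)
  }
  out
}

#' 24-h body temperature summaries
#'
#' Collapses a calibrated, drift-corrected 5-min series into one row per
#' midnight-to-midnight day: minimum, maximum, arithmetic mean and amplitude
#' (maximum minus minimum), with season and study-year labels. Days with fewer
#' than \code{completeness} x 288 samples are excluded (a gap could fake the
#' minimum or maximum) and reported via the \code{"excluded_days"} attribute.
#'
#' @param series a \code{tb_series} object or a data.frame with
#'   \code{timestamp} (POSIXct) and \code{tb_c} columns.
#' @param completeness minimum fraction of the 288 expected samples.
#' @return data.frame with columns \code{animal_id}, \code{date},
#'   \code{tb_min}, \code{tb_max}, \code{tb_mean}, \code{tb_amplitude},
#'   \code{n_samples}, \code{season}, \code{study_year}.
#' @export
daily_tb_summary <- function(series, completeness = 0.8) {
  df <- as_tb_frame(series)
  day <- as.Date(format(df$timestamp, "%Y-%m-%d"))
  sp <- split(df$tb_c, day)
  n <- vapply(sp, length, integer(1))
  keep <- n >= completeness * 288
  excluded <- names(sp)[!keep]
  if (length(excluded))
    message(sprintf("daily_tb_summary: excluded %d incomplete day(s)",
                    length(excluded)))
  dates <- as.Date(names(sp)[keep])
  mins <- vapply(sp[keep], min, numeric(1))
  maxs <- vapply(sp[keep], max, numeric(1))
  animal <- if (inherits(series, "tb_series")) series$animal_id
            else (df$animal_id[1] %||% NA_character_)
  out <- data.frame(
    animal_id = rep(animal, length(dates)),
    date = dates,
    tb_min = mins, tb_max = maxs,
    tb_mean = vapply(sp[keep], mean, numeric(1)),
    tb_amplitude = maxs - mins,
    n_samples = n[keep],
    season = assign_season(dates),
    study_year = assign_study_year(dates),
    row.names = NULL
  )
  attr(out, "excluded_days") <- excluded
  out
}

#' 24-h black globe summaries with photoperiod
#'
#' @param globe data.frame with \code{timestamp} and \code{globe_c} (30-min
#'   series).
#' @param sun sun table from \code{\link{sun_table}} (or with \code{date} and
#'   \code{photoperiod}); days missing from it get \code{NA} photoperiod and a
#'   warning.
#' @return data.frame: \code{date}, \code{globe_min}, \code{globe_max},
#'   \code{globe_mean}, \code{globe_amplitude}, \code{photoperiod}.
#' @export
daily_globe_summary <- function(globe, sun) {
  day <- as.Date(format(globe$timestamp, "%Y-%m-%d"))
  sp <- split(globe$globe_c, day)
  dates <- as.Date(names(sp))
  mins <- vapply(sp, min, numeric(1))
  maxs <- vapply(sp, max, numeric(1))
  out <- data.frame(
    date = dates, globe_min = mins, globe_max = maxs,
    globe_mean = vapply(sp, mean, numeric(1)),
    globe_amplitude = maxs - mins, row.names = NULL
  )
  if (is.null(sun)) {
    out$photoperiod <- NA_real_
    return(out)
  }
  if ("photoperiod" %in% names(sun)) {
    out$photoperiod <- sun$photoperiod[match(out$date, as.Date(sun$date))]
  } else {
    rise <- as.POSIXct(sun$sunrise); set <- as.POSIXct(sun$sunset)
    p <- as.numeric(difftime(set, rise, units = "hours"))
    out$photoperiod <- p[match(out$date, as.Date(sun$date))]
  }
  if (anyNA(out$photoperiod))
    warning(sprintf("photoperiod missing for %d day(s)",
                    sum(is.na(out$photoperiod))))
  out
}

#' Aggregate rain-gauge readings
#'
#' Monthly rainfall is the mean across gauges; annual rainfall is the sum of
#' the monthly means over each November-October study year.
#'
#' @param gauges data.frame with \code{month} ("YYYY-MM"), \code{gauge},
#'   \code{rain_mm}.
#' @return list with \code{monthly} (month, mean rain) and \code{annual}
#'   (study_year, total) data.frames.
#' @export
aggregate_rainfall <- function(gauges) {
  stopifnot(all(c("month", "rain_mm") %in% names(gauges)))
  monthly <- aggregate(rain_mm ~ month, data = gauges, FUN = mean)
  names(monthly)[2] <- "rain_mean_mm"
  yr <- assign_study_year(month_start(monthly$month))
  annual <- aggregate(monthly$rain_mean_mm, list(study_year = yr), sum)
  names(annual)[2] <- "rain_total_mm"
  list(monthly = monthly, annual = annual[annual$study_year != "outside", ])
}

#' Prey abundance per trap, by month, season and year
#'
#' @param survey data.frame with \code{transect}, \code{month} ("YYYY-MM") and
#'   \code{ants_per_trap} (transect total divided by tubes).
#' @return list with \code{monthly} (month x mean, the covariate joined to
#'   daily rows), \code{seasonal} and \code{yearly} mean/SE tables. SEs treat
#'   transect-months as the sampling unit.
#' @export
prey_per_trap <- function(survey) {
  stopifnot(all(c("transect", "month", "ants_per_trap") %in% names(survey)))
  if (any(survey$ants_per_trap < 0)) stop_invalid("negative ant counts")
  mo <- aggregate(ants_per_trap ~ month, data = survey, FUN = mean)
  names(mo)[2] <- "prey_mean"
  d <- month_start(survey$month)
  survey$season <- assign_season(d)
  survey$study_year <- assign_study_year(d)
  mse <- function(x) c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                       n = length(x))
  seas <- do.call(rbind, lapply(split(survey, survey$season), function(s)
    data.frame(season = s$season[1], t(mse(s$ants_per_trap)))))
  yr <- do.call(rbind, lapply(
    split(survey, survey$study_year), function(s)
      data.frame(study_year = s$study_year[1], t(mse(s$ants_per_trap)))))
  rownames(seas) <- rownames(yr) <- NULL
  list(monthly = mo,
       seasonal = seas[seas$season != "excluded-Nov", ],
       yearly = yr[yr$study_year != "outside", ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize tb_series / data.frame input to a timestamp+tb_c frame
as_tb_frame <- function(series) {
  if (inherits(series, "tb_series")) return(series$samples)
  stopifnot(all(c("timestamp", "tb_c") %in% names(series)))
  series
}
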