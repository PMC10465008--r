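#' Construct a body-temperature series
#'
#' A \code{tb_series} holds one animal's core body-temperature record at a
#' nominal 5-min spacing. Timestamps must be strictly increasing; calibrated
#' temperatures outside the plausibility band [20, 45] degC are flagged in the
#' \code{implausible} attribute, never dropped.
#'
#' @param animal_id animal identifier.
#' @param timestamp POSIXct vector.
#' @param tb_c temperatures (degC).
#' @param calibration_applied,drift_corrected logical flags.
#' @return Object of class \code{"tb_series"}.
#' @export
tb_series <- function(animal_id, timestamp, tb_c,
                      calibration_applied = FALSE, drift_corrected = FALSE) {
  stopifnot(length(timestamp) == length(tb_c))
  if (length(timestamp) == 0L) stop_invalid("empty series")
  if (is.unsorted(timestamp, strictly = TRUE)) {
    dup <- timestamp[which(diff(as.numeric(timestamp)) <= 0)[1] + 1]
    stop_invalid("timestamps not strictly increasing (first violation at %s)",
                 format(dup))
  }
  out <- list(animal_id = as.character(animal_id),
              samples = data.frame(timestamp = timestamp, tb_c = tb_c),
              calibration_applied = isTRUE(calibration_applied),
              drift_corrected = isTRUE(drift_corrected))
  class(out) <- "tb_series"
  if (calibration_applied) {
    bad <- which(tb_c < 20 | tb_c > 45)
    if (length(bad)) attr(out, "implausible") <- bad
  }
  out
}

#' @export
print.tb_series <- function(x, ...) {
  cat(sprintf("<tb_series %s: %d samples, %s to %s%s%s>\n", x$animal_id,
              nrow(x$samples), format(min(x$samples$timestamp)),
              format(max(x$samples$timestamp)),
              if (x$calibration_applied) ", calibrated" else "",
              if (x$drift_corrected) ", drift-corrected" else ""))
  invisible(x)
}

#' Read a raw logger CSV
#'
#' Parses the canonical dialect (\code{timestamp,tb_c}, ISO-8601 local
#' timestamps) or a configurable variant. Duplicate timestamps are rejected
#' with the offending timestamp named; gaps relative to the nominal interval
#' are recorded in the \code{"gap_report"} attribute, never interpolated.
#'
#' @param path file path.
#' @param animal_id identifier; defaults to the file name without extension.
#' @param time_col,temp_col column names.
#' @param time_format strptime format, default ISO-8601.
#' @param sep field delimiter.
#' @param nominal_interval expected sample spacing in minutes.
#' @return A \code{tb_series} (uncalibrated, not drift-corrected).
#' @export
parse_logger_csv <- function(path, animal_id = NULL, time_col = "timestamp",
                             temp_col = "tb_c",
                             time_format = "%Y-%m-%dT%H:%M:%S", sep = ",",
                             nominal_interval = 5) {
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_invalid("empty logger file: %s", path)
  if (!all(c(time_col, temp_col) %in% names(raw)))
    stop_invalid("missing column(s) in %s: need %s and %s",
                 path, time_col, temp_col)
  ts <- as.POSIXct(raw[[time_col]], format = time_format, tz = "UTC")
  if (anyNA(ts))
    stop_invalid("unparseable timestamp at data row %d of %s",
                 which(is.na(ts))[1], path)
  temp <- suppressWarnings(as.numeric(raw[[temp_col]]))
  if (anyNA(temp))
    stop_invalid("unparseable temperature at data row %d of %s",
                 which(is.na(temp))[1], path)
  if (anyDuplicated(ts)) {
    stop_invalid("duplicated timestamp %s in %s",
                 format(ts[duplicated(ts)][1]), path)
  }
  o <- order(ts)
  s <- tb_series(animal_id %||% sub("\\.[^.]*$", "", basename(path)),
                 ts[o], temp[o])
  gaps <- which(diff(as.numeric(s$samples$timestamp)) / 60 >
                  1.5 * nominal_interval)
  if (length(gaps))
    attr(s, "gap_report") <- data.frame(
      after = s$samples$timestamp[gaps],
      gap_min = diff(as.numeric(s$samples$timestamp))[gaps] / 60)
  s
}

#' Write a series in the canonical CSV dialect
#'
#' Temperatures are written with four decimals; write -> parse -> write is
#' byte-identical for this dialect.
#'
#' @param series a \code{tb_series} or timestamp/tb_c data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  df <- as_tb_frame(series)
  lines <- c("timestamp,tb_c",
             sprintf("%s,%.4f", format(df$timestamp, "%Y-%m-%dT%H:%M:%S"),
                     df$tb_c))
  writeLines(lines, path)
  invisible(path)
}

#' Fit a water-bath calibration line
#'
#' Ordinary least squares regression of the bath reference on the logger
#' reading over the calibrated range 26-42 degC, so corrected values are
#' predictions of true temperature.
#'
#' @param reference_pairs data.frame (or 2-column matrix) with columns
#'   \code{bath_c} then \code{logger_c}.
#' @return list of class \code{"calibration_curve"}: \code{slope},
#'   \code{intercept}, \code{range}, \code{rmse}.
#' @export
fit_calibration <- function(reference_pairs) {
  rp <- as.data.frame(reference_pairs)
  if (ncol(rp) < 2) stop_invalid("need bath and logger columns")
  names(rp)[1:2] <- c("bath_c", "logger_c")
  rp <- rp[stats::complete.cases(rp[, 1:2]), ]
  if (nrow(rp) < 2) stop_invalid("need at least 2 calibration points")
  if (stats::sd(rp$logger_c) == 0)
    stop_invalid("calibration points have zero spread")
  fit <- stats::lm(bath_c ~ logger_c, data = rp)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              range = c(26, 42),
              rmse = sqrt(mean(stats::residuals(fit)^2)))
  if (out$slope <= 0) stop_invalid("calibration slope must be > 0")
  class(out) <- "calibration_curve"
  out
}

#' Apply a calibration curve to a series
#'
#' @param series an uncalibrated \code{tb_series}.
#' @param curve a \code{calibration_curve}.
#' @return The calibrated series (\code{calibration_applied} set); applying a
#'   curve twice is an error.
#' @export
apply_calibration <- function(series, curve) {
  stopifnot(inherits(series, "tb_series"), inherits(curve, "calibration_curve"))
  if (series$calibration_applied)
    stop_invalid("calibration already applied to %s", series$animal_id)
  tb_series(series$animal_id, series$samples$timestamp,
            curve$intercept + curve$slope * series$samples$tb_c,
            calibration_applied = TRUE,
            drift_corrected = series$drift_corrected)
}

#' Correct logger clock drift
#'
#' The logger crystals drift by about one minute per month; the total measured
#' drift over the deployment is apportioned linearly in time (zero at
#' deployment start, \code{total_drift_minutes} at the end) and timestamps are
#' then snapped back to the nominal 5-min grid.
#'
#' @param series a \code{tb_series}.
#' @param total_drift_minutes signed correction to apply at the deployment end:
#'   the final sample is shifted by exactly this many minutes, earlier samples
#'   proportionally less.
#' @param deployment_span POSIXct length-2 vector covering the series.
#' @param snap_interval grid spacing in minutes.
#' @return The corrected series (\code{drift_corrected} set).
#' @export
correct_clock_drift <- function(series, total_drift_minutes, deployment_span,
                                snap_interval = 5) {
  stopifnot(inherits(series, "tb_series"))
  span <- as.POSIXct(deployment_span)
  ts <- series$samples$timestamp
  if (min(ts) < span[1] || max(ts) > span[2])
    stop_invalid("deployment span does not cover the series")
  span_min <- as.numeric(difftime(span[2], span[1], units = "mins"))
  if (abs(total_drift_minutes) > 0.1 * span_min)
    stop_invalid("implausible drift: |%g| min over a %.0f-min deployment",
                 total_drift_minutes, span_min)
  frac <- as.numeric(difftime(ts, span[1], units = "mins")) / span_min
  shifted <- as.numeric(ts) + frac * total_drift_minutes * 60
  if (!is.null(snap_interval)) {
    step <- snap_interval * 60
    shifted <- round(shifted / step) * step
  }
  tb_series(series$animal_id,
            as.POSIXct(shifted, origin = "1970-01-01", tz = "UTC"),
            series$samples$tb_c,
            calibration_applied = series$calibration_applied,
            drift_corrected = TRUE)
}
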