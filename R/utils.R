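#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic stages draw their randomness from named substreams of one
#' master seed, so any stage can be re-run in isolation and still reproduce
#' the exact numbers it produced inside a full pipeline run.
#'
#' @param master integer master seed.
#' @param stream character name of the substream (e.g. \code{"climate"}).
#' @return An integer seed in \code{[1, 2^31 - 2]}.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(stream), length(stream) == 1L, nzchar(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(as.numeric(master)) * 48271 + h) %% 2147483646 + 1)
}

#' Evaluate an expression with a local RNG seed
#'
#' Restores the caller's RNG state on exit, so seeded helpers do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Day length from latitude and day of year
#'
#' Standard solar geometry (no atmospheric refraction): the day length is
#' \code{2H / 15} hours where \code{cos H = -tan(lat) tan(decl)} and the solar
#' declination follows a sine approximation of the annual cycle.
#'
#' @param date Date vector.
#' @param latitude site latitude in decimal degrees (negative = south).
#' @return Numeric vector of day lengths in hours.
#' @export
photoperiod_hours <- function(date, latitude = -27.22) {
  doy <- as.integer(format(as.Date(date), "%j"))
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  2 * acos(x) * 180 / pi / 15
}

#' Sunrise and sunset table for a date range
#'
#' Sunrise and sunset are placed symmetrically around local solar noon
#' (12:00) using \code{\link{photoperiod_hours}}.
#'
#' @param dates Date vector.
#' @param latitude site latitude in decimal degrees.
#' @return data.frame with columns \code{date}, \code{sunrise}, \code{sunset}
#'   (POSIXct, local) and \code{photoperiod} (hours).
#' @export
sun_table <- function(dates, latitude = -27.22) {
  dates <- as.Date(dates)
  p <- photoperiod_hours(dates, latitude)
  midnight <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  data.frame(
    date = dates,
    sunrise = midnight + (12 - p / 2) * 3600,
    sunset = midnight + (12 + p / 2) * 3600,
    photoperiod = p
  )
}

#' Month-label helpers
#'
#' Calendar months are keyed throughout by "YYYY-MM" labels:
#' \code{month_label} formats dates, \code{month_start} inverts it to the
#' first day of the month, and \code{month_seq} enumerates the labels
#' covering a date range.
#'
#' @param date Date vector.
#' @param label character "YYYY-MM" vector.
#' @param from,to dates delimiting the range (inclusive).
#' @return Character labels or Dates.
#' @export
month_label <- function(date) format(as.Date(date), "%Y-%m")

#' @rdname month_label
#' @export
month_start <- function(label) as.Date(paste0(label, "-01"))

#' @rdname month_label
#' @export
month_seq <- function(from, to) {
  s <- seq(month_start(month_label(from)), as.Date(to), by = "month")
  month_label(s)
}

#' @keywords internal
stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
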