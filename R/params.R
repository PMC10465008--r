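#' Default study calendar
#'
#' The study window runs from 2015-11-01 to 2017-10-31: two year-long periods
#' each starting in November, matching the seasonal calendar used throughout
#' (summer Dec-Feb, autumn Mar-May, winter Jun-Aug, spring Sep-Oct, November
#' excluded from spring summaries).
#'
#' @return list with \code{start}, \code{end} (Dates) and \code{year_starts}.
#' @export
study_calendar <- function() {
  list(start = as.Date("2015-11-01"),
       end = as.Date("2017-10-31"),
       year_starts = as.Date(c("2015-11-01", "2016-11-01")))
}

# Default monthly mean ants/trap. Year 1 is the dry year: prey collapses from
# late summer through winter and recovers abruptly in October; year 2 is wet,
# with no month below ~9 ants/trap. The allocation fixes the year-1 grand mean
# at 11.4 and the winter (across-year) mean at 8.2 ants/trap, and places months
# near 9-12 ants/trap so a breakpoint in that range is identifiable.
default_prey_monthly <- function() {
  c("2015-11" = 21.4, "2015-12" = 26.0, "2016-01" = 28.0, "2016-02" = 20.0,
    "2016-03" = 4.0,  "2016-04" = 2.2,  "2016-05" = 1.6,  "2016-06" = 1.2,
    "2016-07" = 0.4,  "2016-08" = 0.8,  "2016-09" = 3.8,  "2016-10" = 27.4,
    "2016-11" = 13.0, "2016-12" = 30.0, "2017-01" = 34.0, "2017-02" = 27.0,
    "2017-03" = 16.0, "2017-04" = 12.0, "2017-05" = 9.5,  "2017-06" = 11.0,
    "2017-07" = 15.8, "2017-08" = 20.0, "2017-09" = 22.0, "2017-10" = 32.0)
}

#' Generator parameters for the synthetic study system
#'
#' Bundles every coefficient and variance needed to simulate the coupled
#' climate, prey, daily body-temperature and 5-min trace datasets. The fixed
#' effect defaults of the three body-temperature models are the study's
#' reported coefficient tables; variance components are not reported anywhere
#' and are stated here as configuration.
#'
#' @param climate list: \code{mean} and \code{annual_amplitude} of the annual
#'   globe-temperature sinusoid (degC), \code{diurnal_semiamp} (degC),
#'   \code{year2_min_offset} and \code{year2_mean_offset} (degC, applied to the
#'   24-h minimum and mean in study year 2), \code{noise_sd} (degC),
#'   \code{latitude} (decimal degrees, drives the photoperiod curve).
#' @param prey list: \code{monthly_means} named vector of true mean ants/trap
#'   per month, \code{dispersion} (negative binomial size of the transect
#'   total), \code{n_transects}, \code{tubes_per_transect}.
#' @param tb_min_model,tb_max_model,tb_amp_model fixed-effect coefficients of
#'   the three generating models (intercept, photoperiod, prey slope below and
#'   above the knot, the matching globe metric, the knot in ants/trap, and for
#'   the maximum model the emergence-time slope in degC/h).
#' @param variances list of animal random-intercept SDs and residual SDs (degC)
#'   per response, plus the SD of the daily mean around its expected position
#'   between the minimum and maximum.
#' @param emergence list: per-season mean emergence time (decimal hours) and
#'   half-width of the uniform window; return-time window (hours after
#'   midnight). Winter emergence sits in daylight, matching the observed winter
#'   shift to diurnal activity.
#' @param trace list of trace-shape parameters: \code{event_rate} (degC/h of
#'   the fast emergence/return ramps), \code{rise_rate} (degC/h of the slow
#'   rewarming from the daily minimum), \code{rest_fraction} (resting plateau
#'   position between daily min and max), \code{plateau_offset} (degC below the
#'   daily maximum of the active-phase plateau), \code{noise_sd} (degC),
#'   \code{notch_min} (degC, detectability threshold) and
#'   \code{notch_max_duration} (minutes).
#' @param camera list: \code{detection_prob}, \code{jitter_sd} (minutes).
#' @param n_animals number of simulated animals.
#' @return Object of class \code{"generator_params"} (a validated list).
#' @export
generator_params <- function(climate = list(), prey = list(),
                             tb_min_model = list(), tb_max_model = list(),
                             tb_amp_model = list(), variances = list(),
                             emergence = list(), trace = list(),
                             camera = list(), n_animals = 7) {
  p <- list(
    climate = utils::modifyList(list(
      mean = 20.5, annual_amplitude = 8, diurnal_semiamp = 9.5,
      year2_min_offset = -4.0, year2_mean_offset = 2.1,
      noise_sd = 0.8, latitude = -27.22, peak_doy = 15), climate),
    prey = utils::modifyList(list(
      monthly_means = default_prey_monthly(), dispersion = 8,
      n_transects = 30, tubes_per_transect = 10), prey),
    tb_min_model = utils::modifyList(list(
      intercept = 31.30, photoperiod = 0.09, prey_below = 0.10,
      prey_above = 0.0, globe = 0.02, knot = 9), tb_min_model),
    tb_max_model = utils::modifyList(list(
      intercept = 36.18, photoperiod = 0.05, prey_below = -0.03,
      prey_above = 0.0, globe = 0.03, emergence = -0.11, knot = 10),
      tb_max_model),
    tb_amp_model = utils::modifyList(list(
      intercept = 5.29, photoperiod = -0.20, prey_below = -0.11,
      prey_above = 0.0, globe = 0.0, knot = 10), tb_amp_model),
    variances = utils::modifyList(list(
      re_sd = c(tb_min = 0.15, tb_max = 0.20, tb_amplitude = 0.20),
      resid_sd = c(tb_min = 0.22, tb_max = 0.18, tb_amplitude = 0.40),
      mean_sd = 0.10), variances),
    emergence = utils::modifyList(list(
      mean = c(summer = 19.60, autumn = 19.00, winter = 16.93, spring = 19.30),
      halfwidth = c(summer = 1.0, autumn = 1.0, winter = 1.9, spring = 1.0),
      return_window = c(1.5, 3.5)), emergence),
    trace = utils::modifyList(list(
      event_rate = 3.2, rise_rate = 0.48, rest_fraction = 0.66,
      plateau_offset = 0.40, noise_sd = 0.005,
      notch_min = 0.5, notch_max_duration = 60), trace),
    camera = utils::modifyList(list(detection_prob = 0.6, jitter_sd = 10),
                               camera),
    n_animals = n_animals
  )
  class(p) <- "generator_params"
  validate_params(p)
  p
}

#' Validate generator parameters
#'
#' @param p a \code{generator_params} object.
#' @return \code{p}, invisibly, or an error describing the violated invariant.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  if (any(p$prey$monthly_means <= 0))
    stop_invalid("prey monthly means must be > 0")
  if (p$prey$dispersion <= 0) stop_invalid("NB dispersion must be > 0")
  sds <- c(p$variances$re_sd, p$variances$resid_sd, p$variances$mean_sd,
           p$climate$noise_sd, p$trace$noise_sd, p$camera$jitter_sd)
  if (any(sds < 0)) stop_invalid("all SDs must be >= 0")
  knots <- c(p$tb_min_model$knot, p$tb_max_model$knot, p$tb_amp_model$knot)
  if (any(knots < 0 | knots > 18))
    stop_invalid("knots must lie in [0, 18] ants/trap")
  if (p$camera$detection_prob < 0 || p$camera$detection_prob > 1)
    stop_invalid("detection_prob must lie in [0, 1]")
  if (p$n_animals < 1) stop_invalid("need at least one animal")
  invisible(p)
}

# season-specific emergence window (uniform bounds in decimal hours)
emergence_window <- function(p, season) {
  m <- p$emergence$mean[[season]]
  h <- p$emergence$halfwidth[[season]]
  c(m - h, m + h)
}
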