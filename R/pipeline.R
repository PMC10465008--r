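#' Pipeline configuration
#'
#' One structured object holds every tunable of an end-to-end run. In
#' \code{"simulate"} mode the generator parameters and a master seed are
#' mandatory; in \code{"ingest"} mode the input paths must exist.
#'
#' @param mode \code{"simulate"} or \code{"ingest"}.
#' @param params \code{\link{generator_params}} (simulate mode).
#' @param inputs named list of paths (ingest mode): \code{trace_dir},
#'   \code{climate}, \code{sun}, \code{prey}, \code{camera}.
#' @param seed master seed (mandatory in simulate mode).
#' @param outdir output directory, or \code{NULL} to skip writing files.
#' @param completeness day-completeness threshold for 24-h summaries.
#' @param event_threshold,event_window notch rule (degC, minutes).
#' @param emergence_window linear time-of-day window, decimal hours.
#' @param knot_grid candidate breakpoints, ants/trap.
#' @param exclusions data.frame(season, study_year) blocks dropped from the
#'   climate summaries (e.g. a weather-station failure), or \code{NULL}.
#' @param start,end simulation window (simulate mode).
#' @param stages subset of
#'   \code{c("simulate", "summaries", "activity", "models", "report")}.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            params = generator_params(), inputs = NULL,
                            seed = NULL, outdir = NULL, completeness = 0.8,
                            event_threshold = 0.5, event_window = 60,
                            emergence_window = c(4, 23 + 55 / 60),
                            knot_grid = 0:18, exclusions = NULL,
                            start = study_calendar()$start,
                            end = study_calendar()$end,
                            stages = c("simulate", "summaries", "activity",
                                       "models", "report")) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed))
    stop_invalid("simulate mode requires an explicit seed")
  if (mode == "ingest") {
    if (is.null(inputs)) stop_invalid("ingest mode requires input paths")
    missing <- !vapply(unlist(inputs), file.exists, logical(1))
    if (any(missing))
      stop_invalid("missing input path(s): %s",
                   paste(unlist(inputs)[missing], collapse = ", "))
  }
  structure(list(mode = mode, params = params, inputs = inputs, seed = seed,
                 outdir = outdir, completeness = completeness,
                 event_threshold = event_threshold,
                 event_window = event_window,
                 emergence_window = emergence_window, knot_grid = knot_grid,
                 exclusions = exclusions, start = start, end = end,
                 stages = stages),
            class = "pipeline_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: data simulation (or ingest), 24-h summaries,
#' activity detection and reconciliation, the three linear-spline mixed
#' models with AIC breakpoint search (robust standard errors where
#' heteroskedasticity is detected) plus the negative binomial prey model, and
#' the summary report. Every artefact carries the configuration hash and
#' seed; a stage failure stops the run with the completed stages recorded in
#' the error condition.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{"pipeline_run"}: a manifest plus every stage
#'   output (\code{dataset}, \code{daily}, \code{climate_daily},
#'   \code{inferred}, \code{events}, \code{emergence}, \code{analysis},
#'   \code{models}, \code{prey_model}, \code{report}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- list(manifest = list(mode = config$mode, seed = config$seed,
                              config_hash = config_hash(config),
                              completed = character(0)))
  done <- function(stage) run$manifest$completed <<- c(run$manifest$completed,
                                                       stage)
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("pipeline_error", "error", "condition"),
                     list(message = sprintf("stage '%s' failed: %s", stage,
                                            conditionMessage(e)),
                          call = NULL, stage = stage,
                          completed = run$manifest$completed)))
    })
  }

  if ("simulate" %in% config$stages || config$mode == "ingest") {
    if (config$mode == "simulate") {
      run$dataset <- wrap("simulate",
                          simulate_dataset(config$params, config$seed,
                                           start = config$start,
                                           end = config$end))
      stage_log("simulate", "7-animal dataset: %d daily rows, %d true events",
                nrow(run$dataset$daily), NROW(run$dataset$events))
    } else {
      run$dataset <- wrap("ingest", ingest_dataset(config))
      stage_log("ingest", "%d trace file(s) read", length(run$dataset$traces))
    }
    done("simulate")
  }

  if ("summaries" %in% config$stages) {
    run$daily <- wrap("summaries", {
      do.call(rbind, lapply(run$dataset$traces, daily_tb_summary,
                            completeness = config$completeness))
    })
    rownames(run$daily) <- NULL
    cd <- run$dataset$climate_daily %||%
      daily_globe_summary(run$dataset$climate, run$dataset$sun)
    if (!is.null(config$exclusions) && nrow(config$exclusions)) {
      key <- paste(assign_season(cd$date), assign_study_year(cd$date))
      drop <- key %in% paste(config$exclusions$season,
                             config$exclusions$study_year)
      stage_log("summaries", "excluded %d climate day(s) per config",
                sum(drop))
      cd <- cd[!drop, ]
    }
    run$climate_daily <- cd
    run$prey <- wrap("summaries", prey_per_trap(run$dataset$prey_survey))
    stage_log("summaries", "%d animal-days summarised", nrow(run$daily))
    done("summaries")
  }

  if ("activity" %in% config$stages) {
    run$inferred <- wrap("activity", {
      out <- do.call(rbind, lapply(run$dataset$traces, function(s) {
        classify_events(detect_events(s, config$event_threshold,
                                      config$event_window), s)
      }))
      rownames(out) <- NULL
      out
    })
    run$events <- wrap("activity",
                       reconcile_sources(run$dataset$camera, run$inferred))
    run$emergence <- wrap("activity",
                          emergence_covariate(run$events,
                                              config$emergence_window))
    stage_log("activity", "%d reconciled events, %d emergence covariate rows",
              nrow(run$events), nrow(run$emergence))
    done("activity")
  }

  if ("models" %in% config$stages) {
    run$analysis <- wrap("models", {
      emerg <- run$emergence
      cov <- daily_covariates(run$climate_daily,
                              stats::setNames(run$prey$monthly,
                                              c("month", "prey_mean")),
                              emerg)
      merge(run$daily, cov, by = c("animal_id", "date"))
    })
    run$models <- wrap("models", lapply(
      c("tb_min", "tb_max", "tb_amplitude"), function(resp) {
        spec <- model_spec(resp, config$knot_grid)
        sel <- breakpoint_search(spec, run$analysis)
        fit <- sel$best_fit
        diag_ <- run_diagnostics(fit)
        if (diag_$heteroskedastic && fit$n_groups >= 2)
          fit <- robust_se(fit)
        stage_log("models", "%s: knot %d, AIC %.1f, n %d", resp,
                  sel$best_knot, fit$AIC, fit$n_obs)
        list(response = resp, fit = fit, aic_table = sel$aic_table,
             diagnostics = diag_)
      }))
    names(run$models) <- c("tb_min", "tb_max", "tb_amplitude")
    run$prey_model <- wrap("models", fit_nb_counts(run$dataset$prey_survey))
    done("models")
  }

  if ("report" %in% config$stages) {
    run$report <- wrap("report", summarize_run(run))
    done("report")
  }

  class(run) <- "pipeline_run"
  if (!is.null(config$outdir)) write_run(run, config)
  run
}

# read a simulated-layout directory back into the dataset structure
ingest_dataset <- function(config) {
  ins <- config$inputs
  trace_files <- list.files(ins$trace_dir, pattern = "^trace_.*\\.csv$",
                            full.names = TRUE)
  traces <- lapply(trace_files, function(f)
    parse_logger_csv(f, animal_id = sub("^trace_", "",
                                        sub("\\.csv$", "", basename(f)))))
  names(traces) <- vapply(traces, `[[`, "", "animal_id")
  clim <- utils::read.csv(ins$climate)
  clim$timestamp <- as.POSIXct(clim$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")
  sun <- utils::read.csv(ins$sun)
  sun$date <- as.Date(sun$date)
  camera <- NULL
  if (!is.null(ins$camera)) {
    camera <- utils::read.csv(ins$camera)
    camera$timestamp <- as.POSIXct(camera$timestamp,
                                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  list(traces = traces, climate = clim, sun = sun,
       climate_daily = daily_globe_summary(clim, sun),
       prey_survey = utils::read.csv(ins$prey), camera = camera)
}

#' Summarise a pipeline run
#'
#' Produces the season and study-year contrasts of every 24-h body
#' temperature metric (cell means with standard errors, year-2 minus year-1
#' contrasts averaged across seasons, and the summer-vs-winter amplitude
#' contrast averaged across years), alongside the fitted model tables when
#' present. Sections are marked \code{"no data"} when the daily table is
#' empty.
#'
#' @param run a \code{pipeline_run} (or a list with a \code{daily} element).
#' @return list of class \code{"run_report"}.
#' @export
summarize_run <- function(run) {
  daily <- run$daily
  metrics <- c("tb_min", "tb_max", "tb_mean", "tb_amplitude")
  if (is.null(daily) || nrow(daily) == 0) {
    return(structure(list(cells = "no data", year_contrasts = "no data",
                          season_contrasts = "no data"),
                     class = "run_report"))
  }
  d <- daily[daily$season != "excluded-Nov" & daily$study_year != "outside", ]
  cells <- do.call(rbind, lapply(
    split(d, list(d$season, d$study_year), drop = TRUE), function(s) {
      out <- data.frame(season = s$season[1], study_year = s$study_year[1],
                        n = nrow(s))
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(s[[m]])
        out[[paste0(m, "_se")]] <- stats::sd(s[[m]]) / sqrt(nrow(s))
      }
      out
    }))
  rownames(cells) <- NULL
  years <- sort(unique(cells$study_year))
  year_contrasts <- NULL
  if (length(years) == 2) {
    y1 <- cells[cells$study_year == years[1], ]
    y2 <- cells[cells$study_year == years[2], ]
    common <- intersect(y1$season, y2$season)
    y1 <- y1[match(common, y1$season), ]; y2 <- y2[match(common, y2$season), ]
    year_contrasts <- do.call(rbind, lapply(metrics, function(m) {
      diffs <- y2[[paste0(m, "_mean")]] - y1[[paste0(m, "_mean")]]
      se <- sqrt(sum(y1[[paste0(m, "_se")]]^2 + y2[[paste0(m, "_se")]]^2)) /
        length(common)
      data.frame(metric = m, contrast = "year2 - year1",
                 estimate = mean(diffs), se = se)
    }))
  }
  season_contrasts <- NULL
  if (all(c("summer", "winter") %in% cells$season)) {
    season_contrasts <- do.call(rbind, lapply(metrics, function(m) {
      per_year <- vapply(years, function(y) {
        cs <- cells[cells$study_year == y, ]
        if (!all(c("summer", "winter") %in% cs$season)) return(NA_real_)
        cs[[paste0(m, "_mean")]][cs$season == "winter"] -
          cs[[paste0(m, "_mean")]][cs$season == "summer"]
      }, numeric(1))
      data.frame(metric = m, contrast = "winter - summer",
                 estimate = mean(per_year, na.rm = TRUE))
    }))
  }
  structure(list(cells = cells, year_contrasts = year_contrasts,
                 season_contrasts = season_contrasts,
                 models = if (!is.null(run$models))
                   lapply(run$models, function(m) m$fit$coefficients)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Season x study-year cell means\n")
  if (is.character(x$cells)) cat("  no data\n") else
    print(x$cells, digits = 4, row.names = FALSE)
  cat("\nYear contrasts (averaged across seasons)\n")
  if (is.null(x$year_contrasts)) cat("  single year: year row absent\n")
  else if (is.character(x$year_contrasts)) cat("  no data\n")
  else print(x$year_contrasts, digits = 3, row.names = FALSE)
  cat("\nSeason contrasts (averaged across years)\n")
  if (is.null(x$season_contrasts) || is.character(x$season_contrasts))
    cat("  no data\n")
  else print(x$season_contrasts, digits = 3, row.names = FALSE)
  invisible(x)
}

# write the standard artefact set for a completed run
write_run <- function(run, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$config_hash <- run$manifest$config_hash
    df$seed <- config$seed %||% NA
    df
  }
  w <- function(df, f) utils::write.csv(stamp(df), file.path(config$outdir, f),
                                        row.names = FALSE)
  if (!is.null(run$daily)) w(run$daily, "daily_tb.csv")
  if (!is.null(run$climate_daily)) w(run$climate_daily, "daily_climate.csv")
  if (!is.null(run$prey)) w(run$prey$monthly, "prey_monthly.csv")
  if (!is.null(run$events)) {
    ev <- run$events
    ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
    w(ev, "events.csv")
  }
  if (!is.null(run$models)) {
    for (i in seq_along(run$models))
      w(run$models[[i]]$fit$coefficients, paste0("table", i, ".csv"))
    aic <- do.call(rbind, lapply(run$models, function(m)
      cbind(response = m$response, m$aic_table)))
    w(aic, "aic_search.csv")
    diags <- lapply(run$models, function(m)
      m$diagnostics[c("max_cooks_d", "cooks_flag", "max_vif", "vif_flag",
                      "bp_p", "heteroskedastic", "shapiro_w")])
    jsonlite::write_json(diags, file.path(config$outdir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$outdir)
}
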