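#' Detect abrupt body-temperature notches
#'
#' Implements the notch rule: a candidate event exists wherever body
#' temperature rises or falls by at least \code{threshold} degC over strictly
#' less than \code{window} minutes (closed inequality on the magnitude, strict
#' on the window). Overlapping candidates in the same direction merge into a
#' single event, timed at the start of the steepest single 5-min change
#' (earliest wins on ties).
#'
#' @param series a \code{tb_series} (drift-corrected) or a data.frame with
#'   \code{timestamp} and \code{tb_c}.
#' @param threshold minimum absolute change, degC.
#' @param window scan horizon, minutes (exclusive).
#' @return data.frame of candidates: \code{animal_id}, \code{timestamp},
#'   \code{direction} (+1 rise / -1 fall), \code{delta_tb} (signed change of
#'   the strongest qualifying pair), \code{span} (its duration, minutes),
#'   \code{start}, \code{end} (merged extent). Zero rows when the trace never
#'   breaks the rule.
#' @export
detect_events <- function(series, threshold = 0.5, window = 60) {
  df <- as_tb_frame(series)
  aid <- if (inherits(series, "tb_series")) series$animal_id else
    (df$animal_id[1] %||% NA_character_)
  x <- df$tb_c
  tt <- as.numeric(df$timestamp)
  n <- length(x)
  empty <- data.frame(animal_id = character(0), timestamp = df$timestamp[0],
                      direction = integer(0), delta_tb = numeric(0),
                      span = numeric(0), start = df$timestamp[0],
                      end = df$timestamp[0])
  if (n < 2) return(empty)
  max_lag <- max(1L, ceiling(window / 5) + 1L)
  pairs <- vector("list", max_lag)
  for (L in seq_len(min(max_lag, n - 1L))) {
    i <- seq_len(n - L)
    dt <- (tt[i + L] - tt[i]) / 60
    d <- x[i + L] - x[i]
    q <- which(dt < window & dt > 0 & abs(d) >= threshold)
    if (length(q))
      pairs[[L]] <- data.frame(i = q, j = q + L, d = d[q], dt = dt[q])
  }
  pr <- do.call(rbind, pairs)
  if (is.null(pr) || nrow(pr) == 0) return(empty)
  pr$dir <- sign(pr$d)
  out <- lapply(split(pr, pr$dir), function(p) {
    p <- p[order(tt[p$i], tt[p$j]), ]
    run_end <- cummax(tt[p$j])
    grp <- cumsum(c(TRUE, tt[p$i][-1] > run_end[-nrow(p)]))
    do.call(rbind, lapply(split(p, grp), function(g) {
      best <- which(abs(g$d) == max(abs(g$d)))[1]
      i0 <- min(g$i); i1 <- max(g$j)
      steps <- (x[(i0 + 1):i1] - x[i0:(i1 - 1)]) * g$dir[1]
      k <- i0 + which.max(steps) - 1L
      data.frame(timestamp = df$timestamp[k], direction = g$dir[1],
                 delta_tb = g$d[best], span = g$dt[best],
                 start = df$timestamp[i0], end = df$timestamp[i1])
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$timestamp), ]
  rownames(out) <- NULL
  cbind(animal_id = aid, out)
}

# left-aligned rolling range flags: TRUE where the window starting at sample i
# and spanning `span_min` minutes has range < range_max
quiescent_starts <- function(df, span_min, range_max) {
  x <- df$tb_c
  k <- as.integer(span_min / 5) + 1L
  n <- length(x)
  if (n < k) return(logical(n))
  hi <- zoo::rollmax(x, k, align = "left", fill = NA)
  lo <- -zoo::rollmax(-x, k, align = "left", fill = NA)
  ok <- !is.na(hi) & (hi - lo) < range_max
  # windows containing a recording gap are not trustworthy
  dt <- diff(as.numeric(df$timestamp))
  gap_after <- c(dt > 450, FALSE)
  if (any(gap_after)) {
    bad <- which(gap_after)
    for (b in bad) ok[max(1, b - k + 1):min(n, b)] <- FALSE
  }
  ok
}

#' Label candidate notches as emergence or return
#'
#' An emergence leaves the burrow rest phase: the candidate must be preceded
#' (within a grace interval) by at least \code{quiescence_span} minutes of
#' quiescence (range below \code{quiescence_range} degC) sitting in the lower
#' part of the trailing 24-h body-temperature range, where resting
#' heterotherms spend the rest phase. A return enters such a low quiescent
#' state after the candidate. Labels alternate along the series
#' (emergence, return, emergence, ...); candidates fitting neither slot are
#' dropped and counted in the \code{"dropped"} attribute. The sign of the
#' notch is never used: leaving the burrow can warm (day) or cool (night)
#' the animal.
#'
#' @param candidates output of \code{\link{detect_events}}.
#' @param series the same series the candidates came from.
#' @param quiescence_range degC.
#' @param quiescence_span minutes.
#' @param grace maximum minutes between the quiescent window and the event.
#' @param low_fraction a quiescent level counts as the rest phase when it lies
#'   below this fraction of the trailing 24-h range.
#' @return data.frame of labelled events: \code{animal_id}, \code{timestamp},
#'   \code{kind}, \code{source = "tb_inferred"}, \code{delta_tb}, \code{span}.
#' @export
classify_events <- function(candidates, series, quiescence_range = 0.25,
                            quiescence_span = 120, grace = 240,
                            low_fraction = 0.72) {
  df <- as_tb_frame(series)
  aid <- if (inherits(series, "tb_series")) series$animal_id else
    (df$animal_id[1] %||% NA_character_)
  out <- data.frame(animal_id = character(0), timestamp = df$timestamp[0],
                    kind = character(0), source = character(0),
                    delta_tb = numeric(0), span = numeric(0))
  if (is.null(candidates) || nrow(candidates) == 0) return(out)
  qs <- quiescent_starts(df, quiescence_span, quiescence_range)
  tt <- as.numeric(df$timestamp)
  tq <- tt[qs]                               # quiescent window starts
  tq_end <- tq + quiescence_span * 60
  idx_range <- function(from, to) {
    i0 <- findInterval(from, tt) + 1L
    i1 <- findInterval(to, tt)
    if (i1 < i0) integer(0) else i0:i1
  }
  level_near <- function(from, to) {
    idx <- idx_range(from, to)
    if (!length(idx)) return(NA_real_)
    stats::median(df$tb_c[idx])
  }
  is_low <- function(level, t_ref) {
    idx <- idx_range(t_ref - 86400, t_ref)
    if (!length(idx) || is.na(level)) return(FALSE)
    lo <- min(df$tb_c[idx]); hi <- max(df$tb_c[idx])
    hi - lo < 0.3 || level <= lo + low_fraction * (hi - lo)
  }
  seek <- "emergence"
  rows <- list(); dropped <- 0L
  label <- function(cand, kind) data.frame(
    animal_id = aid, timestamp = cand$timestamp, kind = kind,
    source = "tb_inferred", delta_tb = cand$delta_tb, span = cand$span)
  for (r in seq_len(nrow(candidates))) {
    cand <- candidates[r, ]
    t0 <- as.numeric(cand$start); t1 <- as.numeric(cand$end)
    pre_q <- any(tq_end >= t0 - grace * 60 & tq_end <= t0 + 300)
    post_q <- any(tq >= t1 - 300 & tq <= t1 + grace * 60)
    is_em <- pre_q && is_low(level_near(t0 - 3300, t0 - 300), t0)
    is_re <- post_q && is_low(level_near(t1 + 300, t1 + 3300), t1)
    if (seek == "emergence") {
      if (is_em) {
        rows[[length(rows) + 1]] <- label(cand, "emergence")
        seek <- "return"
      } else dropped <- dropped + 1L
    } else {
      if (is_re) {
        rows[[length(rows) + 1]] <- label(cand, "return")
        seek <- "emergence"
      } else if (is_em) {  # the previous return was missed; start a new cycle
        rows[[length(rows) + 1]] <- label(cand, "emergence")
      } else dropped <- dropped + 1L
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else out
  attr(res, "dropped") <- dropped
  res
}

#' Merge camera and body-temperature-inferred events
#'
#' Camera observations take precedence; inferred events fill animal-days the
#' cameras missed. When both sources fall within \code{tolerance} minutes the
#' camera time is kept; larger disagreements also resolve to the camera but
#' are flagged.
#'
#' @param camera data.frame \code{animal_id}, \code{timestamp}, \code{kind}.
#' @param inferred labelled events from \code{\link{classify_events}}.
#' @param tolerance minutes.
#' @return Per animal-day-kind event table with a \code{source} column and a
#'   \code{conflict} flag.
#' @export
reconcile_sources <- function(camera, inferred, tolerance = 60) {
  key <- function(e) paste(e$animal_id, as.Date(format(e$timestamp, "%Y-%m-%d")),
                           e$kind)
  cam <- if (!is.null(camera) && nrow(camera)) {
    camera$source <- "camera"
    camera[!duplicated(key(camera)), c("animal_id", "timestamp", "kind", "source")]
  } else NULL
  inf <- if (!is.null(inferred) && nrow(inferred))
    inferred[!duplicated(key(inferred)),
             c("animal_id", "timestamp", "kind", "source")] else NULL
  if (is.null(cam) && is.null(inf))
    return(data.frame(animal_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      kind = character(0), source = character(0),
                      conflict = logical(0)))
  out <- cam
  conflict <- rep(FALSE, NROW(cam))
  if (!is.null(inf)) {
    if (!is.null(cam)) {
      m <- match(key(inf), key(cam))
      both <- !is.na(m)
      dt <- abs(as.numeric(inf$timestamp[both]) -
                  as.numeric(cam$timestamp[m[both]])) / 60
      conflict[m[both]] <- dt > tolerance
      inf <- inf[!both, , drop = FALSE]
    }
    out <- rbind(out, inf)
    conflict <- c(conflict, rep(FALSE, nrow(inf)))
  }
  out$conflict <- conflict
  out$date <- as.Date(format(out$timestamp, "%Y-%m-%d"))
  out <- out[order(out$animal_id, out$timestamp), ]
  rownames(out) <- NULL
  out
}

#' Emergence-time covariate on the linear 04:00-23:55 window
#'
#' Time of day is circular; restricting emergence times to 04:00-23:55 makes
#' them usable as a linear covariate at the cost of dropping the few events
#' outside the window (those animal-days are lost to the 24-h maximum model
#' only).
#'
#' @param events reconciled event table.
#' @param window decimal-hour bounds, default \code{c(4, 23 + 55/60)}.
#' @return data.frame \code{animal_id}, \code{date}, \code{emergence_h}.
#' @export
emergence_covariate <- function(events, window = c(4, 23 + 55 / 60)) {
  em <- events[events$kind == "emergence", , drop = FALSE]
  h <- as.integer(format(em$timestamp, "%H")) +
    as.integer(format(em$timestamp, "%M")) / 60 +
    as.integer(format(em$timestamp, "%S")) / 3600
  keep <- h >= window[1] & h <= window[2]
  if (any(!keep))
    message(sprintf("emergence_covariate: dropped %d time(s) outside %05.2f-%05.2f",
                    sum(!keep), window[1], window[2]))
  data.frame(animal_id = em$animal_id[keep],
             date = as.Date(format(em$timestamp[keep], "%Y-%m-%d")),
             emergence_h = h[keep])
}

#' Agreement between inferred and camera event times
#'
#' Pairs animal-day-kind events present in both sources and reports the
#' median absolute time difference and the fraction of pairs within each
#' tolerance. No pass/fail judgement is encoded.
#'
#' @param inferred,camera event tables with \code{animal_id},
#'   \code{timestamp}, \code{kind}.
#' @param tolerances minutes.
#' @return list: \code{n_pairs}, \code{median_abs_dt_min},
#'   \code{within} (named fractions).
#' @export
validate_against_camera <- function(inferred, camera,
                                    tolerances = c(15, 30, 60)) {
  key <- function(e) paste(e$animal_id, as.Date(format(e$timestamp, "%Y-%m-%d")),
                           e$kind)
  m <- match(key(inferred), key(camera))
  ok <- !is.na(m)
  if (!any(ok)) {
    warning("no overlapping animal-day events between sources")
    return(list(n_pairs = 0L, median_abs_dt_min = NA_real_,
                within = stats::setNames(rep(NA_real_, length(tolerances)),
                                         paste0("within_", tolerances, "min"))))
  }
  dt <- abs(as.numeric(inferred$timestamp[ok]) -
              as.numeric(camera$timestamp[m[ok]])) / 60
  list(n_pairs = sum(ok),
       median_abs_dt_min = stats::median(dt),
       within = stats::setNames(vapply(tolerances,
                                       function(to) mean(dt <= to), numeric(1)),
                                paste0("within_", tolerances, "min")))
}
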