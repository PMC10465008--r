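#' Linear-spline (piecewise) basis
#'
#' For a knot \code{k} the two basis columns are \code{b1 = min(x, k)} and
#' \code{b2 = max(x - k, 0)}, so the coefficients on \code{b1}/\code{b2} are
#' the slopes below and above the knot and the fitted line is continuous at
#' the knot.
#'
#' @param x numeric vector.
#' @param knot finite breakpoint.
#' @return Two-column matrix \code{b1}, \code{b2}.
#' @export
lspline_basis <- function(x, knot) {
  stopifnot(is.finite(knot))
  cbind(b1 = pmin(x, knot), b2 = pmax(x - knot, 0))
}

#' Specify one of the three body-temperature models
#'
#' Fixed terms are photoperiod, the prey linear-spline pair and the matching
#' 24-h globe metric; the 24-h maximum model additionally (and only that
#' model) carries the time of burrow emergence. Grouping is always the
#' individual animal.
#'
#' @param response \code{"tb_min"}, \code{"tb_max"} or \code{"tb_amplitude"}.
#' @param knot_grid candidate breakpoints, ants/trap (must lie in [0, 18]).
#' @return list of class \code{"model_spec"}.
#' @export
model_spec <- function(response = c("tb_min", "tb_max", "tb_amplitude"),
                       knot_grid = 0:18) {
  response <- match.arg(response)
  if (any(knot_grid < 0 | knot_grid > 18))
    stop_invalid("knot grid must lie within [0, 18] ants/trap")
  globe <- c(tb_min = "globe_min", tb_max = "globe_max",
             tb_amplitude = "globe_amplitude")[[response]]
  structure(list(response = response,
                 globe_term = globe,
                 emergence = response == "tb_max",
                 knot_grid = knot_grid,
                 grouping = "animal_id"),
            class = "model_spec")
}

term_labels <- function(spec, knot) {
  lab <- c("Intercept", "Photoperiod",
           sprintf("Prey abundance (<%s ants/trap)", format(knot)),
           sprintf("Prey abundance (>%s ants/trap)", format(knot)),
           c(globe_min = "24-h minimum black globe temperature",
             globe_max = "24-h maximum black globe temperature",
             globe_amplitude = "24-h black globe temperature amplitude"
           )[[spec$globe_term]])
  if (spec$emergence) lab <- c(lab, "Time of emergence from burrow")
  lab
}

model_frame <- function(spec, data, knot) {
  need <- c(spec$response, "photoperiod", "prey", spec$globe_term,
            spec$grouping, if (spec$emergence) "emergence_h")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_invalid("missing column(s): %s",
                                 paste(miss, collapse = ", "))
  d <- data[, need]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message(sprintf("fit_mixed: %d incomplete row(s) dropped",
                                sum(!cc)))
  d <- d[cc, ]
  b <- lspline_basis(d$prey, knot)
  d$prey_b1 <- b[, 1]; d$prey_b2 <- b[, 2]
  d
}

#' Fit a random-intercept linear-spline mixed model at a fixed knot
#'
#' Fits, by maximum likelihood, the linear mixed model of the chosen 24-h
#' body-temperature metric on photoperiod, the prey spline pair at
#' \code{knot}, the matching globe metric (and emergence time for the 24-h
#' maximum), with individual animals as a random intercept. With a single
#' animal the model degenerates to ordinary least squares. A singular fit
#' (zero animal variance) is returned with a warning flag, not an error.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data daily analysis table (complete cases used, drops logged).
#' @param knot breakpoint in ants/trap.
#' @return Object of class \code{"spline_model_fit"}: coefficient table in the
#'   reported layout, variance components, log-likelihood, AIC, sample sizes,
#'   and the underlying fit.
#' @export
fit_mixed <- function(spec, data, knot) {
  d <- model_frame(spec, data, knot)
  rhs <- paste(c("photoperiod", "prey_b1", "prey_b2", spec$globe_term,
                 if (spec$emergence) "emergence_h"), collapse = " + ")
  n_groups <- length(unique(d[[spec$grouping]]))
  singular <- FALSE
  if (n_groups >= 2) {
    f <- stats::as.formula(paste(spec$response, "~", rhs, "+ (1|",
                                 spec$grouping, ")"))
    fit <- suppressMessages(
      lme4::lmer(f, data = d, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")))
    singular <- lme4::isSingular(fit)
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    tau2 <- as.numeric(vc[[spec$grouping]])
    sig2 <- attr(vc, "sc")^2
    ll <- as.numeric(stats::logLik(fit))
    npar <- attr(stats::logLik(fit), "df")
  } else {
    f <- stats::as.formula(paste(spec$response, "~", rhs))
    fit <- stats::lm(f, data = d)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tau2 <- 0
    sig2 <- summary(fit)$sigma^2
    ll <- as.numeric(stats::logLik(fit))
    npar <- attr(stats::logLik(fit), "df")
  }
  # aliased columns (e.g. an empty above-knot basis) come back NA-padded
  full <- c("(Intercept)", "photoperiod", "prey_b1", "prey_b2",
            spec$globe_term, if (spec$emergence) "emergence_h")
  vc <- as.matrix(stats::vcov(fit))
  est <- stats::setNames(rep(NA_real_, length(full)), full)
  est[names(beta)] <- beta
  sev <- stats::setNames(rep(NA_real_, length(full)), full)
  sev[colnames(vc)] <- sqrt(diag(vc))
  beta <- est; se <- sev
  tab <- data.frame(
    term = term_labels(spec, knot),
    estimate = unname(beta),
    se = unname(se),
    ci_lo = unname(beta - 1.96 * se),
    ci_hi = unname(beta + 1.96 * se),
    t = unname(beta / se),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    robust_se = NA_real_
  )
  structure(list(spec = spec, knot = knot, coefficients = tab,
                 re_var = tau2, resid_var = sig2,
                 logLik = ll, n_par = npar, AIC = 2 * npar - 2 * ll,
                 n_obs = nrow(d), n_groups = n_groups,
                 singular = singular, fit = fit, frame = d),
            class = "spline_model_fit")
}

#' @export
print.spline_model_fit <- function(x, ...) {
  cat(sprintf("Linear-spline mixed model: %s, knot %s ants/trap%s\n",
              x$spec$response, format(x$knot),
              if (x$singular) " (singular random effect)" else ""))
  cat(sprintf("n = %d observations, %d animal(s); AIC = %.1f\n\n",
              x$n_obs, x$n_groups, x$AIC))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' AIC-driven breakpoint search
#'
#' Refits the model at every candidate knot by maximum likelihood and selects
#' the knot with minimal AIC (ties go to the smallest knot). Knots whose fit
#' fails are recorded as \code{NA} and excluded from the argmin.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data daily analysis table.
#' @param grid candidate knots; defaults to the model specification's grid
#'   (integers 0-18 ants/trap).
#' @return list: \code{best_knot}, \code{best_fit} (refitted at the chosen
#'   knot), \code{aic_table} (knot, AIC, logLik, status).
#' @export
breakpoint_search <- function(spec, data, grid = spec$knot_grid) {
  if (!length(grid)) stop_invalid("empty knot grid")
  rows <- lapply(sort(grid), function(k) {
    f <- tryCatch(suppressMessages(fit_mixed(spec, data, k)),
                  error = function(e) NULL)
    if (is.null(f))
      data.frame(knot = k, AIC = NA_real_, logLik = NA_real_, status = "failed")
    else data.frame(knot = k, AIC = f$AIC, logLik = f$logLik, status = "ok")
  })
  aic <- do.call(rbind, rows)
  ok <- which(!is.na(aic$AIC))
  if (!length(ok)) stop_invalid("all knot fits failed")
  best <- aic$knot[ok[which.min(aic$AIC[ok])]]
  list(best_knot = best,
       best_fit = suppressMessages(fit_mixed(spec, data, best)),
       aic_table = aic)
}

#' Cluster-robust (sandwich) standard errors for a spline model fit
#'
#' Replaces the model-based standard errors with heteroskedasticity-consistent
#' standard errors aggregated within animals (the repeated-measures unit),
#' using the marginal residuals and the fitted compound-symmetry covariance;
#' a CR1 small-sample factor G/(G-1) is applied. Estimates are unchanged.
#'
#' @param fit a \code{\link{fit_mixed}} result.
#' @param cluster column name to cluster on (defaults to the grouping factor),
#'   or \code{"observation"} for plain heteroskedasticity-consistent errors
#'   with every row its own cluster.
#' @return The fit with \code{robust_se}, robust CI, t and p columns filled.
#' @export
robust_se <- function(fit, cluster = fit$spec$grouping) {
  d <- fit$frame
  g <- if (identical(cluster, "observation")) seq_len(nrow(d)) else
    d[[cluster]]
  G <- length(unique(g))
  if (G < 2) stop_invalid("cluster-robust SEs undefined with a single cluster")
  X <- if (inherits(fit$fit, "merMod")) lme4::getME(fit$fit, "X") else
    stats::model.matrix(fit$fit)
  est <- fit$coefficients$estimate
  if (ncol(X) == length(est)) X <- X[, !is.na(est), drop = FALSE]
  est <- est[!is.na(est)]
  y <- d[[fit$spec$response]]
  r <- y - as.vector(X %*% est)
  sig2 <- fit$resid_var; tau2 <- fit$re_var
  p <- ncol(X)
  bread_inv <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (gi in split(seq_along(g), g)) {
    Xg <- X[gi, , drop = FALSE]
    rg <- r[gi]
    ng <- length(gi)
    w <- tau2 / (sig2 + ng * tau2)
    U <- (Xg - w * matrix(colSums(Xg), ng, p, byrow = TRUE)) / sig2  # V^-1 X
    bread_inv <- bread_inv + crossprod(Xg, U)
    s <- crossprod(U, rg)
    meat <- meat + tcrossprod(s)
  }
  bread <- solve(bread_inv)
  vc <- bread %*% meat %*% bread * G / (G - 1)
  rse <- sqrt(diag(vc))
  tab <- fit$coefficients
  tab$robust_se <- NA_real_
  tab$robust_se[!is.na(tab$estimate)] <- rse
  tab$ci_lo <- tab$estimate - 1.96 * tab$robust_se
  tab$ci_hi <- tab$estimate + 1.96 * tab$robust_se
  tab$t <- tab$estimate / tab$robust_se
  tab$p <- 2 * stats::pnorm(-abs(tab$t))
  fit$coefficients <- tab
  fit$robust_vcov <- vc
  fit$se_flavour <- "cluster-robust"
  fit
}

#' Negative binomial model for pitfall-trap ant counts
#'
#' Models transect totals with a log link, season and study year as fixed
#' effects and an offset for the number of tubes, so coefficients act on the
#' per-trap rate. The default backend is an NB regression with cluster-robust
#' (by transect) standard errors; a true random-intercept NB mixed model is
#' available as an alternative backend.
#'
#' @param survey data.frame with \code{month} ("YYYY-MM"), \code{transect} and
#'   either \code{total} or \code{ants_per_trap}.
#' @param tubes tubes per transect (offset).
#' @param backend \code{"nb_cluster"} (default) or \code{"nb_glmm"}.
#' @return list: \code{coefficients} (estimate, SE, robust SE where
#'   applicable), \code{theta}, \code{overdispersion} (Pearson ratio),
#'   \code{marginal_means} (per-trap, by study year and season), \code{fit}.
#' @export
fit_nb_counts <- function(survey, tubes = 10,
                          backend = c("nb_cluster", "nb_glmm")) {
  backend <- match.arg(backend)
  d <- survey
  if (!"total" %in% names(d)) d$total <- round(d$ants_per_trap * tubes)
  if (any(d$total < 0)) stop_invalid("negative counts")
  if (all(d$total == 0)) stop_invalid("all counts are zero")
  if (length(unique(d$transect)) < 2) stop_invalid("need >= 2 transects")
  dts <- month_start(d$month)
  d$season <- factor(assign_season(dts))
  d$study_year <- factor(assign_study_year(dts))
  d$log_tubes <- log(tubes)
  terms <- c(if (nlevels(d$season) > 1) "season",
             if (nlevels(d$study_year) > 1) "study_year")
  rhs <- paste(c(if (length(terms)) terms else "1", "offset(log_tubes)"),
               collapse = " + ")
  if (backend == "nb_cluster") {
    fit <- suppressWarnings(
      MASS::glm.nb(stats::as.formula(paste("total ~", rhs)), data = d))
    vc <- sandwich::vcovCL(fit, cluster = d$transect)
    beta <- stats::coef(fit)
    tab <- data.frame(term = names(beta), estimate = unname(beta),
                      se = sqrt(diag(stats::vcov(fit))),
                      robust_se = sqrt(diag(vc)))
    theta <- fit$theta
    mu <- stats::fitted(fit)
  } else {
    f <- lme4::glmer.nb(stats::as.formula(
      paste("total ~", rhs, "+ (1 | transect)")), data = d)
    beta <- lme4::fixef(f)
    tab <- data.frame(term = names(beta), estimate = unname(beta),
                      se = sqrt(diag(as.matrix(stats::vcov(f)))),
                      robust_se = NA_real_)
    theta <- lme4::getME(f, "glmer.nb.theta")
    mu <- stats::fitted(f)
    fit <- f
  }
  pearson <- sum((d$total - mu)^2 / (mu + mu^2 / theta))
  disp <- pearson / (nrow(d) - nrow(tab))
  per_trap <- mu / tubes
  mm_year <- tapply(per_trap, d$study_year, mean)
  mm_season <- tapply(per_trap, d$season, mean)
  rownames(tab) <- NULL
  list(coefficients = tab, theta = theta, overdispersion = disp,
       marginal_means = list(study_year = mm_year, season = mm_season),
       fit = fit)
}

#' Regression diagnostics for a spline model fit
#'
#' Computes the checks applied to every model: maximum Cook's distance (flag
#' above 1), maximum variance inflation factor (flag above 5), a
#' Breusch-Pagan-type heteroskedasticity test, a residual-normality statistic,
#' and the residual-vs-fitted and QQ data for plotting. Influence measures are
#' computed on the whitened (generalised least squares) scale of the marginal
#' model.
#'
#' @param fit a \code{\link{fit_mixed}} result.
#' @return list of class \code{"model_diagnostics"}.
#' @export
run_diagnostics <- function(fit) {
  d <- fit$frame
  X <- if (inherits(fit$fit, "merMod")) lme4::getME(fit$fit, "X") else
    stats::model.matrix(fit$fit)
  beta_all <- fit$coefficients$estimate
  if (ncol(X) == length(beta_all)) X <- X[, !is.na(beta_all), drop = FALSE]
  beta <- beta_all[!is.na(beta_all)]
  y <- d[[fit$spec$response]]
  g <- d[[fit$spec$grouping]]
  sig <- sqrt(fit$resid_var); tau2 <- fit$re_var
  # whiten by V^-1/2 per animal block (compound symmetry has a closed form)
  Xw <- X; yw <- y
  for (gi in split(seq_along(g), g)) {
    ng <- length(gi)
    dd <- (1 - sqrt(fit$resid_var / (fit$resid_var + ng * tau2))) / ng
    Xg <- X[gi, , drop = FALSE]
    Xw[gi, ] <- (Xg - dd * matrix(colSums(Xg), ng, ncol(X), byrow = TRUE)) / sig
    yw[gi] <- (y[gi] - dd * sum(y[gi])) / sig
  }
  qr_ <- qr(Xw)
  h <- rowSums(qr.Q(qr_)^2)
  rw <- yw - as.vector(Xw %*% beta)
  p <- ncol(X)
  s2 <- sum(rw^2) / (length(rw) - p)
  cooks <- rw^2 * h / (p * s2 * (1 - h)^2)
  # VIF on the intended fixed-effect design (from the model frame, so that a
  # column the fitter dropped as aliased is still seen as perfect collinearity)
  Xc <- as.matrix(d[, c("photoperiod", "prey_b1", "prey_b2",
                        fit$spec$globe_term,
                        if (fit$spec$emergence) "emergence_h")])
  vifs <- tryCatch({
    cm <- suppressWarnings(stats::cor(Xc))
    v <- diag(solve(cm))
    if (anyNA(v)) rep(Inf, ncol(Xc)) else v
  }, error = function(e) rep(Inf, ncol(Xc)))
  names(vifs) <- colnames(Xc)
  fitted_m <- as.vector(X %*% beta)
  r <- y - fitted_m
  # Breusch-Pagan style LM test of squared residuals on fitted values
  aux <- stats::lm(I(r^2) ~ fitted_m)
  bp_stat <- length(r) * summary(aux)$r.squared
  bp_p <- stats::pchisq(bp_stat, df = 1, lower.tail = FALSE)
  idx <- if (length(r) > 5000)
    round(seq(1, length(r), length.out = 5000)) else seq_along(r)
  sw <- stats::shapiro.test(r[idx] - mean(r[idx]))
  structure(list(
    max_cooks_d = max(cooks), cooks_flag = max(cooks) > 1,
    which_max_cooks = which.max(cooks),
    max_vif = max(vifs), vif = vifs, vif_flag = max(vifs) > 5,
    bp_stat = bp_stat, bp_p = bp_p, heteroskedastic = bp_p < 0.05,
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    resid_fitted = data.frame(fitted = fitted_m, residual = r),
    qq = stats::qqnorm(r, plot.it = FALSE)
  ), class = "model_diagnostics")
}
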