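# Stage two: mixed-effects meta-regression of storm-specific log relative
# risks with known within-event variances (se^2), a random intercept per
# location (storms nested within locations) and between-location variance tau^2
# profiled out by REML. Exposure-response curves use a natural spline of the
# covariate (df = 2 by default) anchored at a reference value where RR = 1.

#' Assemble the second-stage meta-analysis dataset
#'
#' Joins first-stage event summaries with exposure records, converts RRs to the
#' log scale and reconstructs the standard error from the confidence interval:
#' `se = (log(hi) - log(lo)) / (2 * 1.96)`. Rows with undefined RR, degenerate
#' (zero-width) CIs or inverted CIs are dropped and counted.
#'
#' @param events data.frame of event summaries with `location`, `event_id`,
#'   `cause` (optional), `rr`, `rr_lo`, `rr_hi` and optionally `country`.
#' @param exposures Exposure records with `location`, `event_id`,
#'   `event_max_wind_kn`, `cumulative_rain_mm`, `year`.
#' @param conf_z Normal quantile used to reconstruct the SE (default 1.96).
#' @return A `meta_dataset` data.frame: `event_id`, `location`, `country`,
#'   `cause`, `logrr`, `se`, `wind`, `rain`, `year`; attribute `"n_dropped"`
#'   counts removed rows.
#' @export
build_meta_dataset <- function(events, exposures, conf_z = 1.96) {
  ev <- as.data.frame(events)
  if (is.null(ev$cause)) ev$cause <- "all"
  if (is.null(ev$country)) ev$country <- "overall"
  ex <- as.data.frame(exposures)[, c("location", "event_id",
                                     "event_max_wind_kn",
                                     "cumulative_rain_mm", "year")]
  m <- merge(ev, ex, by = c("location", "event_id"))

  bad_inverted <- !is.na(m$rr_hi) & !is.na(m$rr_lo) & m$rr_hi < m$rr_lo
  if (any(bad_inverted)) {
    message(sum(bad_inverted), " row(s) rejected: inverted CI (hi < lo)")
  }
  se <- (log(m$rr_hi) - log(m$rr_lo)) / (2 * conf_z)
  ok <- !bad_inverted & is.finite(log(m$rr)) & is.finite(se) & se > 0
  n_dropped <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  out <- data.frame(event_id = m$event_id, location = m$location,
                    country = m$country, cause = m$cause,
                    logrr = log(m$rr), se = se[ok],
                    wind = m$event_max_wind_kn, rain = m$cumulative_rain_mm,
                    year = m$year)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("meta_dataset", "data.frame")
  out
}

# -2 REML log-likelihood for the random-intercept model with known v_i.
# Block-diagonal by group: V_g = diag(v) + tau2 * J.
reml_neg2ll <- function(tau2, y, X, v, group) {
  n <- length(y); p <- ncol(X)
  logdetV <- 0
  XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0
  for (g in split(seq_len(n), group)) {
    Vi <- diag(v[g], nrow = length(g)) + tau2
    ch <- chol(Vi)
    logdetV <- logdetV + 2 * sum(log(diag(ch)))
    Xg <- X[g, , drop = FALSE]
    Xw <- backsolve(ch, Xg, transpose = TRUE)
    yw <- backsolve(ch, y[g], transpose = TRUE)
    XtVX <- XtVX + crossprod(Xw)
    XtVy <- XtVy + crossprod(Xw, yw)
    ytVy <- ytVy + sum(yw^2)
  }
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - 2 * sum(beta * XtVy) + as.numeric(t(beta) %*% XtVX %*% beta)
  val <- logdetV + determinant(XtVX, logarithm = TRUE)$modulus + rss
  list(neg2ll = as.numeric(val), beta = as.numeric(beta),
       vcov = solve(XtVX))
}

#' Mixed-effects meta-regression with known within-row variances
#'
#' Linear mixed model on the log-RR scale: fixed effects from `formula`,
#' a random intercept per `group` level with variance tau^2 estimated by
#' restricted maximum likelihood (1-D profile optimisation), and known
#' within-row variances `se^2`. With a single group or `tau2 = 0` the model
#' collapses to the fixed-effects (inverse-variance weighted) fit.
#'
#' @param data A `meta_dataset` (or any data.frame with `logrr` and `se`).
#' @param formula RHS-only fixed-effects formula (default `~ 1`).
#' @param group Name of the grouping column (default `"location"`).
#' @param tau2 Optional fixed value of tau^2; `NULL` (default) estimates it.
#' @return A `mixmeta_fit`: `beta`, `vcov`, `tau2`, `neg2ll_reml`, `aic`,
#'   `objective` (the profile -2 REML log-likelihood as a function of tau^2,
#'   for diagnostics/oracle checks), `converged_boundary` (TRUE if tau^2 hit
#'   0), plus the model frame pieces.
#' @export
fit_mixmeta <- function(data, formula = ~1, group = "location", tau2 = NULL) {
  stopifnot(all(c("logrr", "se") %in% names(data)))
  if (any(data$se <= 0)) stop("all rows need se > 0", call. = FALSE)
  vars <- all.vars(formula)
  used <- which(stats::complete.cases(data[, vars, drop = FALSE]) &
                  is.finite(data$logrr) & is.finite(data$se))
  dat <- data[used, , drop = FALSE]
  X <- stats::model.matrix(formula, dat)
  y <- dat$logrr
  v <- dat$se^2
  g <- factor(dat[[group]])
  if (nrow(X) <= ncol(X)) stop("not enough rows for the fixed effects",
                               call. = FALSE)

  obj <- function(t2) reml_neg2ll(t2, y, X, v, g)$neg2ll

  if (is.null(tau2)) {
    if (nlevels(g) < 2) {
      message("fewer than 2 groups: random intercept dropped (tau^2 = 0)")
      tau2_hat <- 0
    } else {
      upper <- max(stats::var(y), max(v)) * 10 + 1e-8
      opt <- stats::optimize(obj, interval = c(0, upper), tol = 1e-10)
      tau2_hat <- opt$minimum
      if (obj(0) <= opt$objective) tau2_hat <- 0   # boundary check
    }
  } else {
    tau2_hat <- tau2
  }
  fitted <- reml_neg2ll(tau2_hat, y, X, v, g)
  boundary <- is.null(tau2) && tau2_hat < 1e-10
  if (boundary) {
    message("tau^2 estimated at the boundary (0): fixed-effects collapse")
  }

  p <- ncol(X)
  aic <- fitted$neg2ll + 2 * (p + 1)   # marginal AIC on the REML deviance scale

  structure(list(beta = stats::setNames(fitted$beta, colnames(X)),
                 vcov = fitted$vcov, tau2 = tau2_hat,
                 neg2ll_reml = fitted$neg2ll, aic = aic,
                 objective = obj, converged_boundary = boundary,
                 X = X, y = y, v = v, group = g, formula = formula,
                 data = dat),
            class = "mixmeta_fit")
}

#' @export
print.mixmeta_fit <- function(x, ...) {
  cat("Mixed meta-regression (REML, known within-row variances)\n")
  cat(sprintf("  rows: %d  groups: %d  tau^2: %.5f\n",
              nrow(x$X), nlevels(x$group), x$tau2))
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$beta, se = se,
               z = x$beta / se, p = 2 * stats::pnorm(-abs(x$beta / se)))
  print(round(tab, 4))
  invisible(x)
}

#' Pooled exposure-response curve from a meta-regression
#'
#' Fits a univariate mixed meta-regression with the covariate expanded in a
#' natural-spline basis of `df` degrees of freedom (one interior knot at the
#' covariate median and boundary knots at the 1st/99th percentiles for
#' df = 2), then reports `RR(x) = exp(s(x) - s(x_ref))` over the grid with a
#' Wald CI from the fixed-effects covariance. Beyond the boundary knots the
#' natural spline is linear; grid points outside the observed covariate range
#' are flagged as extrapolation.
#'
#' @param data A `meta_dataset`.
#' @param covariate One of `"wind"`, `"rain"`, `"year"`.
#' @param df Natural-spline degrees of freedom (default 2).
#' @param grid Evaluation grid (default: 50 points over the observed range).
#' @param ref Reference covariate value where RR = 1 (default: minimum
#'   observed value; 34 kn for wind when present in the data).
#' @param group Grouping column for the random intercept.
#' @param level Confidence level.
#' @return An `er_curve` data.frame: `covariate`, `x`, `rr`, `lo`, `hi`,
#'   `extrapolated`; attributes `"ref"` and `"fit"`.
#' @export
er_curve <- function(data, covariate = c("wind", "rain", "year"), df = 2,
                     grid = NULL, ref = NULL, group = "location",
                     level = 0.95) {
  covariate <- match.arg(covariate)
  x <- data[[covariate]]
  if (is.null(ref)) ref <- min(x)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 50)

  knots <- stats::median(x)
  bknots <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
  if (df != 2) {
    probs <- seq_len(df - 1) / df
    knots <- stats::quantile(x, probs, names = FALSE)
  }
  basis <- splines::ns(x, knots = knots, Boundary.knots = bknots)
  dat <- data
  for (j in seq_len(ncol(basis))) dat[[paste0(".b", j)]] <- basis[, j]
  form <- stats::as.formula(
    paste("~", paste(paste0(".b", seq_len(ncol(basis))), collapse = " + ")))
  fit <- fit_mixmeta(dat, form, group = group)

  bg <- stats::predict(basis, grid)
  br <- stats::predict(basis, ref)
  C <- cbind(0, sweep(bg, 2, as.numeric(br)))   # zero out the intercept
  est <- as.numeric(C %*% fit$beta)
  se <- sqrt(pmax(rowSums((C %*% fit$vcov) * C), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)

  out <- data.frame(covariate = covariate, x = grid, rr = exp(est),
                    lo = exp(est - zq * se), hi = exp(est + zq * se),
                    extrapolated = grid < min(x) | grid > max(x))
  attr(out, "ref") <- ref
  attr(out, "fit") <- fit
  class(out) <- c("er_curve", "data.frame")
  out
}

#' Country-level pooled relative risks
#'
#' Per-country intercept-only mixed meta-regression (random intercept per
#' location); countries with fewer than `min_rows` rows are reported as
#' unestimable, and single-location countries drop the random effect.
#'
#' @param data A `meta_dataset` with a `country` column.
#' @param min_rows Minimum rows per country (default 3).
#' @param level Confidence level.
#' @return data.frame: `country`, `n`, `rr`, `lo`, `hi`, `tau2`, `estimable`.
#' @export
country_summaries <- function(data, min_rows = 3, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- lapply(split(data, data$country), function(sub) {
    n <- nrow(sub)
    if (n < min_rows) {
      return(data.frame(country = sub$country[1], n = n, rr = NA_real_,
                        lo = NA_real_, hi = NA_real_, tau2 = NA_real_,
                        estimable = FALSE))
    }
    fit <- suppressMessages(fit_mixmeta(sub, ~1, group = "location"))
    est <- fit$beta[1]; se <- sqrt(fit$vcov[1, 1])
    data.frame(country = sub$country[1], n = n, rr = exp(est),
               lo = exp(est - zq * se), hi = exp(est + zq * se),
               tau2 = fit$tau2, estimable = TRUE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Temporal trend of the pooled relative risk
#'
#' Year exposure-response curve ([er_curve()] with `covariate = "year"`),
#' overall or restricted to one country.
#'
#' @param data A `meta_dataset`.
#' @param country Optional country filter.
#' @param df,grid,level Forwarded to [er_curve()].
#' @return An `er_curve` over calendar years.
#' @export
temporal_trend <- function(data, country = NULL, df = 2, grid = NULL,
                           level = 0.95) {
  if (!is.null(country)) data <- data[data$country == country, , drop = FALSE]
  if (nrow(data) < 3) stop("too few rows for a temporal trend", call. = FALSE)
  er_curve(data, "year", df = df, grid = grid, level = level)
}
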