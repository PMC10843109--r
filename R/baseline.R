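# Stage-one baseline: expected daily mortality mu_t from a Poisson GLM with
# log link fitted on control (storm-free) days, plus a moment decomposition of
# the residual variance into a Poisson part and an autocorrelated multiplicative
# noise part.

#' Interpolate decadal population values to annual values
#'
#' Natural cubic spline through the available decadal values, evaluated at each
#' target year; exact at the knots. Linear data are reproduced exactly (the
#' natural spline of collinear points is the straight line).
#'
#' @param years Years at which population is known (>= 2 for interpolation).
#' @param values Population values at those years (> 0).
#' @param target_years Years at which to evaluate (default: full span).
#' @return data.frame with `year` and `pop`.
#' @export
interpolate_population <- function(years, values,
                                   target_years = seq(min(years), max(years))) {
  stopifnot(length(years) == length(values), all(values > 0))
  if (length(years) == 1) {
    warning("single population value: constant extrapolation")
    return(data.frame(year = target_years, pop = rep(values, length(target_years))))
  }
  o <- order(years)
  sp <- stats::spline(years[o], values[o], xout = target_years,
                      method = "natural")
  data.frame(year = target_years, pop = sp$y)
}

#' Control (storm-free) days of a mortality series
#'
#' Removes, for every exposure record, the exposure days and the post-storm
#' exclusion window `[t0, t0 + exclusion_days]` (inclusive at both ends).
#'
#' @param dates Vector of the series' dates.
#' @param events Exposure records (as from [classify_exposure()]); needs `t0`
#'   and, if present, the `exposure_days` list column. `NULL`/empty = no events.
#' @param exclusion_days Post-storm exclusion length in days (60 in the main
#'   analysis; 30 and 90 as sensitivity settings).
#' @return Logical vector flagging control days, same length as `dates`.
#' @export
control_periods <- function(dates, events = NULL, exclusion_days = 60) {
  stopifnot(exclusion_days >= 1)
  ctrl <- rep(TRUE, length(dates))
  if (is.null(events) || NROW(events) == 0) return(ctrl)
  for (i in seq_len(nrow(events))) {
    t0 <- events$t0[i]
    ctrl[dates >= t0 & dates <= t0 + exclusion_days] <- FALSE
    if (!is.null(events$exposure_days)) {
      ctrl[dates %in% events$exposure_days[[i]]] <- FALSE
    }
  }
  if (!any(ctrl)) {
    stop("no control days left: cannot fit a baseline", call. = FALSE)
  }
  ctrl
}

#' Fit the expected-mortality baseline on control days
#'
#' Poisson regression with log link of daily deaths on a natural-spline slow
#' trend, Fourier seasonal terms, day-of-week indicators (Monday reference) and
#' an intercept, with log population as offset. Fitted on control days only;
#' expected deaths `mu_hat` are predicted for all days.
#'
#' @param series data.frame with `date`, `deaths` (non-negative integers) and
#'   `pop` (annual population attached per day, > 0).
#' @param control Logical vector of control days (see [control_periods()]);
#'   default all days.
#' @param trend_knots_years Spacing of the trend-spline interior knots in
#'   years (default 7, i.e. 1 knot per 7 years).
#' @param harmonics Number of Fourier harmonics for the yearly seasonality
#'   (default 2; 0 drops the seasonal term).
#' @param use_trend,use_dow Include the trend spline / day-of-week indicators.
#' @return A `baseline_fit` with elements `glm`, `mu_hat` (all days),
#'   `control`, `series` and the model's term structure.
#' @export
fit_baseline <- function(series, control = NULL, trend_knots_years = 7,
                         harmonics = 2, use_trend = TRUE, use_dow = TRUE) {
  stopifnot(all(c("date", "deaths", "pop") %in% names(series)))
  if (any(series$deaths < 0)) stop("negative death counts", call. = FALSE)
  if (any(series$pop <= 0)) stop("non-positive population", call. = FALSE)
  if (is.null(control)) control <- rep(TRUE, nrow(series))

  X <- baseline_design(series$date, trend_knots_years, harmonics,
                       use_trend, use_dow)
  p <- ncol(X) + 1
  if (sum(control) < 10 * p) {
    stop(sprintf("too few control days (%d) for %d coefficients",
                 sum(control), p), call. = FALSE)
  }

  dat <- data.frame(deaths = series$deaths, X, check.names = FALSE)
  form <- if (ncol(X) == 0) deaths ~ 1 else deaths ~ .
  fit <- stats::glm(form, data = dat, family = stats::poisson(),
                    offset = log(series$pop), subset = which(control))
  if (!fit$converged) {
    stop("baseline Poisson GLM did not converge after ", fit$iter,
         " iterations", call. = FALSE)
  }
  # predict for ALL days (the glm was fitted on the control subset)
  eta <- cbind(1, as.matrix(X)) %*% stats::coef(fit) + log(series$pop)
  mu_hat <- as.numeric(exp(eta))

  structure(list(glm = fit, mu_hat = mu_hat, control = control,
                 series = series, trend_knots_years = trend_knots_years,
                 harmonics = harmonics, use_trend = use_trend,
                 use_dow = use_dow),
            class = "baseline_fit")
}

# Design matrix (without intercept) for the baseline GLM.
baseline_design <- function(dates, trend_knots_years = 7, harmonics = 2,
                            use_trend = TRUE, use_dow = TRUE) {
  tnum <- as.numeric(dates - dates[1])
  span_years <- (max(tnum) + 1) / 365.25
  parts <- list()
  if (use_trend) {
    k <- max(1, floor(span_years / trend_knots_years))
    tr <- splines::ns(tnum, df = k + 1)
    colnames(tr) <- paste0("trend", seq_len(ncol(tr)))
    parts$trend <- tr
  }
  if (harmonics > 0) {
    doy <- as.integer(format(dates, "%j"))
    sea <- do.call(cbind, lapply(seq_len(harmonics), function(k) {
      cbind(sin(2 * pi * k * doy / 365.25), cos(2 * pi * k * doy / 365.25))
    }))
    colnames(sea) <- paste0(rep(c("sin", "cos"), harmonics),
                            rep(seq_len(harmonics), each = 2))
    parts$season <- sea
  }
  if (use_dow) {
    dow <- factor(as.integer(format(dates, "%u")), levels = 1:7)
    dw <- stats::model.matrix(~dow)[, -1, drop = FALSE]
    colnames(dw) <- paste0("dow", 2:7)
    parts$dow <- dw
  }
  if (length(parts) == 0) {
    return(matrix(numeric(0), nrow = length(dates), ncol = 0))
  }
  as.data.frame(do.call(cbind, parts))
}

#' Estimate the dispersion and autocorrelation of the multiplicative noise
#'
#' Works on the relative residuals z_t = Y_t / mu_t - 1 of control days, whose
#' variance decomposes as nu / mu_t + sigma_eps^2 (white Poisson part +
#' autocorrelated multiplicative noise). Because the Poisson part is serially
#' independent, the lag-k autocovariance of z estimates
#' sigma_eps^2 * rho_eps(k) directly (the 1/mu white part only contributes at
#' lag 0), so the AR(1) coefficient comes from the lag-ratio least-squares
#' estimator phi = sum(c_k c_{k+1}) / sum(c_k^2) over the first `max_lag`
#' autocovariances, and sigma_eps^2 = c_1 / phi. A detectability gate (c_1
#' must exceed 1.645 times its sampling SE and phi must be at least 0.1) guards
#' against reading noise into pure Poisson data; below the gate the series is
#' treated as pure Poisson (sigma_eps = 0). The Poisson dispersion is
#' nu = mean(mu z^2) - sigma_eps^2 mean(mu).
#'
#' @param baseline A `baseline_fit`.
#' @param ar_order AR order for the noise (only 1 is currently implemented).
#' @param max_lag Number of autocovariance lags used (default 5).
#' @return List with `nu` (Poisson dispersion, ~1 for pure Poisson),
#'   `sigma_eps` (stationary SD of the multiplicative noise) and `phi`
#'   (AR(1) coefficient; 0 when no autocorrelated noise is detectable).
#' @export
estimate_noise <- function(baseline, ar_order = 1, max_lag = 5) {
  stopifnot(inherits(baseline, "baseline_fit"))
  if (ar_order != 1) stop("only AR(1) noise is implemented", call. = FALSE)
  ctrl <- baseline$control
  mu <- baseline$mu_hat[ctrl]
  y <- baseline$series$deaths[ctrl]
  z <- y / mu - 1

  if (all(abs(z) < 1e-12)) {
    return(list(nu = 1, sigma_eps = 0, phi = 0))
  }

  # autocovariances over pairs of contiguous control days only
  d <- as.numeric(baseline$series$date[ctrl])
  n <- length(z)
  ck <- vapply(seq_len(max_lag), function(k) {
    ok <- which(diff(d, lag = k) == k)
    if (length(ok) < 30) return(NA_real_)
    mean(z[ok] * z[ok + k]) - mean(z[ok]) * mean(z[ok + k])
  }, numeric(1))
  ck <- ck[!is.na(ck)]

  c0 <- stats::var(z)
  se_c1 <- c0 / sqrt(n)
  sigma2 <- 0
  phi <- 0
  if (length(ck) >= 2 && ck[1] > 1.645 * se_c1) {
    K <- length(ck)
    phi_hat <- sum(ck[-K] * ck[-1]) / sum(ck[-K]^2)
    if (is.finite(phi_hat) && phi_hat >= 0.1) {
      phi <- min(phi_hat, 0.98)
      sigma2 <- ck[1] / phi
      sigma2 <- min(sigma2, c0)           # cannot exceed the total variance
    }
  }
  # below the detectability gate the series is treated as pure Poisson
  # (sigma2 = 0); a white-noise variance-decomposition estimate would be
  # dominated by its own sampling error at realistic death counts

  nu <- mean(mu * z^2) - sigma2 * mean(mu)
  if (!is.finite(nu) || nu <= 0) {
    warning("Poisson dispersion estimated <= 0; reset to 1")
    nu <- 1
  }
  list(nu = as.numeric(nu), sigma_eps = sqrt(as.numeric(sigma2)),
       phi = as.numeric(phi))
}
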