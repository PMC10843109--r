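# Forward simulation of the mixed Poisson mortality model with known injected
# storm effects: Y_t | eps_t ~ Poisson(mu_t * (1 + f(t)) * eps_t), where mu_t
# carries the population offset, slow trend, yearly seasonality and day-of-week
# effects, and eps_t is log-normal AR(1) multiplicative noise with E[eps] = 1.

#' Simulation configuration for synthetic mortality series
#'
#' @param n_locations Number of locations.
#' @param years Number of simulated years (series starts 2000-01-01).
#' @param baseline_rate Expected deaths/day at the reference population.
#' @param trend_amplitude Log-scale slope per decade of the slow trend.
#' @param seasonal_amplitude Log-scale amplitude of the yearly cosine.
#' @param dow_effects Seven log-scale day-of-week effects (Mon..Sun).
#' @param noise_sd Stationary SD of the log-noise eta (>= 0).
#' @param noise_ar1 Lag-1 autocorrelation phi of eta, |phi| < 1.
#' @param injected_effects List of effects, each a list with fields `location`,
#'   `t0` (Date), `shape` (one of "rect", "triangular", "exp-decay"),
#'   `peak` (fractional increase, e.g. 0.3 for +30%; must be > -1) and
#'   `duration` (days, >= 1).
#' @param pop0 Reference population (default 1e5).
#' @param pop_growth Population growth factor per decade (default 1.05).
#' @param cause_fractions Multinomial split of all-cause deaths into
#'   cardiovascular / respiratory / other streams.
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_locations = 1, years = 15, baseline_rate = 30,
                       trend_amplitude = 0.02, seasonal_amplitude = 0.1,
                       dow_effects = rep(0, 7), noise_sd = 0.05,
                       noise_ar1 = 0.5, injected_effects = list(),
                       pop0 = 1e5, pop_growth = 1.05,
                       cause_fractions = c(cvd = 0.32, resp = 0.10),
                       seed = 1L) {
  stopifnot(n_locations >= 1, years >= 1, baseline_rate > 0,
            length(dow_effects) == 7, noise_sd >= 0, abs(noise_ar1) < 1,
            pop0 > 0, pop_growth > 0)
  for (ef in injected_effects) {
    stopifnot(is.list(ef),
              all(c("location", "t0", "shape", "peak", "duration") %in% names(ef)))
    if (ef$duration < 1) stop("effect duration must be >= 1 day", call. = FALSE)
    if (ef$peak <= -1) stop("peak percent increase must be > -100%", call. = FALSE)
    if (!ef$shape %in% c("rect", "triangular", "exp-decay")) {
      stop("unknown effect shape: ", ef$shape, call. = FALSE)
    }
  }
  structure(list(
    n_locations = n_locations, years = years, baseline_rate = baseline_rate,
    trend_amplitude = trend_amplitude, seasonal_amplitude = seasonal_amplitude,
    dow_effects = dow_effects, noise_sd = noise_sd, noise_ar1 = noise_ar1,
    injected_effects = injected_effects, pop0 = pop0, pop_growth = pop_growth,
    cause_fractions = cause_fractions, seed = as.integer(seed)
  ), class = "sim_config")
}

# effect profile over day offsets 0..(duration-1)
effect_profile <- function(shape, peak, duration) {
  k <- seq_len(duration) - 1
  switch(shape,
    rect = rep(peak, duration),
    triangular = peak * (1 - k / duration),
    `exp-decay` = peak * exp(-3 * k / duration)
  )
}

#' Generate decadal gridded population tables
#'
#' A smooth positive spatial field (log-Gaussian bumps over the grid) scaled by
#' a per-decade growth factor.
#'
#' @param grid A `tc_grid` from [make_grid()].
#' @param decades Integer vector of decade years (>= 2 values).
#' @param seed Integer seed.
#' @param growth Growth factor applied per decade (default 1.05).
#' @return data.frame `year`, `cell`, `cell_lon`, `cell_lat`, `pop`.
#' @export
gen_population <- function(grid, decades, seed, growth = 1.05) {
  if (length(decades) < 2) stop("need >= 2 decades", call. = FALSE)
  set.seed(seed)
  n_bumps <- 8
  cx <- stats::runif(n_bumps, min(grid$cell_lon), max(grid$cell_lon))
  cy <- stats::runif(n_bumps, min(grid$cell_lat), max(grid$cell_lat))
  amp <- stats::runif(n_bumps, 0.5, 2)
  wid <- stats::runif(n_bumps, 1, 4)
  field <- rep(0.1, nrow(grid))
  for (j in seq_len(n_bumps)) {
    field <- field + amp[j] *
      exp(-((grid$cell_lon - cx[j])^2 + (grid$cell_lat - cy[j])^2) / (2 * wid[j]^2))
  }
  base <- 1e4 * field
  out <- lapply(seq_along(decades), function(i) {
    data.frame(year = decades[i], cell = grid$cell,
               cell_lon = grid$cell_lon, cell_lat = grid$cell_lat,
               pop = base * growth^(i - 1))
  })
  do.call(rbind, out)
}

#' Simulate per-location daily mortality and rainfall with known truth
#'
#' Draws, for every location, daily all-cause deaths from the mixed Poisson
#' model (population offset x trend x season x day-of-week, log-normal AR(1)
#' multiplicative noise normalised to mean 1, injected storm effects of known
#' shape), splits them into cause-specific streams by multinomial thinning,
#' and generates a seasonal gamma rainfall series with bursts on effect days.
#'
#' @param cfg A [sim_config()].
#' @return List with `mortality` (location, date, deaths_all, deaths_cvd,
#'   deaths_resp, pop), `rainfall` (location, date, rain_mm), `population`
#'   (location, year, pop) and `truth` — one record per injected effect with
#'   the true f(t) series, true POC days, true expected and true excess deaths.
#' @export
gen_location_series <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  start <- as.Date("2000-01-01")
  dates <- seq(start, by = "day", length.out = round(cfg$years * 365.25))
  n <- length(dates)
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  dow <- as.integer(format(dates, "%u"))          # 1 = Monday
  t_dec <- as.numeric(dates - start) / 3652.5     # decades since start

  for (ef in cfg$injected_effects) {
    if (ef$t0 < start || ef$t0 > dates[n]) {
      stop("injected effect t0 outside the simulated span", call. = FALSE)
    }
  }

  years_u <- sort(unique(yr))
  pop_y <- cfg$pop0 * cfg$pop_growth^((years_u - years_u[1]) / 10)
  names(pop_y) <- years_u

  mort <- vector("list", cfg$n_locations)
  rainl <- vector("list", cfg$n_locations)
  truth <- list()
  sd_stat <- cfg$noise_sd

  for (loc in seq_len(cfg$n_locations)) {
    loc_id <- sprintf("loc%03d", loc)
    pop_t <- pop_y[as.character(yr)]
    mu <- cfg$baseline_rate * (pop_t / cfg$pop0) *
      exp(cfg$trend_amplitude * t_dec +
            cfg$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
            cfg$dow_effects[dow])

    # AR(1) log-noise, stationary start, normalised so E[eps] = 1
    if (sd_stat > 0) {
      innov_sd <- sd_stat * sqrt(1 - cfg$noise_ar1^2)
      eta <- numeric(n)
      eta[1] <- stats::rnorm(1, 0, sd_stat)
      if (n > 1) {
        e <- stats::rnorm(n - 1, 0, innov_sd)
        for (t in 2:n) eta[t] <- cfg$noise_ar1 * eta[t - 1] + e[t - 1]
      }
      eps <- exp(eta - sd_stat^2 / 2)
    } else {
      eps <- rep(1, n)
    }

    f <- rep(0, n)
    for (ef in cfg$injected_effects) {
      if (ef$location != loc_id && ef$location != loc) next
      prof <- effect_profile(ef$shape, ef$peak, ef$duration)
      idx0 <- as.integer(ef$t0 - start) + 1L
      idx <- idx0 + seq_along(prof) - 1L
      keep <- idx <= n
      f[idx[keep]] <- f[idx[keep]] + prof[keep]
      poc_days <- dates[idx[keep]][prof[keep] > 0]
      truth[[length(truth) + 1]] <- list(
        location = loc_id, t0 = ef$t0, shape = ef$shape, peak = ef$peak,
        duration = ef$duration,
        f = data.frame(date = dates[idx[keep]], f = prof[keep]),
        poc_days = poc_days,
        true_expected = sum(mu[idx[keep]][prof[keep] > 0]),
        true_excess = sum(mu[idx[keep]] * prof[keep])
      )
    }

    y <- stats::rpois(n, mu * (1 + f) * eps)
    frac <- cfg$cause_fractions
    split_mat <- t(vapply(y, function(yt) {
      stats::rmultinom(1, yt, c(frac[1], frac[2], 1 - sum(frac)))[, 1]
    }, integer(3)))

    mort[[loc]] <- data.frame(
      location = loc_id, date = dates, deaths_all = y,
      deaths_cvd = split_mat[, 1], deaths_resp = split_mat[, 2],
      pop = as.numeric(pop_t)
    )

    wet <- stats::rbinom(n, 1, 0.4)
    seas_mean <- 4 + 3 * cos(2 * pi * (doy - 200) / 365.25)
    rain <- wet * stats::rgamma(n, shape = 0.8, scale = seas_mean / 0.8)
    rain[f > 0] <- rain[f > 0] + stats::rgamma(sum(f > 0), shape = 2, scale = 15)
    rainl[[loc]] <- data.frame(location = loc_id, date = dates, rain_mm = rain)
  }

  pop_tab <- do.call(rbind, lapply(seq_len(cfg$n_locations), function(loc) {
    data.frame(location = sprintf("loc%03d", loc), year = years_u,
               pop = as.numeric(pop_y))
  }))

  list(mortality = do.call(rbind, mort), rainfall = do.call(rbind, rainl),
       population = pop_tab, truth = truth)
}

#' Write simulated mortality / rainfall series as long-format CSV
#'
#' @param sim Output of [gen_location_series()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_series_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- merge(sim$mortality, sim$rainfall, by = c("location", "date"))
  m <- m[order(m$location, m$date),
         c("location", "date", "deaths_all", "deaths_cvd", "deaths_resp",
           "rain_mm")]
  paths <- c(mortality = file.path(dir, "mortality.csv"),
             population = file.path(dir, "population.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(m, paths[["mortality"]], row.names = FALSE)
  utils::write.csv(sim$population, paths[["population"]], row.names = FALSE)
  truth <- lapply(sim$truth, function(tr) {
    tr$t0 <- as.character(tr$t0)
    tr$poc_days <- as.character(tr$poc_days)
    tr$f <- data.frame(date = as.character(tr$f$date), f = tr$f$f)
    tr
  })
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
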