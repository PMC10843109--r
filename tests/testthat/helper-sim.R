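# Shared fixtures, built in code.

# Flat series: constant mu = rate (no trend/season/dow, fixed population).
flat_config <- function(years = 10, rate = 30, noise_sd = 0, noise_ar1 = 0,
                        effects = list(), seed = 1) {
  sim_config(years = years, baseline_rate = rate, trend_amplitude = 0,
             seasonal_amplitude = 0, dow_effects = rep(0, 7),
             noise_sd = noise_sd, noise_ar1 = noise_ar1, pop_growth = 1,
             injected_effects = effects, seed = seed)
}

sim_series <- function(cfg, cause = "deaths_all") {
  sim <- gen_location_series(cfg)
  m <- sim$mortality
  list(series = data.frame(date = m$date, deaths = m[[cause]], pop = m$pop),
       truth = sim$truth, sim = sim)
}

# Toy meta dataset with row-level grouping (plain random-effects meta).
toy_meta <- function(logrr, se, location = paste0("s", seq_along(logrr)),
                     wind = 50, rain = 10, year = 2005,
                     country = "overall") {
  d <- data.frame(event_id = paste0("e", seq_along(logrr)),
                  location = location, country = country, cause = "all",
                  logrr = logrr, se = se, wind = wind, rain = rain,
                  year = year)
  class(d) <- c("meta_dataset", "data.frame")
  d
}

# Simulated meta dataset: 150 rows over 30 locations, known slope/tau.
sim_meta <- function(slope = 0.004, tau = 0.05, n = 150, n_loc = 30,
                     seed = 1) {
  set.seed(seed)
  loc <- sample(rep(seq_len(n_loc), length.out = n))
  wind <- stats::runif(n, 34, 130)
  u <- stats::rnorm(n_loc, 0, tau)
  se <- stats::runif(n, 0.05, 0.15)
  y <- slope * wind + u[loc] + stats::rnorm(n, 0, se)
  toy_meta(y, se, location = paste0("L", loc), wind = wind,
           rain = stats::runif(n, 0, 300), year = sample(1980:2019, n, TRUE))
}

demo_pipeline_config <- function(out_dir, seed = 3, ...) {
  pipeline_config(out_dir = out_dir, seed = seed,
                  simulate = list(n_storms = 3, n_locations = 6, years = 12,
                                  region = c(120, 132, 12, 26),
                                  effect = list(shape = "rect", peak = 0.3,
                                                duration = 21)),
                  ...)
}
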