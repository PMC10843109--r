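# Event-effect module: spline basis with hit-day discontinuity, GLS fit,
# POC detection and event summaries.

test_that("event basis has the documented rank and jump structure", {
  dates <- as.Date("2003-01-01") + 0:365        # 366-day window
  t0 <- dates[150]
  X <- event_basis(dates, t0, knots_per_year = 6)
  expect_length(attr(X, "knots"), 6)
  expect_equal(qr(X)$rank, 6 + 1 + 1)           # spline cols + jump
  expect_true(all(X[dates < t0, "jump"] == 0))
  expect_true(all(X[dates >= t0, "jump"] == 1))
  # translation invariance: a pure calendar shift leaves the matrix unchanged
  shift <- 730
  X2 <- event_basis(dates + shift, t0 + shift, knots_per_year = 6)
  expect_equal(unclass(X), unclass(X2), ignore_attr = TRUE)
  expect_error(event_basis(dates[1], dates[1]), "shorter")
  expect_error(event_basis(dates, max(dates) + 5), "outside")
})

test_that("GLS reduces exactly to OLS when Sigma is proportional to identity", {
  # constant series so mu_hat is constant -> diag(nu/mu) = c * I
  ser <- data.frame(date = as.Date("2004-01-01") + 0:59,
                    deaths = rpois(60, 30), pop = rep(1e5, 60))
  set.seed(5); ser$deaths <- rpois(60, 30)
  bl <- fit_baseline(ser, use_trend = FALSE, harmonics = 0, use_dow = FALSE)
  t0 <- ser$date[31]
  noise <- list(nu = 1, sigma_eps = 0, phi = 0)
  ef <- fit_event_effect(bl, noise, t0, window = c(-15, 14),
                         baseline_uncertainty = FALSE)
  w_dates <- seq(t0 - 15, t0 + 14, by = "day")
  X <- event_basis(w_dates, t0, knots_per_year = 6)
  z <- ser$deaths[ser$date %in% w_dates] / bl$mu_hat[ser$date %in% w_dates] - 1
  beta_ols <- as.numeric(qr.solve(X, z))
  expect_equal(ef$beta, beta_ols, tolerance = 1e-10)
})

test_that("POC detection applies the first-run rule and tie-breaks", {
  mk <- function(lo, t0, dates) {
    structure(list(empty = FALSE, t0 = t0, dates = dates, lo = lo,
                   level = 0.95), class = "event_effect")
  }
  dates <- as.Date("2005-01-01") + 0:99
  t0 <- dates[40]
  lo <- rep(-1, 100)
  lo[40:60] <- 1                              # significant on t0..t0+20
  poc <- detect_poc(mk(lo, t0, dates))
  expect_equal(poc$poc_length, 21L)
  expect_equal(poc$poc_start, t0)
  # nothing significant
  poc0 <- detect_poc(mk(rep(-1, 100), t0, dates))
  expect_equal(poc0$poc_length, 0L)
  expect_true(is.na(poc0$poc_start))
  # two runs: first wins under the default rule, longest under the flag
  lo2 <- rep(-1, 100)
  lo2[40:45] <- 1                             # days 0-5 post t0
  lo2[50:58] <- 1                             # days 10-18 post t0
  expect_equal(detect_poc(mk(lo2, t0, dates))$poc_length, 6L)
  expect_equal(detect_poc(mk(lo2, t0, dates), rule = "longest")$poc_length, 9L)
  # significance before t0 never counts
  lo3 <- rep(-1, 100); lo3[10:20] <- 1
  expect_equal(detect_poc(mk(lo3, t0, dates))$poc_length, 0L)
})

test_that("event summary satisfies the observed = expected + excess identity", {
  set.seed(9)
  t0 <- as.Date("2006-08-01")
  cfg <- flat_config(years = 10, rate = 50, noise_sd = 0.05, noise_ar1 = 0.5,
                     seed = 111,
                     effects = list(list(location = "loc001", t0 = t0,
                                         shape = "rect", peak = 0.3,
                                         duration = 21)))
  out <- sim_series(cfg)
  ctrl <- control_periods(out$series$date, data.frame(t0 = t0), 60)
  bl <- fit_baseline(out$series, ctrl)
  nz <- estimate_noise(bl)
  ef <- fit_event_effect(bl, nz, t0)
  s <- summarize_event(ef)
  expect_equal(s$observed, s$expected + s$excess, tolerance = 1e-9)
  expect_equal(s$rr, s$observed / s$expected, tolerance = 1e-12)
  expect_true(s$excess_lo <= s$excess && s$excess <= s$excess_hi)
  expect_true(s$rr_lo <= s$rr && s$rr <= s$rr_hi)
  expect_gt(s$excess, 0)                     # a +30% effect must be detected
  expect_lt(s$p, 0.05)
})

test_that("null effect yields excess near 0 and RR near 1 over the fallback window", {
  set.seed(13)
  cfg <- flat_config(years = 10, rate = 40, seed = 121)
  out <- sim_series(cfg)
  t0 <- as.Date("2005-06-01")
  bl <- fit_baseline(out$series)
  nz <- suppressWarnings(estimate_noise(bl))
  ef <- fit_event_effect(bl, nz, t0)
  s <- summarize_event(ef)
  if (s$poc_length == 0) {
    expect_true(s$window_flagged)            # fallback [t0, t0+2] window
  }
  expect_lt(abs(s$rr - 1), 0.25)
})

test_that("widening the CI level monotonically shrinks the POC", {
  set.seed(17)
  t0 <- as.Date("2006-08-01")
  cfg <- flat_config(years = 10, rate = 50, noise_sd = 0.05, noise_ar1 = 0.5,
                     seed = 131,
                     effects = list(list(location = "loc001", t0 = t0,
                                         shape = "rect", peak = 0.25,
                                         duration = 21)))
  out <- sim_series(cfg)
  ctrl <- control_periods(out$series$date, data.frame(t0 = t0), 60)
  bl <- fit_baseline(out$series, ctrl)
  nz <- estimate_noise(bl)
  lens <- vapply(c(0.80, 0.90, 0.95, 0.99), function(lv) {
    ef <- fit_event_effect(bl, nz, t0, level = lv)
    detect_poc(ef)$poc_length
  }, integer(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("days under other storms' exclusion windows are dropped from the fit", {
  set.seed(19)
  t0 <- as.Date("2006-08-01")
  other_t0 <- as.Date("2006-03-01")
  cfg <- flat_config(years = 10, rate = 50, seed = 141)
  out <- sim_series(cfg)
  ev_all <- data.frame(t0 = c(t0, other_t0))
  ctrl <- control_periods(out$series$date, ev_all, 60)
  bl <- fit_baseline(out$series, ctrl)
  nz <- suppressWarnings(estimate_noise(bl))
  ef60 <- fit_event_effect(bl, nz, t0, other_events = data.frame(t0 = other_t0),
                           exclusion_days = 60)
  expect_equal(sum(!ef60$kept), 61)          # [other_t0, other_t0 + 60]
  ef30 <- fit_event_effect(bl, nz, t0, other_events = data.frame(t0 = other_t0),
                           exclusion_days = 30)
  ef90 <- fit_event_effect(bl, nz, t0, other_events = data.frame(t0 = other_t0),
                           exclusion_days = 90)
  expect_equal(sum(!ef30$kept), 31)
  expect_equal(sum(!ef90$kept), 91)
  # sensitivity contract: the estimator is the same machinery, only the
  # retained days change
  expect_equal(ncol(ef30$basis), ncol(ef90$basis))
  # a window fully excluded comes back flagged empty
  ef_empty <- fit_event_effect(bl, nz, t0, window = c(-5, 5),
                               other_events = data.frame(t0 = t0 - 5),
                               exclusion_days = 60)
  expect_true(ef_empty$empty)
  expect_equal(summarize_event(ef_empty)$poc_length, 0L)
})
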