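# Wind-field module: unit conversions, Holland profile, rasterisation,
# exposure classification.

test_that("knot conversions reproduce the gale-force threshold in all units", {
  expect_equal(round(knots_to_ms(34), 1), 17.5)
  expect_equal(round(knots_to_kmh(34)), 63)
  expect_equal(round(knots_to_mph(34)), 39)
  expect_equal(knots_to_ms(0), 0)
  expect_equal(ms_to_knots(knots_to_ms(c(10, 34, 120))), c(10, 34, 120))
  expect_error(knots_to_ms(-1), "non-negative")
})

test_that("Holland profile matches the closed form at r_max with no Coriolis", {
  # V(r_max) = sqrt(B * dp / rho * e^-1) when f_c = 0
  v <- holland_wind_speed(50, 5000, 50, 1.5, lat = 0, surface_reduction = 1)
  expect_equal(v, sqrt(1.5 * 5000 / 1.15 * exp(-1)), tolerance = 1e-12)
  # degenerate storm and vortex centre
  expect_equal(holland_wind_speed(80, 0, 50, 1.5, lat = 0,
                                  surface_reduction = 1), 0)
  expect_equal(holland_wind_speed(0, 5000, 50, 1.5), 0)
  expect_error(holland_wind_speed(10, 5000, 50, 3.0), "Holland B")
  expect_error(holland_wind_speed(-1, 5000, 50, 1.5), "radius")
})

test_that("radial profile peaks at r_max and decays monotonically far out", {
  r <- seq(0.5, 800, by = 0.5)
  v <- holland_wind_speed(r, 6000, 40, 1.3, lat = 0, surface_reduction = 1)
  expect_equal(r[which.max(v)], 40, tolerance = 1)
  far <- r >= 80   # beyond 2 r_max
  expect_true(all(diff(v[far]) < 0))
  expect_lt(max(v[r >= 400]), v[r == 80])
  # Coriolis on: still a single interior maximum near r_max
  v2 <- holland_wind_speed(r, 6000, 40, 1.3, lat = 25, surface_reduction = 1)
  expect_equal(r[which.max(v2)], 40, tolerance = 2)
})

test_that("holland_b stays in [0.5, 2.5] over a wide parameter sweep", {
  grid <- expand.grid(dp = c(1, 10, 50, 100, 150), ddt = c(-3, 0, 3),
                      lat = c(5, 20, 45), vt = c(0, 5, 15))
  b <- with(grid, holland_b(dp, ddt, lat, vt))
  expect_true(all(b >= 0.5 & b <= 2.5))
})

test_that("make_grid builds exact 0.5-degree cells and rejects bad boxes", {
  g <- make_grid(c(120, 125), c(10, 15))
  expect_s3_class(g, "tc_grid")
  expect_equal(sort(unique(diff(sort(unique(g$cell_lon))))), 0.5)
  expect_equal(attr(g, "res"), 0.5)
  expect_error(make_grid(c(125, 120), c(10, 15)), "degenerate")
})

test_that("rasterize_storm matches a 1-minute brute-force oracle on a 10x10 grid", {
  tr <- gen_tracks(1, c(121, 124, 16, 19), seed = 42)[[1]]
  grid <- make_grid(c(120, 125), c(15, 20))[1:100, ]
  wg <- rasterize_storm(tr, grid, interp_step = 1, b = 1.4,
                        surface_reduction = 0.9)

  # independent brute force: per-minute linear interpolation + direct formula
  pts <- tr$points
  tt <- as.numeric(pts$time)
  mins <- seq(tt[1], tt[length(tt)], by = 60)
  lon <- approx(tt, pts$lon, mins)$y
  lat <- approx(tt, pts$lat, mins)$y
  dp <- pmax(approx(tt, pts$env_pres - pts$pres, mins)$y, 0) * 100
  rmw <- approx(tt, pts$rmw, mins)$y
  day <- as.Date(as.POSIXct(mins, origin = "1970-01-01", tz = "UTC"),
                 tz = "UTC")
  # translation speed via the same forward difference the module uses
  n <- length(mins)
  stepkm <- haversine_km(lon[-n], lat[-n], lon[-1], lat[-1])
  vt <- c(stepkm / (1 / 60), 0) * 1000 / 3600
  vt[n] <- vt[n - 1]

  oracle <- expand.grid(cell = grid$cell, date = unique(day))
  oracle$wind <- 0
  for (i in seq_len(n)) {
    d <- haversine_km(grid$cell_lon, grid$cell_lat, lon[i], lat[i])
    w <- ifelse(d > 500, 0,
                holland_wind_speed(d, dp[i], rmw[i], 1.4, lat[i], vt[i], 0.9))
    sel <- oracle$date == day[i]
    oracle$wind[sel] <- pmax(oracle$wind[sel], w)
  }
  oracle <- oracle[oracle$wind > 0, ]
  m <- merge(as.data.frame(wg), oracle, by = c("cell", "date"))
  expect_equal(nrow(m), nrow(wg))
  expect_true(all(abs(m$wind_ms - m$wind) / pmax(m$wind, 1e-6) < 0.01))
})

test_that("a stationary single-day storm rasterises to its snapshot field", {
  pts <- data.frame(
    time = as.POSIXct("2005-07-01 00:00:00", tz = "UTC") + c(0, 6, 12, 18) * 3600,
    lon = 122.2, lat = 17.3, pres = 960, env_pres = 1010, rmw = 40,
    vmax_kn = 80)
  tr <- structure(list(event_id = "STAT", points = pts), class = "tc_track")
  grid <- make_grid(c(120, 125), c(15, 20))
  wg <- rasterize_storm(tr, grid, interp_step = 360, b = 1.4)
  d <- haversine_km(grid$cell_lon, grid$cell_lat, 122.2, 17.3)
  snap <- ifelse(d > 500, 0, holland_wind_speed(d, 5000, 40, 1.4, 17.3, 0, 0.9))
  m <- merge(as.data.frame(wg), data.frame(cell = grid$cell, snap = snap))
  expect_equal(m$wind_ms, m$snap, tolerance = 1e-10)
})

test_that("a track far from every cell yields an all-zero (empty) grid", {
  tr <- gen_tracks(1, c(60, 62, -20, -18), seed = 5)[[1]]
  grid <- make_grid(c(120, 125), c(15, 20))
  wg <- rasterize_storm(tr, grid)
  expect_equal(nrow(wg), 0)
})

test_that("classify_exposure applies the inclusive 34-knot day rule", {
  days <- as.Date("2005-07-01") + 0:3
  wind <- data.frame(event_id = "E1", date = days, cell = 0L,
                     cell_lon = 120.25, cell_lat = 15.25,
                     wind_ms = knots_to_ms(c(30, 36, 40, 20)))
  locs <- data.frame(location = "locA", cell = 0L)
  rec <- classify_exposure(wind, locs)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$t0, days[2])
  expect_equal(rec$exposure_days[[1]], days[2:3])
  expect_equal(rec$event_max_wind_kn, 40, tolerance = 1e-9)
  expect_equal(rec$year, 2005L)

  # all below threshold: no record
  wind$wind_ms <- knots_to_ms(c(30, 33, 33.9, 20))
  expect_equal(nrow(classify_exposure(wind, locs)), 0)

  # exactly 34.0 knots is exposed (inclusive rule)
  wind$wind_ms <- knots_to_ms(c(10, 34, 10, 10))
  rec <- classify_exposure(wind, locs)
  expect_equal(rec$t0, days[2])
  expect_equal(rec$n_exposure_days, 1L)
})

test_that("cumulative rainfall is summed over [t0 - window, t0] and flags gaps", {
  days <- as.Date("2005-07-01") + 0:5
  wind <- data.frame(event_id = "E1", date = days[4], cell = 0L,
                     cell_lon = 120.25, cell_lat = 15.25,
                     wind_ms = knots_to_ms(40))
  locs <- data.frame(location = "locA", cell = 0L)
  rain <- data.frame(location = "locA", date = days, rain_mm = c(1, 2, 4, 8, 16, 32))
  rec <- classify_exposure(wind, locs, rain, rain_window = 2)
  expect_false(rec$rain_missing)
  expect_equal(rec$cumulative_rain_mm, 2 + 4 + 8)   # days 2..4
  # a required rain day missing -> flagged, NA rain
  rec2 <- classify_exposure(wind, locs, rain[-2, ], rain_window = 2)
  expect_true(rec2$rain_missing)
  expect_true(is.na(rec2$cumulative_rain_mm))
})

test_that("exposure t0 falls within the storm's track time span", {
  tracks <- gen_tracks(3, c(120, 130, 12, 24), seed = 8)
  grid <- make_grid(c(115, 135), c(8, 28))
  n_checked <- 0
  for (tr in tracks) {
    wg <- rasterize_storm(tr, grid)
    if (nrow(wg) == 0) next
    # put locations on the cells the storm actually touched
    top <- unique(wg$cell[order(-wg$wind_ms)])[1:5]
    locs <- data.frame(location = sprintf("L%02d", seq_along(top)), cell = top)
    rec <- classify_exposure(wg, locs)
    if (nrow(rec) == 0) next
    span <- as.Date(range(tr$points$time), tz = "UTC")
    expect_true(all(rec$t0 >= span[1] & rec$t0 <= span[2]))
    n_checked <- n_checked + nrow(rec)
  }
  expect_gt(n_checked, 0)
})
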