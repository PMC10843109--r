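# Parametric Holland wind field: radial gradient-wind profile, rasterisation of
# best-track storms onto a 0.5 degree grid, and per-location exposure records.

AIR_DENSITY <- 1.15      # kg/m^3, ambient near-surface air density
EARTH_OMEGA <- 7.292e-5  # rad/s
EARTH_RADIUS_KM <- 6371.0

#' Coriolis parameter
#'
#' @param lat Latitude in degrees.
#' @return Coriolis parameter f_c in 1/s (absolute value; the wind-profile
#'   formula only uses its magnitude).
#' @export
coriolis <- function(lat) {
  abs(2 * EARTH_OMEGA * sin(lat * pi / 180))
}

#' Holland B shape parameter from storm characteristics
#'
#' Surface regression for the profile-peakedness parameter B in the improved
#' Holland model: a function of the pressure deficit, its time derivative,
#' latitude and storm translation speed, clipped to \[0.5, 2.5\].
#'
#' @param delta_p_hpa Pressure deficit (environmental minus central), hPa.
#' @param dp_dt_hpa_h Time derivative of central pressure, hPa per hour
#'   (negative while deepening).
#' @param lat Latitude, degrees.
#' @param v_trans_ms Translation speed of the storm centre, m/s.
#' @return B, dimensionless, in \[0.5, 2.5\].
#' @export
holland_b <- function(delta_p_hpa, dp_dt_hpa_h = 0, lat = 20, v_trans_ms = 0) {
  dp <- pmax(delta_p_hpa, 1)
  x <- 0.6 * (1 - dp / 215)
  b <- -4.4e-5 * dp^2 + 0.01 * dp + 0.03 * dp_dt_hpa_h -
    0.014 * abs(lat) + 0.15 * v_trans_ms^x + 1.0
  pmin(pmax(b, 0.5), 2.5)
}

#' Holland gradient-wind radial profile
#'
#' Sustained wind speed at distance `r_km` from the storm centre:
#' \deqn{V(r) = \sqrt{\frac{B\,\Delta p}{\rho}\Big(\frac{r_m}{r}\Big)^B
#'   e^{-(r_m/r)^B} + \Big(\frac{r f_c}{2}\Big)^2} - \frac{r f_c}{2}}
#' with air density \eqn{\rho} = 1.15 kg/m^3 and Coriolis parameter from the
#' latitude. An optional translation asymmetry adds a fraction of the
#' translation speed scaled by the attenuation factor
#' \eqn{r_m r / (r_m^2 + r^2)}, and the result is multiplied by a scalar
#' surface reduction factor (gradient-to-surface wind).
#'
#' @param r_km Distance(s) from the centre, km. `r = 0` returns 0 (vortex eye).
#' @param delta_p_pa Pressure deficit in Pa (>= 0).
#' @param r_max_km Radius of maximum winds, km (> 0).
#' @param b Holland B parameter, dimensionless, in \[0.5, 2.5\].
#' @param lat Latitude in degrees (sets the Coriolis parameter).
#' @param translation_ms Storm translation speed, m/s (0 = symmetric vortex).
#' @param surface_reduction Scalar gradient-to-surface wind factor, default 0.9.
#' @return Wind speed(s) in m/s.
#' @export
holland_wind_speed <- function(r_km, delta_p_pa, r_max_km, b,
                               lat = 20, translation_ms = 0,
                               surface_reduction = 0.9) {
  if (any(r_km < 0)) stop("radius must be >= 0", call. = FALSE)
  if (delta_p_pa < 0) stop("pressure deficit must be >= 0", call. = FALSE)
  if (r_max_km <= 0) stop("radius of maximum winds must be > 0", call. = FALSE)
  if (b < 0.5 || b > 2.5) stop("Holland B must lie in [0.5, 2.5]", call. = FALSE)

  fc <- coriolis(lat)
  r_m <- r_km * 1000
  rmax_m <- r_max_km * 1000

  v <- numeric(length(r_km))
  pos <- r_km > 0
  if (any(pos)) {
    x <- (rmax_m / r_m[pos])^b
    core <- b * delta_p_pa / AIR_DENSITY * x * exp(-x)
    rf2 <- r_m[pos] * fc / 2
    v_grad <- sqrt(core + rf2^2) - rf2
    atten <- rmax_m * r_m[pos] / (rmax_m^2 + r_m[pos]^2)
    v[pos] <- pmax(v_grad + translation_ms * atten, 0)
  }
  v * surface_reduction
}

#' Define a regular 0.5-degree grid
#'
#' @param lon_range,lat_range Length-2 numeric vectors (degrees) delimiting the
#'   box. Cell centres are placed at x.25 / x.75 so cells tile the box exactly.
#' @param res Grid resolution in degrees (fixed at 0.5 for this analysis).
#' @return A `tc_grid`: data.frame of cell centres with columns `cell`,
#'   `cell_lon`, `cell_lat` (0-based cell index, row-major from the south-west).
#' @export
make_grid <- function(lon_range, lat_range, res = 0.5) {
  if (length(lon_range) != 2 || length(lat_range) != 2 ||
      diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    stop("degenerate lon/lat box", call. = FALSE)
  }
  lons <- seq(floor(lon_range[1] / res) * res + res / 2, lon_range[2], by = res)
  lats <- seq(floor(lat_range[1] / res) * res + res / 2, lat_range[2], by = res)
  g <- expand.grid(cell_lon = lons, cell_lat = lats, KEEP.OUT.ATTRS = FALSE)
  g <- data.frame(cell = seq_len(nrow(g)) - 1L, g)
  attr(g, "res") <- res
  class(g) <- c("tc_grid", "data.frame")
  g
}

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees; vectors recycle.
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Linear time interpolation of a track to a regular step (minutes).
# Returns data.frame with time, lon, lat, delta_p_pa, r_max_km, b, v_trans_ms.
interpolate_track <- function(track, interp_step = 60) {
  pts <- track$points
  if (nrow(pts) < 2) stop("track needs at least 2 points", call. = FALSE)
  t0 <- pts$time[1]
  tn <- pts$time[nrow(pts)]
  times <- seq(t0, tn, by = interp_step * 60)
  tt <- as.numeric(pts$time)
  ti <- as.numeric(times)
  lin <- function(y) stats::approx(tt, y, xout = ti)$y
  lon <- lin(pts$lon); lat <- lin(pts$lat)
  pres <- lin(pts$pres); env <- lin(pts$env_pres)
  rmw <- lin(pts$rmw)
  dp_hpa <- pmax(env - pres, 0)

  # translation speed and pressure tendency from finite differences
  n <- length(ti)
  dt_h <- diff(ti) / 3600
  step_km <- haversine_km(lon[-n], lat[-n], lon[-1], lat[-1])
  v_trans <- c(step_km / dt_h, 0) * 1000 / 3600   # m/s, forward difference
  v_trans[n] <- v_trans[n - 1]
  dp_dt <- c(diff(pres) / dt_h, 0)
  dp_dt[n] <- dp_dt[n - 1]

  data.frame(
    time = times, lon = lon, lat = lat,
    delta_p_pa = dp_hpa * 100, r_max_km = rmw,
    dp_dt_hpa_h = dp_dt, v_trans_ms = v_trans
  )
}

#' Rasterise a storm track to daily maximum sustained winds
#'
#' The track is linearly interpolated in time to `interp_step` minutes; at each
#' snapshot the Holland profile is evaluated at the great-circle distance from
#' the storm centre to every cell centroid, and the daily cell value is the
#' maximum over the day's snapshots (UTC calendar days). Cells farther than
#' `cutoff_km` from the centre at a snapshot contribute 0 for that snapshot.
#'
#' @param track A `tc_track` (see [gen_tracks()] / [read_tracks_csv()]).
#' @param grid A `tc_grid` from [make_grid()].
#' @param interp_step Interpolation step, minutes.
#' @param cutoff_km Distance beyond which the wind is set to 0 (default 500).
#' @param surface_reduction Gradient-to-surface factor, default 0.9.
#' @param b Optional fixed Holland B; if `NULL`, B is computed per snapshot via
#'   [holland_b()].
#' @return A `wind_grid`: data.frame with columns `event_id`, `date`, `cell`,
#'   `cell_lon`, `cell_lat`, `wind_ms` (cells never above 0 are omitted).
#' @export
rasterize_storm <- function(track, grid, interp_step = 60, cutoff_km = 500,
                            surface_reduction = 0.9, b = NULL) {
  snaps <- interpolate_track(track, interp_step)
  days <- as.Date(snaps$time, tz = "UTC")
  uday <- unique(days)
  ncell <- nrow(grid)
  out <- vector("list", length(uday))
  for (k in seq_along(uday)) {
    idx <- which(days == uday[k])
    wmax <- numeric(ncell)
    for (i in idx) {
      d <- haversine_km(grid$cell_lon, grid$cell_lat, snaps$lon[i], snaps$lat[i])
      near <- d <= cutoff_km
      if (!any(near)) next
      bi <- if (is.null(b)) {
        holland_b(snaps$delta_p_pa[i] / 100, snaps$dp_dt_hpa_h[i],
                  snaps$lat[i], snaps$v_trans_ms[i])
      } else b
      w <- holland_wind_speed(d[near], snaps$delta_p_pa[i], snaps$r_max_km[i],
                              bi, snaps$lat[i], snaps$v_trans_ms[i],
                              surface_reduction)
      wmax[near] <- pmax(wmax[near], w)
    }
    keep <- wmax > 0
    if (any(keep)) {
      out[[k]] <- data.frame(
        event_id = track$event_id, date = uday[k],
        cell = grid$cell[keep], cell_lon = grid$cell_lon[keep],
        cell_lat = grid$cell_lat[keep], wind_ms = wmax[keep]
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(event_id = character(), date = as.Date(character()),
                      cell = integer(), cell_lon = numeric(),
                      cell_lat = numeric(), wind_ms = numeric())
  }
  class(res) <- c("wind_grid", "data.frame")
  res
}

#' Derive per-location exposure records from a wind grid
#'
#' Exposure days are days on which the location's grid cell experienced a
#' maximum sustained wind at or above `threshold_kn` (34 knots by default,
#' inclusive). For each storm-location pair the hit day t0 is the earliest
#' exposure day, the event windspeed is the maximum over exposure days (knots),
#' and the cumulative rainfall is summed over `[t0 - rain_window, t0]`.
#'
#' @param wind A `wind_grid` (possibly several storms rbind-ed).
#' @param locations data.frame with columns `location` and `cell` mapping each
#'   location to one grid cell.
#' @param rain Optional data.frame `location`, `date`, `rain_mm`; if `NULL` or
#'   days are missing, the record is kept with `rain_mm = NA` and
#'   `rain_missing = TRUE`.
#' @param rain_window Days before t0 included in the rainfall accumulation
#'   (default 2, i.e. the window `[t0-2, t0]`).
#' @param threshold_kn Exposure threshold in knots (default 34).
#' @return data.frame of exposure records: `location`, `event_id`, `t0`,
#'   `n_exposure_days`, `exposure_days` (list column of Dates),
#'   `event_max_wind_kn`, `cumulative_rain_mm`, `rain_missing`, `year`.
#' @export
classify_exposure <- function(wind, locations, rain = NULL, rain_window = 2,
                              threshold_kn = 34) {
  stopifnot(all(c("location", "cell") %in% names(locations)))
  hit <- merge(as.data.frame(wind), locations, by = "cell")
  hit$wind_kn <- ms_to_knots(hit$wind_ms)
  # inclusive threshold, robust to unit round-trip float error
  hit <- hit[hit$wind_kn >= threshold_kn * (1 - 1e-12), , drop = FALSE]
  if (nrow(hit) == 0) return(empty_exposure())

  keys <- unique(hit[, c("location", "event_id")])
  recs <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- hit[hit$location == keys$location[i] &
                 hit$event_id == keys$event_id[i], , drop = FALSE]
    days <- sort(unique(sub$date))
    t0 <- min(days)
    rain_mm <- NA_real_
    rain_missing <- TRUE
    if (!is.null(rain)) {
      want <- seq(t0 - rain_window, t0, by = "day")
      rsub <- rain[rain$location == keys$location[i] & rain$date %in% want, ]
      if (nrow(rsub) == length(want)) {
        rain_mm <- sum(rsub$rain_mm)
        rain_missing <- FALSE
      }
    }
    data.frame(
      location = keys$location[i], event_id = keys$event_id[i], t0 = t0,
      n_exposure_days = length(days),
      exposure_days = I(list(days)),
      event_max_wind_kn = max(sub$wind_kn),
      cumulative_rain_mm = rain_mm, rain_missing = rain_missing,
      year = as.integer(format(t0, "%Y"))
    )
  })
  out <- do.call(rbind, recs)
  out[order(out$location, out$t0), , drop = FALSE]
}

empty_exposure <- function() {
  data.frame(location = character(), event_id = character(),
             t0 = as.Date(character()), n_exposure_days = integer(),
             exposure_days = I(list()), event_max_wind_kn = numeric(),
             cumulative_rain_mm = numeric(), rain_missing = logical(),
             year = integer())
}
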