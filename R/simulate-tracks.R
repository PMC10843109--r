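# Synthetic best-track generator emulating the structure of IBTrACS records:
# 6-hourly positions, a pressure-deficit lifecycle, radius of maximum winds
# and a pressure-consistent maximum sustained wind.

#' Generate synthetic best-track cyclone records
#'
#' Each storm starts at a random genesis point in the box and follows a smooth
#' random-walk motion (persistent heading with small perturbations). The
#' pressure deficit follows an intensify-peak-decay lifecycle; the maximum
#' sustained wind is tied to the deficit through a square-root
#' pressure-wind relation and clipped to `vmax_bounds`.
#'
#' @param n_storms Number of storms (>= 1).
#' @param region Length-4 numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param years Length-2 integer range of genesis years (default 2000-2014).
#' @param vmax_bounds Allowed range of maximum sustained wind, knots.
#' @return List of `tc_track` objects, each with fields `event_id` and
#'   `points` (data.frame: `time`, `lon`, `lat`, `pres`, `env_pres`, `rmw`,
#'   `vmax_kn`).
#' @export
gen_tracks <- function(n_storms, region, seed,
                       years = c(2000, 2014), vmax_bounds = c(10, 180)) {
  if (n_storms < 1) stop("n_storms must be >= 1", call. = FALSE)
  if (length(region) != 4 || region[2] <= region[1] || region[4] <= region[3]) {
    stop("invalid lon/lat box: need c(lon_min, lon_max, lat_min, lat_max) ",
         "with positive extents", call. = FALSE)
  }
  set.seed(seed)
  env_pres <- 1010
  lapply(seq_len(n_storms), function(s) {
    n_steps <- sample(20:40, 1)                      # 5-10 days at 6 h
    genesis_day <- as.Date(sprintf("%d-01-01", sample(years[1]:years[2], 1))) +
      sample.int(330, 1)
    times <- as.POSIXct(genesis_day, tz = "UTC") + (seq_len(n_steps) - 1) * 21600

    lon <- numeric(n_steps); lat <- numeric(n_steps)
    lon[1] <- stats::runif(1, region[1], region[2])
    lat[1] <- stats::runif(1, region[3], region[4])
    heading <- stats::runif(1, 0, 2 * pi)
    speed_kmh <- stats::runif(1, 10, 30)
    for (i in 2:n_steps) {
      heading <- heading + stats::rnorm(1, 0, 0.15)
      speed_kmh <- max(5, speed_kmh + stats::rnorm(1, 0, 2))
      step_deg <- speed_kmh * 6 / 111               # ~deg per 6 h
      lon[i] <- lon[i - 1] + step_deg * cos(heading) /
        max(cos(lat[i - 1] * pi / 180), 0.2)
      lat[i] <- max(-89, min(89, lat[i - 1] + step_deg * sin(heading)))
    }

    # deficit lifecycle: half-sine ramp to a random peak, then decay
    peak_dp <- stats::runif(1, 20, 80)              # hPa
    phase <- seq(0, pi, length.out = n_steps)
    dp <- peak_dp * sin(phase)^1.5
    dp <- pmax(dp, 1)
    rmw <- stats::runif(1, 25, 70) * (1 - 0.3 * dp / max(dp)) + 5
    rmw <- pmin(pmax(rmw, 20), 80)
    vmax <- pmin(pmax(6.3 * dp^0.644, vmax_bounds[1]), vmax_bounds[2])

    structure(list(
      event_id = sprintf("SYN%04d", s),
      points = data.frame(
        time = times, lon = lon, lat = lat,
        pres = env_pres - dp, env_pres = env_pres,
        rmw = rmw, vmax_kn = vmax
      )
    ), class = "tc_track")
  })
}

#' Write / read best-track records as IBTrACS-like CSV
#'
#' Columns: `SID`, `ISO_TIME`, `LAT`, `LON`, `PRES`, `ENV_PRES`, `RMW`, `WIND`.
#'
#' @param tracks List of `tc_track` objects.
#' @param path Output CSV path.
#' @return `write_tracks_csv`: the path, invisibly. `read_tracks_csv`: a list
#'   of `tc_track` objects.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(SID = tr$event_id,
               ISO_TIME = format(tr$points$time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               LAT = tr$points$lat, LON = tr$points$lon,
               PRES = tr$points$pres, ENV_PRES = tr$points$env_pres,
               RMW = tr$points$rmw, WIND = tr$points$vmax_kn)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("SID", "ISO_TIME", "LAT", "LON", "PRES", "ENV_PRES", "RMW", "WIND")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("track CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$SID), function(sub) {
    tm <- as.POSIXct(sub$ISO_TIME, tz = "UTC")
    o <- order(tm)
    sub <- sub[o, ]; tm <- tm[o]
    if (any(duplicated(tm))) {
      stop("duplicate timestamps in storm ", sub$SID[1], call. = FALSE)
    }
    if (any(sub$ENV_PRES < sub$PRES)) {
      stop("environmental pressure below central pressure in storm ",
           sub$SID[1], call. = FALSE)
    }
    structure(list(
      event_id = sub$SID[1],
      points = data.frame(time = tm, lon = sub$LON, lat = sub$LAT,
                          pres = sub$PRES, env_pres = sub$ENV_PRES,
                          rmw = sub$RMW, vmax_kn = sub$WIND)
    ), class = "tc_track")
  })
}
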