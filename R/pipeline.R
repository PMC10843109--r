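# End-to-end orchestration: simulate -> wind field -> exposure -> baseline ->
# event effects -> meta-regression, driven by a single JSON configuration and
# reproducible given the seed. Every stage writes its artifact as CSV/JSON in
# the output directory; the run report carries a provenance block.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed for the whole run.
#' @param threshold_kn Exposure threshold in knots (default 34).
#' @param exclusion_days Post-storm exclusion window, one of 30/60/90
#'   (default 60).
#' @param knots_per_year Event-spline knot density (default 6).
#' @param meta_df Natural-spline df for exposure-response curves (default 2).
#' @param causes Death streams to analyse (subset of
#'   `c("all", "cvd", "resp")`).
#' @param simulate List of generator settings (`n_storms`, `n_locations`,
#'   `years`, `region`, `effect` = list(shape, peak, duration)) or `NULL` to
#'   read pre-existing input files.
#' @param paths Named list of input paths (`tracks`, `mortality`, `rainfall`)
#'   when not simulating.
#' @param rain_window Rainfall accumulation window before t0, days.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, threshold_kn = 34,
                            exclusion_days = 60, knots_per_year = 6,
                            meta_df = 2, causes = "all",
                            simulate = list(n_storms = 5, n_locations = 12,
                                            years = 15,
                                            region = c(120, 135, 10, 30),
                                            effect = list(shape = "rect",
                                                          peak = 0.3,
                                                          duration = 21)),
                            paths = NULL, rain_window = 2) {
  stopifnot(threshold_kn > 0, exclusion_days >= 1,
            all(causes %in% c("all", "cvd", "resp")))
  if (!exclusion_days %in% c(30, 60, 90)) {
    warning("exclusion_days outside the analysed set {30, 60, 90}")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 threshold_kn = threshold_kn,
                 exclusion_days = exclusion_days,
                 knots_per_year = knots_per_year, meta_df = meta_df,
                 causes = causes, simulate = simulate, paths = paths,
                 rain_window = rain_window),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$simulate <- if (is.null(cfg$simulate)) NULL else as.list(cfg$simulate)
  if (!is.null(cfg$simulate$effect)) {
    cfg$simulate$effect <- as.list(cfg$simulate$effect)
  }
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  plain$out_dir <- NULL    # hash the scientific settings, not where they land
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Validate pipeline input files
#'
#' Schema diagnostics (never an error): required columns, non-negative integer
#' deaths, per-location date contiguity, positive population, strictly
#' increasing track timestamps.
#'
#' @param paths Named list/vector with any of `tracks`, `mortality`,
#'   `population`.
#' @return data.frame with `file`, `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(paths) {
  rows <- list()
  add <- function(file, check, pass, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(file = file, check = check,
                                            pass = pass, detail = detail)
  }
  if (!is.null(paths$mortality) && file.exists(paths$mortality)) {
    m <- utils::read.csv(paths$mortality, stringsAsFactors = FALSE)
    need <- c("location", "date", "deaths_all")
    add(paths$mortality, "columns", all(need %in% names(m)),
        paste(setdiff(need, names(m)), collapse = ","))
    if (all(need %in% names(m))) {
      m$date <- as.Date(m$date)
      dnum <- all(m$deaths_all >= 0 & m$deaths_all == round(m$deaths_all))
      add(paths$mortality, "deaths_nonneg_integer", dnum)
      gaps <- vapply(split(m$date, m$location), function(d) {
        d <- sort(d)
        i <- which(diff(d) != 1)
        if (length(i)) as.character(d[i[1]]) else ""
      }, character(1))
      bad <- gaps[gaps != ""]
      add(paths$mortality, "date_contiguity", length(bad) == 0,
          if (length(bad)) {
            paste0("gap after ", bad[1], " in ", names(bad)[1])
          } else "")
    }
  }
  if (!is.null(paths$population) && file.exists(paths$population)) {
    p <- utils::read.csv(paths$population, stringsAsFactors = FALSE)
    add(paths$population, "columns",
        all(c("location", "year", "pop") %in% names(p)))
    if ("pop" %in% names(p)) {
      add(paths$population, "population_positive", all(p$pop > 0))
    }
  }
  if (!is.null(paths$tracks) && file.exists(paths$tracks)) {
    tr <- utils::read.csv(paths$tracks, stringsAsFactors = FALSE)
    need <- c("SID", "ISO_TIME", "LAT", "LON", "PRES", "ENV_PRES", "RMW",
              "WIND")
    add(paths$tracks, "columns", all(need %in% names(tr)),
        paste(setdiff(need, names(tr)), collapse = ","))
    if (all(need %in% names(tr))) {
      bad <- vapply(split(tr, tr$SID), function(s) {
        any(diff(as.POSIXct(s$ISO_TIME, tz = "UTC")) <= 0)
      }, logical(1))
      add(paths$tracks, "timestamps_increasing", !any(bad),
          if (any(bad)) paste("storm", names(bad)[bad][1]) else "")
    }
  }
  do.call(rbind, rows)
}

#' Run the full two-stage pipeline
#'
#' Executes simulate (optional), wind field, exposure classification, baseline
#' and event-effect estimation per location and cause, and the second-stage
#' meta-regression; writes every intermediate artifact under
#' `config$out_dir` and returns (and writes) a JSON run report with counts,
#' per-cause POC summaries, pooled RRs and a provenance block.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "init"
  report <- list(provenance = list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("cyclonemort")),
    r_version = as.character(getRversion())
  ))

  tryCatch({
    # ---- stage: simulate (or load) ------------------------------------------
    stage <- "simulate"
    if (!is.null(config$simulate)) {
      sim <- simulate_world(config)
      tracks <- sim$tracks; grid <- sim$grid; locations <- sim$locations
      mortality <- sim$mortality; rainfall <- sim$rainfall
      write_tracks_csv(tracks, file.path(config$out_dir, "tracks.csv"))
      write_series_csv(sim$series, config$out_dir)
      utils::write.csv(locations, file.path(config$out_dir, "locations.csv"),
                       row.names = FALSE)
    } else {
      tracks <- read_tracks_csv(config$paths$tracks)
      mortality <- utils::read.csv(config$paths$mortality,
                                   stringsAsFactors = FALSE)
      mortality$date <- as.Date(mortality$date)
      rainfall <- utils::read.csv(config$paths$rainfall,
                                  stringsAsFactors = FALSE)
      rainfall$date <- as.Date(rainfall$date)
      locations <- utils::read.csv(config$paths$locations,
                                   stringsAsFactors = FALSE)
      all_lon <- unlist(lapply(tracks, function(t) t$points$lon))
      all_lat <- unlist(lapply(tracks, function(t) t$points$lat))
      grid <- make_grid(range(all_lon) + c(-3, 3), range(all_lat) + c(-3, 3))
    }
    report$n_locations <- length(unique(mortality$location))
    report$n_storms <- length(tracks)

    # ---- stage: wind field ---------------------------------------------------
    stage <- "windfield"
    wind <- do.call(rbind, lapply(tracks, rasterize_storm, grid = grid))
    utils::write.csv(as.data.frame(wind),
                     file.path(config$out_dir, "wind_grid.csv"),
                     row.names = FALSE)

    # ---- stage: exposure -----------------------------------------------------
    stage <- "exposure"
    exposures <- classify_exposure(wind, locations, rainfall,
                                   rain_window = config$rain_window,
                                   threshold_kn = config$threshold_kn)
    exp_out <- exposures[, setdiff(names(exposures), "exposure_days")]
    utils::write.csv(exp_out, file.path(config$out_dir, "exposures.csv"),
                     row.names = FALSE)
    report$n_events <- nrow(exposures)

    # ---- stage: baseline + event effects ------------------------------------
    stage <- "events"
    events <- list()
    if (nrow(exposures) > 0) {
      for (loc in unique(exposures$location)) {
        msub <- mortality[mortality$location == loc, , drop = FALSE]
        loc_ev <- exposures[exposures$location == loc, , drop = FALSE]
        ctrl <- control_periods(msub$date, loc_ev, config$exclusion_days)
        for (cause in config$causes) {
          col <- switch(cause, all = "deaths_all", cvd = "deaths_cvd",
                        resp = "deaths_resp")
          ser <- data.frame(date = msub$date, deaths = msub[[col]],
                            pop = msub$pop)
          bl <- fit_baseline(ser, ctrl)
          nz <- estimate_noise(bl)
          for (i in seq_len(nrow(loc_ev))) {
            eff <- fit_event_effect(
              bl, nz, t0 = loc_ev$t0[i],
              other_events = loc_ev[-i, , drop = FALSE],
              exclusion_days = config$exclusion_days,
              knots_per_year = config$knots_per_year)
            s <- summarize_event(eff)
            s$location <- loc
            s$event_id <- loc_ev$event_id[i]
            s$cause <- cause
            events[[length(events) + 1]] <- s
          }
        }
      }
    }
    events <- if (length(events)) do.call(rbind, events) else NULL
    if (!is.null(events)) {
      utils::write.csv(events, file.path(config$out_dir, "events.csv"),
                       row.names = FALSE)
      poc_by_cause <- lapply(split(events$poc_length, events$cause), function(p)
        list(mean = mean(p), sd = if (length(p) > 1) stats::sd(p) else 0))
      report$poc_by_cause <- poc_by_cause
    }

    # ---- stage: meta ---------------------------------------------------------
    stage <- "meta"
    report$pooled_rr <- NULL
    if (!is.null(events)) {
      meta <- build_meta_dataset(events[events$rr_defined, , drop = FALSE],
                                 exposures)
      if (nrow(meta) >= 3) {
        utils::write.csv(as.data.frame(meta),
                         file.path(config$out_dir, "meta_dataset.csv"),
                         row.names = FALSE)
        pooled <- lapply(split(meta, meta$cause), function(sub) {
          fit <- suppressMessages(fit_mixmeta(sub, ~1))
          se <- sqrt(fit$vcov[1, 1])
          list(rr = exp(fit$beta[1]),
               lo = exp(fit$beta[1] - 1.96 * se),
               hi = exp(fit$beta[1] + 1.96 * se),
               tau2 = fit$tau2, n = nrow(sub))
        })
        report$pooled_rr <- pooled
        if (length(unique(meta$wind)) >= 3) {
          crv <- er_curve(meta, "wind", df = config$meta_df)
          utils::write.csv(as.data.frame(crv),
                           file.path(config$out_dir, "er_wind.csv"),
                           row.names = FALSE)
        }
      }
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

# Simulated world for the demo pipeline: storms over a region, locations on
# grid cells under the tracks, mortality series with effects injected at the
# true exposure hit days (so ground truth and detected exposure align).
simulate_world <- function(config) {
  sc <- config$simulate
  tracks <- gen_tracks(sc$n_storms, sc$region, seed = config$seed,
                       years = c(2000, max(2000, 2000 + sc$years - 2)))
  grid <- make_grid(sc$region[1:2] + c(-2, 2), sc$region[3:4] + c(-2, 2))

  # put locations on the cells with the strongest storm winds so exposure occurs
  wind <- do.call(rbind, lapply(tracks, rasterize_storm, grid = grid))
  cell_max <- tapply(wind$wind_ms, wind$cell, max)
  ranked <- as.integer(names(sort(cell_max, decreasing = TRUE)))
  n_loc <- sc$n_locations
  cells <- ranked[seq_len(min(n_loc, length(ranked)))]
  if (length(cells) < n_loc) {
    cells <- c(cells, setdiff(grid$cell, cells)[seq_len(n_loc - length(cells))])
  }
  locations <- data.frame(location = sprintf("loc%03d", seq_len(n_loc)),
                          cell = cells)

  # provisional exposure (no rain yet) to learn the true hit days
  exposures0 <- classify_exposure(wind, locations,
                                  threshold_kn = config$threshold_kn)
  effects <- list()
  if (nrow(exposures0) > 0) {
    for (i in seq_len(nrow(exposures0))) {
      effects[[i]] <- list(location = exposures0$location[i],
                           t0 = exposures0$t0[i],
                           shape = sc$effect$shape, peak = sc$effect$peak,
                           duration = sc$effect$duration)
    }
  }
  cfg <- sim_config(n_locations = n_loc, years = sc$years,
                    injected_effects = effects, seed = config$seed)
  series <- gen_location_series(cfg)
  list(tracks = tracks, grid = grid, locations = locations,
       mortality = series$mortality, rainfall = series$rainfall,
       series = series, truth = series$truth)
}
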