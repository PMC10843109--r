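# cyclonemort

Two-stage estimation of tropical-cyclone (TC) mortality impacts, for
environmental-epidemiology researchers working with daily death counts and
best-track storm archives.

Single-storm studies do not generalize: TC health effects vary strongly with
storm intensity, place and time. This package implements, end to end, the
pipeline used in multicountry TC epidemiology:

1. **Exposure.** Best-track records (IBTrACS-style: centre position, central
   and environmental pressure, radius of maximum winds) are converted to
   gridded daily maximum sustained winds at 0.5° × 0.5° with a parametric
   Holland vortex profile,

   V(r) = √( BΔp/ρ · (r_m/r)^B · e^−(r_m/r)^B + (r f_c/2)² ) − r f_c/2,

   and a location is *exposed* on days when its grid cell reaches ≥ 34 knots
   (17.5 m/s, 63 km/h — gale force). The first such day is the hit day t₀.

2. **Storm-specific effects (stage 1).** Daily deaths follow a mixed Poisson
   model,

   Y_t | ε_t ~ Poisson( μ_t · [1 + f(t)] · ε_t ),
   μ_t = exp( α(t) + s(t) + w(t) ) · offset(N_y),

   with a slow trend α, yearly seasonality s, day-of-week effects w, a
   population offset N_y, and autocorrelated multiplicative noise ε. The
   baseline μ is fitted by Poisson regression on *control* days (outside
   exposure days and a 60-day post-storm washout), the noise variance and
   AR(1) structure are estimated from control-day residuals, and the relative
   increase f(t) is a natural cubic spline (6 knots/year) with a level
   discontinuity at t₀, estimated by generalized least squares. The **period
   of concern (POC)** is the first contiguous post-t₀ run of days whose 95% CI
   for f excludes 0; excess deaths are Σ μ̂ f̂ over the POC, and the relative
   risk is RR = observed / expected with expected = observed − excess.

3. **Pooling (stage 2).** Storm-specific log RRs (with their known SEs) are
   pooled by a mixed meta-regression — random intercept per location (storms
   nested within locations), between-location variance τ² by REML — giving
   pooled exposure-response curves (natural spline, df = 2) in windspeed,
   cumulative rainfall and calendar year.

A synthetic-data module generates storms, populations, rainfall and mortality
series with *known injected effects*, so every stage is testable without any
restricted data.

## Worked example

Estimate one storm's effect on a simulated series with a known +30% / 21-day
injected effect at μ ≈ 50 deaths/day:

```r
library(cyclonemort)

t0 <- as.Date("2007-09-10")
cfg <- sim_config(years = 15, baseline_rate = 50, noise_sd = 0.05,
                  noise_ar1 = 0.5,
                  injected_effects = list(list(location = "loc001", t0 = t0,
                                               shape = "rect", peak = 0.3,
                                               duration = 21)),
                  seed = 42)
sim <- gen_location_series(cfg)
m <- sim$mortality
series <- data.frame(date = m$date, deaths = m$deaths_all, pop = m$pop)

ctrl     <- control_periods(series$date, data.frame(t0 = t0), exclusion_days = 60)
baseline <- fit_baseline(series, ctrl)
noise    <- estimate_noise(baseline)
effect   <- fit_event_effect(baseline, noise, t0)
summarize_event(effect)
#>           t0  poc_start poc_length observed expected excess excess_lo excess_hi
#> 1 2007-09-10 2007-09-10         45     2669     2270  399.5     299.4     499.6
#>      rr rr_lo rr_hi        p window_flagged rr_defined
#> 1 1.176 1.125 1.229 5.77e-13          FALSE      TRUE
```

The detected POC starts on the hit day and lasts 45 days; 399.5 excess deaths
(95% CI 299–500) against a ground truth of 317 (`sim$truth[[1]]$true_excess`),
which the CI covers. The POC is longer than the injected 21 days because the
6-knots/year spline deliberately smooths the effect — it conserves the excess
mass but spreads it in time (across 100 replicates the mean relative bias of
the excess is about +2%; see the methods vignette).

The full pipeline (simulate → wind field → exposure → events → meta), from
the packaged demo configuration:

```r
cfg <- read_pipeline_config(system.file("extdata", "demo_config.json",
                                        package = "cyclonemort"))
cfg$out_dir <- "demo_out"
report <- run_pipeline(cfg)
#> $n_storms   5      $n_events  12
#> $poc_by_cause$all  mean 39.4, sd 7.3 days
#> $pooled_rr$all     rr 1.153 (1.134, 1.173), tau2 0, n 12
```

Twelve storm-location events are detected; pooling their RRs gives 1.153
(95% CI 1.134–1.173) — the smoothed imprint of the injected +30% pulses. The
same run is available from the command line:

```sh
Rscript inst/cli/cyclonemort run-all --config inst/extdata/demo_config.json
```

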