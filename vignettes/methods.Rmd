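---
title: "Methods: storm-specific excess mortality, periods of concern, and pooled exposure-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclonemort)
```

## The model

Daily death counts in a location are modelled as a mixed Poisson process

$$Y_t \mid \varepsilon_t \sim \mathrm{Poisson}\!\big(\mu_t\,[1 + f(t)]\,\varepsilon_t\big),
\qquad
\mu_t = N_y\, e^{\alpha(t) + s(t) + w(t)},$$

where $\mu_t$ is the expected count under normal conditions — a population
offset $N_y$ (annual), a slow trend $\alpha(t)$, a yearly seasonal term
$s(t)$ and day-of-week effects $w(t)$ — $f(t)$ is the relative increase in
mortality caused by a storm ($f \cdot 100$ = percent increase), and
$\varepsilon_t$ is a stationary, autocorrelated, multiplicative noise process
with $E[\varepsilon] = 1$ representing natural variability (epidemics,
weather) beyond Poisson sampling. The modelling assumptions are: counts are
conditionally Poisson; natural variability is multiplicative and
exchangeable with the storm effect; and $f \equiv 0$ on days sufficiently far
from any storm ("control periods").

## Stage 1: baseline, noise, event effect

**Baseline.** $\mu_t$ is fitted by a log-link Poisson GLM on control days
only — all days except storm exposure days and a post-storm washout window
$[t_0, t_0 + 60]$ (30- and 90-day variants are sensitivity settings). The
design is a natural cubic spline in time for $\alpha$ (1 interior knot per
7 years), Fourier seasonality (2 harmonics), and six weekday indicators
against Monday. Defaults follow common surveillance practice; both are
configurable. $\hat\mu$ is then *predicted* for all days, including
non-control days.

**Noise.** On control days the relative residuals $z_t = Y_t/\hat\mu_t - 1$
satisfy $\mathrm{Var}(z_t) \approx \nu/\mu_t + \sigma_\varepsilon^2$ and,
because the Poisson part is serially independent,
$\mathrm{Cov}(z_t, z_{t+k}) = \sigma_\varepsilon^2 \rho_\varepsilon(k)$ for
$k \ge 1$. We therefore estimate the AR(1) noise from the lagged
autocovariances $c_k$: $\hat\phi = \sum_k c_k c_{k+1} / \sum_k c_k^2$,
$\hat\sigma^2_\varepsilon = c_1/\hat\phi$, and the Poisson dispersion from
the variance identity $\hat\nu = \overline{\mu z^2} -
\hat\sigma^2_\varepsilon \bar\mu$. A detectability gate ($c_1$ above 1.645
times its sampling SE, $\hat\phi \ge 0.1$) prevents reading noise into pure
Poisson data; below the gate the series is treated as pure Poisson and any
white extra-variance is absorbed into $\nu$. We chose this over a direct
least-squares decomposition of $z_t^2$ on $1/\hat\mu_t$ because, at
realistic counts (30–50 deaths/day), the spread of $1/\mu_t$ is so small
that the decomposition's intercept is dominated by its own sampling error;
the lag-based estimator recovers $\phi = 0.7$ within $\pm 0.1$ in over 90%
of 20-year replicates at 100 deaths/day, which the decomposition cannot.

**Event effect.** Over a window of ±365 days around the hit day $t_0$
(clipped to the data, other storms' washout days dropped), $f$ is
parameterised as a natural cubic spline with 6 interior knots per year —
placed evenly, so the basis is invariant to calendar shifts — plus an
indicator column $1[t \ge t_0]$ that permits a level discontinuity at the
hit day (sudden direct deaths). The coefficients are estimated by
generalized least squares of $z$ on this basis under the covariance

$$\Sigma_{st} = \begin{cases}
\hat\nu/\hat\mu_t + \hat\sigma_\varepsilon^2 & s = t\\
\hat\sigma_\varepsilon^2\, \hat\phi^{|s-t|} & s \ne t
\end{cases}
\;+\; \big[X_{\mathrm{bl}}\, \hat V_\theta\, X_{\mathrm{bl}}'\big]_{st},$$

where the final low-rank term propagates the baseline GLM's estimation
uncertainty ($z$ is computed with $\hat\mu$, not $\mu$). In null
simulations this term is what moves pointwise CI coverage from ~93.3% to
~94.5%; it can be disabled (`baseline_uncertainty = FALSE`) for oracle
comparisons against OLS with an explicitly constructed covariance.

**POC, excess, RR.** The period of concern is the first maximal contiguous
run of days at/after $t_0$ whose 95% CI for $f$ (normal approximation,
$\pm 1.96\,\mathrm{SE}$) excludes 0 from below; a "longest run" tie-break is
available by flag, and the total count of significant days is reported for
diagnostics. Excess deaths are $\sum_{t \in \mathrm{POC}} \hat\mu_t
\hat f(t)$ with SE through the same linear functional of the GLS
coefficients; observed deaths are summed over the POC, expected = observed −
excess, RR = observed/expected, and the log-RR SE uses the delta method
SE(excess)/expected. When no POC is detected the quantities are accumulated
over a minimal direct window $[t_0, t_0+2]$ and flagged — the accumulation
window is otherwise the POC itself — our design choice for where to
accumulate the burden.

## Stage 2: mixed meta-regression

Each storm-location event contributes a row $(\log RR_i,\ se_i)$ with
covariates (event maximum windspeed in knots, cumulative rainfall in mm over
$[t_0-2, t_0]$, calendar year). The pooling model is a linear mixed model on
the log-RR scale with *known* within-row variances $se_i^2$, a random
intercept per location (storms nested within locations), and
between-location variance $\tau^2$ estimated by REML, profiled by 1-D
optimisation; the block structure (diag$(v)$ + $\tau^2 J$ per location)
makes each evaluation cheap. $\tau^2 = 0$ collapses exactly to the
inverse-variance-weighted fixed-effects estimate (a tested oracle), and the
REML optimum is verified against a brute-force grid scan. Log scale is used
because it is the meta-analytic standard and keeps pooled RRs positive.

Exposure-response curves use one covariate at a time (univariate, matching
the stratified presentation this family of analyses uses), expanded in a
natural spline with df = 2: one interior knot at the covariate median,
boundary knots at the 1st/99th percentiles. Curves are reported as
$RR(x) = \exp(\hat s(x) - \hat s(x_{\mathrm{ref}}))$ with Wald CIs from the
fixed-effects covariance; the reference $x_{\mathrm{ref}}$ is the minimum
observed exposure (34 kn for wind) — the anchoring convention is recorded in
the curve's attributes since published curves do not state theirs. Beyond
the boundary knots the natural spline is linear and grid points outside the
observed range are flagged as extrapolation. Country summaries are
per-country intercept-only fits (< 3 rows → unestimable; single-location
countries lose the random effect, with a message); temporal trends are year
curves, overall or per country.

## The synthetic world

The generator draws, per location: annual population with mild growth
(default +5%/decade, reference 100,000); $\mu_t$ from a configurable
baseline rate, log-linear trend per decade, cosine seasonality and
day-of-week multipliers; AR(1) Gaussian log-noise $\eta_t$ with stationary
SD $\sigma$ and lag-1 correlation $\phi$, exponentiated and normalised so
$E[\varepsilon] = 1$ ($\varepsilon = e^{\eta - \sigma^2/2}$); injected
effects of known shape (rectangular, triangular, exponential-decay), peak
and duration; and Poisson draws $Y_t \sim \mathrm{Poisson}(\mu_t (1 +
f(t)) \varepsilon_t)$. Cause-specific streams are multinomial thinnings of
the all-cause stream (32% cardiovascular, 10% respiratory) — thinning a
Poisson process yields independent Poisson sub-streams, our resolution of
the open question about cause correlation. Rainfall is a seasonal gamma
wet-day process with additive bursts on effect days; only its ordering and
magnitude matter downstream. Default noise ($\sigma = 0.05$, $\phi = 0.5$)
and effect (+30% for 21 days) follow the calibration scenarios stated for
this pipeline's acceptance checks. Synthetic best tracks are 6-hourly
random walks with a half-sine pressure-deficit lifecycle, radius of maximum
winds in 20–80 km, and a square-root pressure-wind relation.

What the generator does **not** emulate: real country borders or location
geographies, ICD coding and cause misclassification, reporting delays or
data gaps, temperature/holiday mortality structure, spatially correlated
noise across locations, or landfall friction effects on wind. A green
recovery test therefore establishes correctness of the estimators under the
stated generative model, not robustness to those real-data features.

## Wind field

The Holland gradient-wind profile uses air density 1.15 kg/m³ and the
Coriolis parameter from latitude; the shape parameter B comes from the
improved-Holland surface regression (pressure deficit, its time derivative,
latitude, translation speed), clipped to [0.5, 2.5], or may be supplied
directly. Translation asymmetry adds the storm's forward speed scaled by the
bounded attenuation factor $r_m r/(r_m^2 + r^2)$; a scalar
gradient-to-surface reduction factor (default 0.9) and a 500 km cutoff
radius are configurable package defaults. Tracks
are interpolated linearly in time (default hourly; the test oracle uses
1-minute steps), the profile is evaluated at the great-circle distance to
each 0.5° cell centre, and daily cell values are maxima over the UTC day's
snapshots. Input winds are assumed 1-minute sustained; a convention
conversion factor is exposed (default 1). All qualifying days of one storm
at one location are merged into a single exposure record.

## Numerical choices and degenerate inputs

- GLS solves use Cholesky whitening; a non-positive-definite covariance gets
  a relative ridge (1e-8 of the mean diagonal) with a warning.
- REML profiling uses `optimize` on $[0, 10(\mathrm{var}(y) \vee \max v)]$
  with tolerance 1e-10 and an explicit boundary check at $\tau^2 = 0$.
- A single population point extrapolates as a constant with a warning; an
  empty control set is a hard error; an event window fully excluded by other
  storms returns a flagged empty result; expected deaths ≤ 0 flags the RR
  as undefined.
- POC ties: first significant run wins (the source speaks of "a post-TC
  period", singular); `rule = "longest"` is the documented alternative.
- Exposure threshold comparison allows 1e-12 relative tolerance so a day at
  exactly 34 knots survives unit round-trips.

## Known limitations

- **POC length under sharp effects.** The 6-knots/year spline (~61-day knot
  spacing, with only a level jump at $t_0$) cannot represent a sharp effect
  *offset*: a 21-day rectangular pulse is smeared over ~50–60 days. The
  excess mass is conserved (mean relative bias ≈ +2% across 100
  replicates), but the CI-based POC tracks the smeared bump: median
  estimated POC ≈ 41 days for a 21-day pulse. Interpret POC as "period of
  detectable elevation under the smoothing prior", not as the effect's
  support.
- Pointwise null CI coverage is ~94.5% rather than exactly 95%: the residual
  gap comes from Poisson skewness and the plug-in of $\hat\mu$ in the
  variance weights.
- Only AR(1) noise is implemented; the seasonal term is harmonic (a
  periodic-spline option is stubbed); slope breaks at $t_0$ and summed
  discontiguous POC spells are recorded as open alternatives, not
  implemented.
- Wald CIs in the meta stage ignore $\tau^2$ estimation error and undercover
  in very small designs (few locations); this is the standard behaviour of
  known-variance mixed meta-regression.
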