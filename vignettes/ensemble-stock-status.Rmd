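---
title: "Ensemble assessment of global fish stock status: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble assessment of global fish stock status: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Scientifically assessed fish stocks report two status ratios per year: the
biomass relative to the biomass that would sustain maximum sustainable
yield, B/B~MSY~, and the exploitation rate (the fraction of biomass caught
per year) relative to its MSY counterpart, U/U~MSY~. A stock is "within
target" when B/B~MSY~ ≥ 1 and U/U~MSY~ ≤ 1. Whether *global* stocks have
recovered, however, is not a property of any single stock: it requires
averaging hundreds of heterogeneous series — stocks that differ by orders
of magnitude in size, start reporting in different decades, and stop
reporting at different recent years.

`fishstatus` treats that averaging step itself as the object of study. It
computes an ensemble of ten diagnostics of global status — five statistical
averaging methods crossed with two rebuilding-target definitions — rather
than committing to one, and summarises their agreement (ensemble mean and
spread), alongside per-stock diagnostics: Kobe-quadrant status, trend
slopes over each stock's most recent decade of data, and the proportion of
stocks within targets since 1950.

## Averaging methods

For a year $t$ with reporting stocks $i = 1..n_t$ carrying ratios $x_{it}$
and time-invariant weights $w_i$:

* **Unweighted mean** and **median** ($w_i = 1$): every stock counts
  equally (a species-diversity view).
* **Biomass-weighted** and **catch-weighted** means: $w_i$ is the stock's
  time-mean observed biomass or time-mean catch (a food-supply view).
  Weighted mean $\bar x_w = \sum w_i x_{it} / \sum w_i$ with standard error
  $\sqrt{\sum w_i^2 (x_{it}-\bar x_w)^2} / \sum w_i$, which reduces to the
  familiar $\mathrm{sd}\sqrt{(n-1)/n}/\sqrt n$ under equal weights. Weights
  are deliberately *time-invariant*: annual weights would confound weight
  trends with status trends.
* **Median SE** uses the normal-theory factor $1.2533\,\mathrm{SE_{mean}}$;
  a bootstrap SE is available behind a flag. This avoids a bootstrap
  dependency in the default path while remaining honest about the median's
  efficiency.
* **Hierarchical state-space smoother** (below).

Averaging is done on the arithmetic ratio scale: the recovery criterion is
stated on that scale and the Kobe axes are linear. A geometric-mean variant
(`method = "geometric_mean"`) is provided for sensitivity analysis but is
not part of the ten-member ensemble.

## Rebuilding targets

* `assessment_bmsy`: the assessment's own reference point. A pre-divided
  B/B~MSY~ series, where reported, takes precedence over B divided by the
  reference point (the assessment-reported ratio is authoritative; a
  disagreement between the two is flagged with a warning).
* `half_max_biomass`: the precautionary target of half the historical
  maximum biomass, computed as half the maximum of the stock's *observed*
  biomass series (non-missing years only). This requires no additional
  model, at the cost of depending on the observation window: a stock first
  assessed after its depletion will understate its historical maximum. The
  exploitation target is U~MSY~ under both definitions, so switching
  targets rescales each stock's biomass series by one positive constant and
  leaves the exploitation series untouched.

## The state-space smoother

The smoother separates a shared global signal from stock-level offsets and
observation noise, on the log-ratio scale (ratios are positive and
right-skewed; a random walk is scale-free on logs):

$$x_t = x_{t-1} + \eta_t,\quad \eta_t \sim N(0, \sigma^2_{proc})$$
$$a_s \sim N(0, \sigma^2_{stock}), \qquad
  y_{st} = x_t + a_s + \varepsilon_{st},\quad
  \varepsilon_{st} \sim N(0, \sigma^2_{obs})$$

Because the offsets are static, the model is handled *exactly* by a Kalman
filter over the augmented state $(x_t, a_1, \dots, a_S)$: the random walk
receives process noise, the offsets none, and each year's observations are
absorbed in one block update (one Cholesky factorisation of the
$n_t \times n_t$ innovation covariance). We chose exact joint estimation
over the cheaper two-stage alternative (centering each stock by its own
mean and filtering the residual panel) because the block-update filter is
fast enough for panels of a few hundred stocks, and because it makes the
marginal likelihood exactly the multivariate-normal density implied by the
joint covariance — a property the test suite verifies directly by brute
force on small instances (tolerance 1e-8).

Numerical choices:

* The initial state prior is $x_1 \sim N(\mu_0, 10)$ with $\mu_0$ the grand
  mean of the log observations. Centering on $\mu_0$ with variance 10 is
  effectively diffuse for status ratios (which live well within
  $e^{\pm 3}$) while keeping the filter well conditioned; a genuinely huge
  prior variance (say $10^6$) makes the first-year update numerically
  indefinite in corners of the parameter space and derails the optimiser.
* Variances are estimated by bounded quasi-Newton (L-BFGS-B) on log
  standard deviations, three fixed starting points, bounds
  $[10^{-4}, 10]$; the best converged start wins. Non-convergence from
  every start is an error carrying the per-start log; degenerate
  (constant) input drives variances to the lower bound with a warning.
* Smoothing uses the Rauch–Tung–Striebel recursion over the augmented
  state; the smoothed trajectory is defined for every year of the window,
  including years with no observations, which are bridged by the random
  walk with correspondingly inflated variance.
* Back-transform to the ratio scale: estimate $\exp(m + v/2)$ (lognormal
  mean correction), delta-method SE $\exp(m + v/2)\sqrt v$.

With constant input the level is recovered exactly, but the offset SD is
only weakly identified (there is no between-stock spread to measure against
the prior); the identifiable statements — a flat log-scale trajectory and a
process variance at its bound — are what the tests assert.

## Ensemble summary and recovery classification

The ensemble per year is the unweighted mean of the available member
estimates with a normal-approximation 95% interval, mean ± 1.96 SD across
members. Percentile intervals are unstable with ten members; the choice is
recorded in each run's metadata. The reporting window starts in 1980 and
ends at the latest year where at least half the filtered stocks still
report (recent assessment years are incomplete); both are configurable.
Years with fewer than 20 reporting stocks are masked in every member.

A member "supports recovery" at the endpoint year when its global average
biomass is at or above target and its exploitation at or below target.
Values on a target line count as within target — the boundary is a
measure-zero event on continuous data, but fixing it (with a small
floating-point tolerance, 1e-8) keeps classification reproducible, and the
inclusive direction is the one consistent with the Kobe "green" quadrant.
Each member also reports whether its 95% CI (estimate ± 1.96 SE) straddles
the target line — low statistical confidence in either direction.

## Per-stock diagnostics

* **Kobe quadrants**: green (b ≥ 1, u ≤ 1), red (b < 1, u > 1), yellow
  split by which criterion fails.
* **Trends**: OLS slope of each ratio on calendar year over the stock's
  most recent ten *observed* years (not calendar years — series with
  recent gaps use their last available decade), requiring at least eight
  observations. Classification is by the raw slope sign; a p-value
  threshold is available behind a flag but off by default, since trend
  fractions are descriptive here, not hypothesis tests.
* **Proportion series**: among stocks reporting in a year, the fraction
  within each target, from 1950, defined where at least 20 stocks report.
  The extrema report returns the maximum historical proportion below the
  biomass target and over the exploitation target, their years (earliest
  on ties, with a message), and the improvement to the final year in
  percentage points.
* The "up to" headline percentages are maxima across the two target
  definitions.

## The synthetic panel generator

`simulate_panel()` produces panels with known truth from Schaefer
(logistic) surplus production, $B_{t+1} = B_t + r B_t (1 - B_t/K) - C_t$
with $C_t = U_t B_t$, chosen because the reference points have closed
forms ($B_{MSY} = K/2$, $U_{MSY} = r/2$), giving exact truths for recovery
tests. The default configuration is the package's standing study
condition: 200 stocks over 1950–2016; carrying capacities lognormal
(sdlog 1.5, spanning orders of magnitude); growth rates uniform on
[0.1, 0.8]; a fish-down-then-partial-rebuild exploitation history (U ramps
from 0.2 to 1.8 × U~MSY~ over the first 60% of years, then declines to
0.9 × U~MSY~, with lognormal per-stock path heterogeneity, sd 0.3);
20% lognormal observation error applied independently to biomass and
exploitation rate (catch exact); assessment start years staggered
uniformly over up to 25 years; and 30% of stocks truncated by one to five
recent years. Where the generator needed a number that no external
constraint fixes (the stagger width, the path heterogeneity), we chose
once what a fisheries analyst would call a realistic panel and left it.

The generator emulates the *statistical* structure of an assessed-stock
compilation — size disparities, staggered windows, recent missingness,
paired noisy ratio series with exact reference points — and deliberately
not its biology: no age structure, no process error in $r$ or $K$, no
assessment-model feedback (reference points are reported without error).
Passing tests on synthetic panels therefore demonstrate that the
*statistics* are computed correctly under known truth, not that any
particular empirical conclusion holds; the empirical path
(`read_ram_long()` on a RAM-style export) shares every line of code after
input.

Degenerate dynamics are guarded: exploitation paths are capped at 0.95
(U is a caught fraction), biomass has a floor at $10^{-3} K$ whose breach
triggers path resampling and, after five failures, an "extinction under
scenario" error. The biomass update adds net production minus catch as a
single term so that the MSY fixed point is preserved exactly in floating
point — the end-to-end equilibrium tests rely on this.

## Problem sizes and determinism

The test suite runs entirely on synthetic panels of 3–200 stocks; the
analysis scripts and `scripts/acceptance.R` use the default 200-stock,
67-year condition, which completes in a few minutes on one core (the four
state-space fits dominate). All randomness flows through explicit seeds;
a fixed seed reproduces every CSV byte for byte (no timestamps are
written).

## Known limitations

* The half-max target inherits the observation window: late-assessed,
  already-depleted stocks understate their historical maximum.
* The ensemble members are not independent (five methods share the same
  data and two targets share everything but a per-stock rescaling), so the
  ± 1.96 SD band is a spread summary, not a confidence interval with
  frequentist coverage.
* The state-space model assumes a single shared trend; regional or
  taxonomic structure is out of scope.
* With heavy missingness the per-year reporting set changes composition
  over time, and all methods (not only the means) inherit that selection;
  the masking rule bounds but does not remove it.
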