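# fishstatus

Has global fishing recovered? Scientifically assessed fish stocks report
two annual status ratios: biomass relative to the level sustaining maximum
sustainable yield (B/B<sub>MSY</sub>) and exploitation rate relative to its
MSY counterpart (U/U<sub>MSY</sub>). Any statement about *global* stock
status requires averaging hundreds of heterogeneous series — stocks whose
sizes span orders of magnitude, whose assessments start in different
decades, and whose most recent years are often missing — and the answer
turns out to depend on how you average.

`fishstatus` makes that dependence explicit. Instead of one global
trajectory it computes an **ensemble of ten diagnostics** — five averaging
methods (unweighted mean, biomass-weighted mean, catch-weighted mean,
median, and a hierarchical state-space random-walk smoother) crossed with
two rebuilding-target definitions (the assessment's own B<sub>MSY</sub>,
and the precautionary target of half the historical maximum biomass) — and
summarises their agreement: ensemble mean, 95% spread interval, and a
support/refute count for the hypothesis that the global average is within
both targets (B/B<sub>MSY</sub> ≥ 1 and U/U<sub>MSY</sub> ≤ 1). Alongside
the ensemble it reports per-stock diagnostics: Kobe-quadrant status at the
most recent estimate, OLS trend slopes over each stock's last observed
decade, and the proportion of stocks within targets each year since 1950.

The state-space member models the panel of log ratios as a shared latent
random walk plus static stock offsets and observation noise,

    x_t = x_{t-1} + eta_t,   y_{s,t} = x_t + a_s + eps_{s,t},

fitted by exact maximum marginal likelihood (augmented-state Kalman filter
with block year updates) and smoothed with the Rauch–Tung–Striebel
recursion; see the methods vignette (`vignettes/ensemble-stock-status.Rmd`)
for the full model, parameter meanings, and numerical choices.

Inputs are RAM-Legacy-style long tables (`stock_id, series_id, year,
value` plus a reference-point table); a built-in Schaefer
surplus-production simulator generates statistically realistic panels with
known truth (B<sub>MSY</sub> = K/2, U<sub>MSY</sub> = r/2) so the entire
pipeline is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic panel (200 stocks, 1950–2016, fish-down-then-partial-rebuild
exploitation histories, 20% observation error, staggered starts, truncated
recent years):

```sh
Rscript analysis/01_simulate.R      # simulate + export RAM-style CSVs
Rscript analysis/02_ensemble.R      # 10-member ensemble + recovery verdicts
Rscript analysis/03_stock_status.R  # Kobe status, trends, proportions
Rscript analysis/04_report.R        # end-to-end run + plain-text report
```

`02_ensemble.R` prints, for seed 1:

```
<ensemble_result> 10 members per quantity, window 1980-2016
  b (2016): ensemble 0.909 [0.621, 1.197], 10 members
  u (2016): ensemble 0.886 [0.802, 0.970], 10 members

At 2016: 3 members support recovery, 7 refute, 0 undetermined
CIs straddle B=BMSY for 6 members, U=UMSY for 0 members
```

Read: at the last reporting year the ten diagnostics disagree — the
ensemble-average biomass sits just below target (0.909) with a member
spread straddling the B = B<sub>MSY</sub> line, while exploitation is
below target (0.886) for every member; only three of ten diagnostics would
call this world "recovered". `03_stock_status.R` adds the stock-level
view for the same panel:

```
'Up to' figures across targets: 65% below biomass target, 40% above exploitation target
Trends over the last observed decade: 11% of stocks declining in B/BMSY, 6% increasing in U/UMSY
Assessment targets: max 94% below biomass target in 1995; max 96% over exploitation target in 1988
Improvements since those maxima: 29 and 59 percentage points
```

The same functions run unchanged on a real RAM Legacy export: pass
`timeseries_path`/`refpoints_path` to `run_pipeline()` (or
`read_ram_long()` directly), with the series-id vocabulary editable in
`inst/extdata/ram_series_aliases.yaml` and total- vs spawning-biomass
series selectable via `series_preference`.

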