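#!/usr/bin/env Rscript
# Per-stock diagnostics: Kobe status at the most recent estimate, trend
# slopes over each stock's last observed decade, distributional summaries
# under both rebuilding targets, and the proportion-within-target series
# since 1950 with its historical extrema.

suppressPackageStartupMessages(library(fishstatus))

in_dir <- "results/data"
out_dir <- "results"

panel <- filter_panel(
  read_ram_long(file.path(in_dir, "timeseries.csv"),
                file.path(in_dir, "refpoints.csv")),
  min_years = 10, require_both_ratios = TRUE
)

sm <- status_summary(panel)
print(sm$per_target)
cat(sprintf("\n'Up to' figures across targets: %.0f%% below biomass target, %.0f%% above exploitation target\n",
            sm$maxima[["pct_below_b"]], sm$maxima[["pct_above_u"]]))
cat(sprintf("Trends over the last observed decade: %.0f%% of stocks declining in B/BMSY, %.0f%% increasing in U/UMSY\n",
            sm$maxima[["pct_b_down"]], sm$maxima[["pct_u_up"]]))

props <- lapply(c(assessment_bmsy = "assessment_bmsy",
                  half_max_biomass = "half_max_biomass"), function(tk) {
  proportion_series(suppressWarnings(make_ratios(panel, tk)),
                    start_year = 1950, min_stocks_per_year = 20)
})
ex <- props$assessment_bmsy$extrema
cat(sprintf("Assessment targets: max %.0f%% below biomass target in %d; max %.0f%% over exploitation target in %d\n",
            100 * ex$max_prop_below_b, ex$year_max_below_b,
            100 * ex$max_prop_over_u, ex$year_max_over_u))
cat(sprintf("Improvements since those maxima: %.0f and %.0f percentage points\n",
            100 * ex$improvement_b, 100 * ex$improvement_u))

readr::write_csv(dplyr::bind_rows(sm$status), file.path(out_dir, "stock_status.csv"))
readr::write_csv(sm$per_target, file.path(out_dir, "status_summary.csv"))
readr::write_csv(sm$histograms, file.path(out_dir, "histograms.csv"))
readr::write_csv(
  dplyr::bind_rows(lapply(names(props), function(tk) {
    tibble::tibble(props[[tk]]$series, target_kind = tk)
  })),
  file.path(out_dir, "proportions.csv"))
readr::write_csv(dplyr::bind_rows(lapply(props, `[[`, "extrema")),
                 file.path(out_dir, "extrema.csv"))
cat(sprintf("Tables written to %s\n", out_dir))
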