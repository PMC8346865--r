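#!/usr/bin/env Rscript
# Build the 10-member ensemble of global status trajectories (5 averaging
# methods x 2 rebuilding targets, for B/BMSY and U/UMSY), classify recovery
# at the last reporting year, and write the member and ensemble tables.
#
# Reads the long-format panel written by 01_simulate.R.

suppressPackageStartupMessages(library(fishstatus))

in_dir <- "results/data"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

panel <- read_ram_long(file.path(in_dir, "timeseries.csv"),
                       file.path(in_dir, "refpoints.csv"))
panel <- filter_panel(panel, min_years = 10, require_both_ratios = TRUE)
print(panel)

ens <- suppressWarnings(
  build_ensemble(panel, min_stocks_per_year = 20, window_start = 1980)
)
print(ens)

rec <- classify_recovery(ens)
cat(sprintf("\nAt %d: %d members support recovery, %d refute, %d undetermined\n",
            rec$year, rec$counts[["recovered"]], rec$counts[["not_recovered"]],
            rec$counts[["undetermined"]]))
cat(sprintf("CIs straddle B=BMSY for %d members, U=UMSY for %d members\n",
            sum(rec$members$straddle_b), sum(rec$members$straddle_u)))

readr::write_csv(ens$members, file.path(out_dir, "members.csv"))
readr::write_csv(ens$ensemble, file.path(out_dir, "ensemble.csv"))
readr::write_csv(rec$members, file.path(out_dir, "recovery_members.csv"))
cat(sprintf("Tables written to %s\n", out_dir))
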