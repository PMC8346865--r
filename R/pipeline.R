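#' Run the full status-assessment pipeline
#'
#' Orchestrates the analysis end to end: obtain a stock panel (simulated,
#' or read from RAM-style long tables), filter it, build the 10-member
#' ensemble of global trajectories, classify recovery at the last reporting
#' year, compute per-stock status and trends under both rebuilding targets,
#' and the proportion-within-target series. All outputs are written as tidy
#' UTF-8 CSVs plus a provenance JSON and a YAML echo of the configuration;
#' a run is reproducible bit for bit from the echoed config and inputs (no
#' timestamps are written).
#'
#' `config` is a named list with elements:
#' \describe{
#'   \item{simulate}{logical; simulate the panel (using `sim`) instead of
#'     reading files}
#'   \item{sim}{list of [sim_config()] arguments (when `simulate = TRUE`)}
#'   \item{timeseries_path, refpoints_path}{input CSVs (when
#'     `simulate = FALSE`)}
#'   \item{series_preference}{`"total_biomass"` (default) or
#'     `"spawning_biomass"`}
#'   \item{min_years, require_both_ratios}{[filter_panel()] settings
#'     (defaults 10, TRUE)}
#'   \item{min_stocks_per_year, window_start, last_year_frac}{
#'     [build_ensemble()] settings (defaults 20, 1980, 0.5)}
#'   \item{window_years, min_trend_years, bin_width}{trend/histogram
#'     settings (defaults 10, 8, 0.1)}
#'   \item{start_year_proportions}{first year of the proportion series
#'     (default 1950)}
#'   \item{seed}{seed for the simulator (overrides `sim$seed`)}
#' }
#'
#' @param config named list, see Details
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the in-memory artifacts (`panel`,
#'   `ensemble`, `recovery`, `summary`, `proportions`) and `paths` of all
#'   files written
#' @export
run_pipeline <- function(config, out_dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg <- utils::modifyList(list(
    simulate = FALSE, sim = list(), timeseries_path = NULL, refpoints_path = NULL,
    series_preference = "total_biomass",
    min_years = 10, require_both_ratios = TRUE,
    min_stocks_per_year = 20, window_start = 1980, last_year_frac = 0.5,
    window_years = 10, min_trend_years = 8, bin_width = 0.1,
    start_year_proportions = 1950, seed = NULL
  ), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  panel <- stage("input", {
    if (isTRUE(cfg$simulate)) {
      sim_args <- cfg$sim
      if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
      simulate_panel(do.call(sim_config, sim_args))
    } else if (!is.null(cfg$timeseries_path) && !is.null(cfg$refpoints_path)) {
      read_ram_long(cfg$timeseries_path, cfg$refpoints_path,
                    series_preference = cfg$series_preference)
    } else {
      stop("config must set simulate = TRUE or provide timeseries_path and refpoints_path")
    }
  })
  panel <- stage("filter", {
    filter_panel(panel, min_years = cfg$min_years,
                 require_both_ratios = cfg$require_both_ratios)
  })
  ensemble <- stage("ensemble", {
    build_ensemble(panel, min_stocks_per_year = cfg$min_stocks_per_year,
                   window_start = cfg$window_start,
                   last_year_frac = cfg$last_year_frac)
  })
  recovery <- stage("recovery", classify_recovery(ensemble))
  summary <- stage("status", {
    status_summary(panel, window_years = cfg$window_years,
                   min_trend_years = cfg$min_trend_years,
                   bin_width = cfg$bin_width)
  })
  proportions <- stage("proportions", {
    lapply(c(assessment_bmsy = "assessment_bmsy",
             half_max_biomass = "half_max_biomass"), function(tk) {
      proportion_series(suppressWarnings(make_ratios(panel, tk)),
                        start_year = cfg$start_year_proportions,
                        min_stocks_per_year = cfg$min_stocks_per_year)
    })
  })

  paths <- stage("write", {
    p <- list(
      members = file.path(out_dir, "members.csv"),
      ensemble = file.path(out_dir, "ensemble.csv"),
      recovery = file.path(out_dir, "recovery_members.csv"),
      status = file.path(out_dir, "stock_status.csv"),
      summary = file.path(out_dir, "status_summary.csv"),
      histograms = file.path(out_dir, "histograms.csv"),
      proportions = file.path(out_dir, "proportions.csv"),
      extrema = file.path(out_dir, "extrema.csv"),
      provenance = file.path(out_dir, "provenance.json"),
      config = file.path(out_dir, "run_config.yaml")
    )
    readr::write_csv(ensemble$members, p$members)
    readr::write_csv(ensemble$ensemble, p$ensemble)
    rec <- ensemble_recovery_table(recovery)
    readr::write_csv(rec, p$recovery)
    readr::write_csv(dplyr::bind_rows(summary$status), p$status)
    readr::write_csv(summary$per_target, p$summary)
    readr::write_csv(summary$histograms, p$histograms)
    prop_tab <- dplyr::bind_rows(lapply(names(proportions), function(tk) {
      tibble::tibble(proportions[[tk]]$series, target_kind = tk)
    }))
    readr::write_csv(prop_tab, p$proportions)
    readr::write_csv(dplyr::bind_rows(lapply(proportions, `[[`, "extrema")),
                     p$extrema)
    jsonlite::write_json(list(
      package = "fishstatus",
      version = as.character(utils::packageVersion("fishstatus")),
      seed = cfg$seed %||% cfg$sim$seed,
      source = panel$meta$source,
      filters = panel$meta$filters,
      n_stocks = n_stocks(panel),
      window = ensemble$window,
      ensemble_config = ensemble$config,
      maxima = as.list(summary$maxima)
    ), p$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], p$config)
    p
  })

  invisible(list(panel = panel, ensemble = ensemble, recovery = recovery,
                 summary = summary, proportions = proportions, paths = paths))
}

# recovery verdicts (members + ensemble) as one flat table
ensemble_recovery_table <- function(recovery) {
  members <- recovery$members
  ens <- tibble::tibble(
    method = "ensemble", target_kind = "ensemble",
    b = recovery$ensemble$b, b_se = NA_real_,
    u = recovery$ensemble$u, u_se = NA_real_,
    verdict = recovery$ensemble$verdict,
    straddle_b = recovery$ensemble$straddle_b,
    straddle_u = recovery$ensemble$straddle_u
  )
  out <- dplyr::bind_rows(members, ens)
  out$year <- recovery$year
  out
}

#' Assemble a human-readable run report
#'
#' Reads the CSV artifacts written by [run_pipeline()] (every reported
#' number is re-derivable from those files alone) and formats a plain-text
#' summary: the member endpoint table with recovery verdicts and the
#' support/refute count, confidence-interval straddle diagnostics, the
#' "up to" status maxima across target definitions, and the historical
#' extrema of the proportion series with the implied improvements.
#'
#' @param out_dir directory written by [run_pipeline()]
#' @param path optional path for the report text (default
#'   `out_dir/report.txt`)
#' @return the report, a character vector of lines (invisibly); also
#'   written to `path`
#' @export
make_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  need <- c("recovery_members.csv", "status_summary.csv", "extrema.csv",
            "ensemble.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing)) {
    stop(sprintf("missing run artifacts in %s: %s", out_dir,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rec <- readr::read_csv(file.path(out_dir, "recovery_members.csv"),
                         show_col_types = FALSE)
  sumtab <- readr::read_csv(file.path(out_dir, "status_summary.csv"),
                            show_col_types = FALSE)
  extrema <- readr::read_csv(file.path(out_dir, "extrema.csv"),
                             show_col_types = FALSE)

  mem <- rec[rec$method != "ensemble", , drop = FALSE]
  ens <- rec[rec$method == "ensemble", , drop = FALSE]
  counts <- table(factor(mem$verdict,
                         levels = c("recovered", "not_recovered", "undetermined")))
  lines <- c(
    sprintf("Global stock-status ensemble report (endpoint year %d)", rec$year[1]),
    "",
    sprintf("Members (%d): %d support recovery, %d refute, %d undetermined",
            nrow(mem), counts[["recovered"]], counts[["not_recovered"]],
            counts[["undetermined"]]),
    sprintf("CIs straddling the B=BMSY line: %d of %d members%s",
            sum(mem$straddle_b, na.rm = TRUE), nrow(mem),
            if (nrow(ens) && isTRUE(ens$straddle_b)) " (and the ensemble)" else ""),
    sprintf("CIs straddling the U=UMSY line: %d of %d members%s",
            sum(mem$straddle_u, na.rm = TRUE), nrow(mem),
            if (nrow(ens) && isTRUE(ens$straddle_u)) " (and the ensemble)" else ""),
    "",
    "Member endpoints (B/BMSY, U/UMSY):",
    sprintf("  %-18s %-18s b=%6s u=%6s  %s",
            mem$method, mem$target_kind,
            formatC(mem$b, digits = 3, format = "f"),
            formatC(mem$u, digits = 3, format = "f"), mem$verdict),
    "",
    "Across-target status maxima ('up to' figures):",
    sprintf("  below biomass target: %.1f%%; above exploitation target: %.1f%%",
            max(sumtab$pct_below_b), max(sumtab$pct_above_u)),
    sprintf("  trending down in B/BMSY: %.1f%%; trending up in U/UMSY: %.1f%%",
            max(sumtab$pct_b_down, na.rm = TRUE),
            max(sumtab$pct_u_up, na.rm = TRUE)),
    "",
    "Proportion-series extrema:"
  )
  for (i in seq_len(nrow(extrema))) {
    e <- extrema[i, ]
    lines <- c(lines,
      sprintf("  [%s] max below biomass target %.0f%% in %d (improvement %.0f pts); max over exploitation target %.0f%% in %d (improvement %.0f pts)",
              e$target_kind, 100 * e$max_prop_below_b, e$year_max_below_b,
              100 * e$improvement_b, 100 * e$max_prop_over_u,
              e$year_max_over_u, 100 * e$improvement_u))
  }
  writeLines(lines, path)
  invisible(lines)
}
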