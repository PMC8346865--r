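#' Configuration for the synthetic stock-panel generator
#'
#' Defines a panel of stocks governed by Schaefer (logistic) surplus
#' production, B_{t+1} = B_t + r B_t (1 - B_t/K) - C_t with C_t = U_t B_t,
#' so that the MSY reference points have closed forms B_MSY = K/2 and
#' U_MSY = r/2 and simulated panels carry exact truth for recovery tests.
#'
#' The defaults emulate the statistical structure of a global
#' assessed-stock compilation: a couple of hundred stocks whose carrying
#' capacities span orders of magnitude, assessments that begin in staggered
#' years, series that are truncated in recent years for a fraction of
#' stocks, lognormal observation error on reported biomass and exploitation
#' rate, and a fish-down-then-partial-rebuild exploitation history.
#'
#' @param n_stocks number of stocks (>= 1)
#' @param n_years number of simulated years (>= 2)
#' @param start_year first calendar year of the panel
#' @param carrying_capacity_log_mean,carrying_capacity_log_sd lognormal
#'   parameters for the carrying capacity K (biomass units)
#' @param growth_rate_range interval for the intrinsic growth rate r
#'   (per year); must lie within (0, 2)
#' @param exploitation_scenario shape of the exploitation-rate history:
#'   `"fish_down_then_rebuild"` ramps U linearly from 0.2 to 1.8 x U_MSY over
#'   the first 60% of years then declines to 0.9 x U_MSY; `"constant"` holds
#'   U at `constant_u_mult` x U_MSY; `"random_walk"` is a lognormal random
#'   walk around U_MSY
#' @param obs_sd lognormal observation-error SD (log scale) applied
#'   independently to reported biomass and exploitation rate; catch is
#'   reported without error
#' @param missing_recent_fraction fraction of stocks whose most recent
#'   observations are truncated
#' @param max_missing_years maximum number of truncated final years
#' @param start_stagger_max maximum delay (years, uniform on 0..max) of a
#'   stock's first observed year relative to `start_year`
#' @param u_path_sd lognormal SD of a per-stock multiplier applied to the
#'   scenario exploitation path (stock-to-stock trend heterogeneity)
#' @param initial_depletion initial biomass as a fraction of K
#' @param constant_u_mult exploitation level, as a multiple of U_MSY, used
#'   by the `"constant"` scenario
#' @param seed random seed recorded in the panel's provenance
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_stocks = 200,
                       n_years = 67,
                       start_year = 1950,
                       carrying_capacity_log_mean = log(1e5),
                       carrying_capacity_log_sd = 1.5,
                       growth_rate_range = c(0.1, 0.8),
                       exploitation_scenario = c("fish_down_then_rebuild",
                                                 "constant", "random_walk"),
                       obs_sd = 0.2,
                       missing_recent_fraction = 0.3,
                       max_missing_years = 5,
                       start_stagger_max = 25,
                       u_path_sd = 0.3,
                       initial_depletion = 1,
                       constant_u_mult = 1,
                       seed = 1L) {
  exploitation_scenario <- match.arg(exploitation_scenario)
  assert_scalar_number(n_stocks, "n_stocks", lower = 1)
  assert_scalar_number(n_years, "n_years", lower = 2)
  assert_scalar_number(obs_sd, "obs_sd", lower = 0)
  assert_scalar_number(missing_recent_fraction, "missing_recent_fraction", 0, 1)
  assert_scalar_number(max_missing_years, "max_missing_years", lower = 0)
  assert_scalar_number(start_stagger_max, "start_stagger_max", lower = 0)
  assert_scalar_number(u_path_sd, "u_path_sd", lower = 0)
  assert_scalar_number(initial_depletion, "initial_depletion", lower = 1e-6, upper = 1)
  assert_scalar_number(constant_u_mult, "constant_u_mult", lower = 0)
  if (length(growth_rate_range) != 2L || growth_rate_range[1] <= 0 ||
      growth_rate_range[2] >= 2 || diff(growth_rate_range) < 0) {
    stop("growth_rate_range must be an interval within (0, 2)", call. = FALSE)
  }
  structure(list(
    n_stocks = as.integer(n_stocks), n_years = as.integer(n_years),
    start_year = as.integer(start_year),
    carrying_capacity_log_mean = carrying_capacity_log_mean,
    carrying_capacity_log_sd = carrying_capacity_log_sd,
    growth_rate_range = growth_rate_range,
    exploitation_scenario = exploitation_scenario,
    obs_sd = obs_sd,
    missing_recent_fraction = missing_recent_fraction,
    max_missing_years = as.integer(max_missing_years),
    start_stagger_max = as.integer(start_stagger_max),
    u_path_sd = u_path_sd,
    initial_depletion = initial_depletion,
    constant_u_mult = constant_u_mult,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

# Target exploitation-rate path for one stock, as a multiple of U_MSY = r/2.
scenario_u_path <- function(config, u_msy) {
  n <- config$n_years
  path <- switch(config$exploitation_scenario,
    constant = rep(config$constant_u_mult, n),
    fish_down_then_rebuild = {
      n_up <- max(2L, ceiling(0.6 * n))
      up <- seq(0.2, 1.8, length.out = n_up)
      down <- seq(1.8, 0.9, length.out = n - n_up + 1L)[-1L]
      c(up, down)
    },
    random_walk = {
      steps <- c(rnorm(1, 0, 0.3), rnorm(n - 1L, 0, 0.1))
      exp(cumsum(steps))
    }
  )
  path * u_msy
}

# One stock's true trajectory under Schaefer dynamics. Returns NULL when the
# biomass floor (1e-3 K) is hit, signalling the caller to resample the path.
simulate_truth <- function(K, r, u_path, initial_depletion) {
  n <- length(u_path)
  u <- pmin(u_path, 0.95)  # U is a caught fraction; keep strictly below 1
  B <- numeric(n)
  C <- numeric(n)
  B[1] <- initial_depletion * K
  floor_B <- 1e-3 * K
  for (t in seq_len(n)) {
    C[t] <- u[t] * B[t]
    if (t < n) {
      # net surplus production minus catch, added as one term so the MSY
      # fixed point (where it is exactly zero) is preserved in floating point
      B[t + 1] <- B[t] + (r * B[t] * (1 - B[t] / K) - C[t])
      if (B[t + 1] <= floor_B) return(NULL)
    }
  }
  list(B = B, U = u, C = C)
}

#' Simulate a panel of assessed stocks with known truth
#'
#' Draws per-stock carrying capacities and growth rates, simulates Schaefer
#' surplus-production dynamics under the configured exploitation scenario,
#' applies independent lognormal observation error to biomass and
#' exploitation rate, staggers first observed years, truncates recent years
#' for a fraction of stocks, and returns a [stock_panel()] whose reference
#' points are the exact truths B_MSY = K/2 and U_MSY = r/2. The generating
#' truth (full, noise-free trajectories) is attached for recovery tests.
#'
#' Stocks whose dynamics hit the biomass floor (1e-3 K) have their
#' exploitation path resampled up to five times; if the floor is still hit
#' the simulation stops with an "extinction under scenario" error.
#'
#' @param config a [sim_config()]
#' @return a `stock_panel` with `truth` attached and the config echoed in
#'   `meta`
#' @export
#' @examples
#' p <- simulate_panel(sim_config(n_stocks = 5, n_years = 20, seed = 42))
#' n_stocks(p)
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    n <- config$n_stocks
    ids <- sprintf("sim%03d", seq_len(n))
    years <- config$start_year + seq_len(config$n_years) - 1L
    K <- rlnorm(n, config$carrying_capacity_log_mean, config$carrying_capacity_log_sd)
    r <- runif(n, config$growth_rate_range[1], config$growth_rate_range[2])
    retries <- integer(n)

    truth_series <- vector("list", n)
    obs_series <- vector("list", n)
    for (i in seq_len(n)) {
      u_msy <- r[i] / 2
      truth <- NULL
      for (attempt in 0:5) {
        mult <- if (config$u_path_sd > 0) exp(rnorm(1, 0, config$u_path_sd)) else 1
        u_path <- scenario_u_path(config, u_msy) * mult
        truth <- simulate_truth(K[i], r[i], u_path, config$initial_depletion)
        if (!is.null(truth)) break
        retries[i] <- retries[i] + 1L
      }
      if (is.null(truth)) {
        stop(sprintf("extinction under scenario for stock %s (r=%.3f): biomass floor hit after %d resamples",
                     ids[i], r[i], retries[i]), call. = FALSE)
      }
      truth_series[[i]] <- tibble::tibble(
        stock_id = ids[i], year = years,
        B_true = truth$B, U_true = truth$U, catch_true = truth$C
      )
      # observation window: staggered start, optionally truncated end
      first_idx <- 1L + if (config$start_stagger_max > 0) {
        sample.int(config$start_stagger_max + 1L, 1L) - 1L
      } else 0L
      first_idx <- min(first_idx, config$n_years - 1L)
      obs <- tibble::tibble(
        stock_id = ids[i], year = years,
        B = truth$B * exp(rnorm(config$n_years, 0, config$obs_sd)),
        U = truth$U * exp(rnorm(config$n_years, 0, config$obs_sd)),
        catch = truth$C
      )
      obs_series[[i]] <- obs[first_idx:config$n_years, , drop = FALSE]
    }

    # truncate recent years for a random subset of stocks
    n_miss <- round(config$missing_recent_fraction * n)
    if (n_miss > 0 && config$max_missing_years > 0) {
      miss_ids <- sample(ids, n_miss)
      for (i in match(miss_ids, ids)) {
        k <- sample.int(config$max_missing_years, 1L)
        keep <- seq_len(max(1L, nrow(obs_series[[i]]) - k))
        obs_series[[i]] <- obs_series[[i]][keep, , drop = FALSE]
      }
    }

    series <- dplyr::bind_rows(obs_series)
    refpoints <- tibble::tibble(stock_id = ids, B_MSY = K / 2, U_MSY = r / 2)
    truth <- list(
      stocks = tibble::tibble(stock_id = ids, K = K, r = r,
                              B_MSY_true = K / 2, U_MSY_true = r / 2),
      series = dplyr::bind_rows(truth_series)
    )
    stock_panel(series, refpoints, truth = truth,
                meta = list(source = "simulate_panel",
                            config = unclass(config),
                            seed = config$seed,
                            path_retries = sum(retries)))
  })
}

#' Export a panel as RAM-style long tables
#'
#' Writes the panel in the long CSV dialect consumed by [read_ram_long()]:
#' a time-series table with columns (stock_id, series_id, year, value) and a
#' reference-point table with columns (stock_id, parameter_id, value). Only
#' non-missing values are written, so a read-back round trip reproduces the
#' panel's observations exactly (up to CSV numeric precision).
#'
#' @param panel a `stock_panel`
#' @param timeseries_path,refpoints_path output CSV paths
#' @return invisibly, a list with the two paths
#' @export
export_ram_like <- function(panel, timeseries_path, refpoints_path) {
  stopifnot(inherits(panel, "stock_panel"))
  if (nrow(panel$series) == 0L) stop("cannot export an empty panel", call. = FALSE)
  roles <- c(B = "TB-MT", U = "ER-ratio", catch = "TC-MT",
             b_ratio = "TBdivTBmsy-dimensionless",
             u_ratio = "ERdivERmsy-dimensionless")
  long <- tidyr::pivot_longer(panel$series, cols = names(roles),
                              names_to = "role", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  ts <- tibble::tibble(stock_id = long$stock_id,
                       series_id = unname(roles[long$role]),
                       year = long$year, value = long$value)
  ts <- ts[order(ts$stock_id, ts$series_id, ts$year), ]
  rp_long <- tidyr::pivot_longer(panel$refpoints, cols = c("B_MSY", "U_MSY"),
                                 names_to = "param", values_to = "value")
  rp_long <- rp_long[!is.na(rp_long$value), , drop = FALSE]
  rp <- tibble::tibble(stock_id = rp_long$stock_id,
                       parameter_id = ifelse(rp_long$param == "B_MSY",
                                             "TBmsy-MT", "ERmsy-ratio"),
                       value = rp_long$value)
  readr::write_csv(ts, timeseries_path)
  readr::write_csv(rp, refpoints_path)
  invisible(list(timeseries = timeseries_path, refpoints = refpoints_path))
}
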