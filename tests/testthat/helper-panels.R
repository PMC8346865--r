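# Fixture builders shared across test files. All panels are generated in
# code; nothing is read from disk.

# Noise-free panel held exactly at the MSY fixed point: B0 = K/2 and
# U = U_MSY so that B/BMSY and U/UMSY are exactly 1 in every year.
msy_fixed_point_config <- function(n_stocks = 10, n_years = 15, seed = 11,
                                   start_year = 1990) {
  sim_config(
    n_stocks = n_stocks, n_years = n_years, start_year = start_year,
    exploitation_scenario = "constant", constant_u_mult = 1,
    initial_depletion = 0.5, obs_sd = 0, u_path_sd = 0,
    missing_recent_fraction = 0, start_stagger_max = 0, seed = seed
  )
}

# Schaefer panel resting exactly at the MSY equilibrium under BOTH target
# definitions: each stock spends one transient year (before `from_year`) at
# its unfished biomass K -- establishing a historical maximum of K, so the
# half-max target max(B)/2 equals B_MSY = K/2 -- and is then fished down in
# one step (U = 1/2) to K/2, where U = U_MSY holds it exactly. From
# `from_year` onward every ratio is exactly 1 under both targets.
msy_equilibrium_panel <- function(n_stocks = 25, from_year = 1950,
                                  last_year = 2016, seed = 19) {
  set.seed(seed)
  K <- rlnorm(n_stocks, log(1e5), 1)
  r <- runif(n_stocks, 0.2, 0.8)
  ids <- sprintf("eq%03d", seq_len(n_stocks))
  years <- (from_year - 1):last_year
  series <- do.call(rbind, lapply(seq_len(n_stocks), function(i) {
    B <- c(K[i], rep(K[i] / 2, length(years) - 1))
    U <- c(0.5, rep(r[i] / 2, length(years) - 1))
    data.frame(stock_id = ids[i], year = years, B = B, U = U, catch = U * B)
  }))
  stock_panel(series,
              data.frame(stock_id = ids, B_MSY = K / 2, U_MSY = r / 2))
}

# Hand-built panel: explicit series values, no simulator involved.
manual_panel <- function(series, refpoints) {
  stock_panel(series, refpoints)
}

# A small panel where every stock shares a common trajectory plus noise.
common_trajectory_panel <- function(n_stocks = 30, years = 1991:2010,
                                    traj = NULL, noise_sd = 0.1, seed = 5) {
  if (is.null(traj)) traj <- 0.6 + 0.03 * seq_along(years)
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    series <- do.call(rbind, lapply(seq_len(n_stocks), function(i) {
      data.frame(
        stock_id = sprintf("s%02d", i), year = years,
        B = traj * exp(rnorm(length(years), 0, noise_sd)) * 100,
        U = 0.5 * traj * exp(rnorm(length(years), 0, noise_sd)) * 0.2,
        catch = 10
      )
    }))
    refpoints <- data.frame(stock_id = sprintf("s%02d", seq_len(n_stocks)),
                            B_MSY = 100, U_MSY = 0.2)
    stock_panel(series, refpoints)
  })
}

# Long-format export of a panel to temp files; returns the two paths.
export_to_tmp <- function(panel) {
  ts <- tempfile(fileext = ".csv")
  rp <- tempfile(fileext = ".csv")
  export_ram_like(panel, ts, rp)
  list(ts = ts, rp = rp)
}

# Independent brute-force marginal likelihood of the hierarchical
# state-space model from the implied joint covariance (calendar-year gaps
# in the random walk; offsets share covariance within a stock; initial
# state centred on the grand mean of the log observations, matching the
# model definition).
brute_force_ss_loglik <- function(d, sigma_proc, sigma_stock, sigma_obs, x0_var) {
  t <- d$year - min(d$year) + 1
  s <- match(d$stock_id, sort(unique(d$stock_id)))
  n <- nrow(d)
  Cov <- outer(t, t, function(i, j) x0_var + sigma_proc^2 * (pmin(i, j) - 1)) +
    sigma_stock^2 * outer(s, s, "==") + sigma_obs^2 * diag(n)
  y <- log(d$value)
  y <- y - mean(y)
  ch <- chol(Cov)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}
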