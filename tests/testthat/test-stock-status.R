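test_that("Kobe quadrants follow the inclusive boundary rule", {
  expect_equal(as.character(kobe_classify(1.2, 0.8)), "green")
  expect_equal(as.character(kobe_classify(0.5, 1.5)), "red")
  expect_equal(as.character(kobe_classify(1.0, 1.0)), "green")
  expect_equal(as.character(kobe_classify(0.5, 0.5)), "yellow_b")
  expect_equal(as.character(kobe_classify(1.5, 1.5)), "yellow_u")
  expect_true(is.na(kobe_classify(NA, 1)))
  expect_error(kobe_classify(-0.1, 1), "non-negative")
  expect_error(kobe_classify(1, c(1, 2)), "align")
})

test_that("quadrant fractions partition the classified stocks", {
  set.seed(61)
  b <- rlnorm(500, 0, 0.5); u <- rlnorm(500, 0, 0.5)
  q <- kobe_classify(b, u)
  expect_equal(sum(table(q)), 500)
  expect_false(anyNA(q))
})

test_that("trend slopes match exact lines and brute-force normal equations", {
  expect_equal(trend_slope(2001:2010, 1 + 0.1 * (0:9))$slope, 0.1)
  expect_equal(trend_slope(2001:2010, rep(1.4, 10))$slope, 0)
  set.seed(77)
  for (i in 1:5) {
    y <- rlnorm(10, 0, 0.3)
    yrs <- 2001:2010
    # normal equations, computed independently
    xbar <- mean(yrs); ybar <- mean(y)
    beta <- sum((yrs - xbar) * (y - ybar)) / sum((yrs - xbar)^2)
    expect_equal(trend_slope(yrs, y)$slope, beta)
  }
  # slope equivariance: scale multiplies, shift leaves unchanged
  y <- rlnorm(10, 0, 0.3)
  s0 <- trend_slope(2001:2010, y)$slope
  expect_equal(trend_slope(2001:2010, 5 * y)$slope, 5 * s0)
  expect_equal(trend_slope(2001:2010, y + 3)$slope, s0)
})

test_that("trend window uses the most recent observed years, not calendar years", {
  # 14 observed years with a recent gap: window is the last 10 observed
  yrs <- c(1995:2004, 2008:2011)
  vals <- c(rep(1, 10), 2, 3, 4, 5)
  res <- trend_slope(yrs, vals, window_years = 10, min_years = 8)
  expect_equal(res$n, 10)
  # last 10 observed years are 1999:2004 + 2008:2011
  keep <- tail(seq_along(yrs), 10)
  beta <- coef(lm(vals[keep] ~ yrs[keep]))[[2]]
  expect_equal(res$slope, beta)
  # insufficient data
  expect_true(is.na(trend_slope(2001:2005, rnorm(5), min_years = 8)$slope))
})

test_that("status summary counts match direct enumeration", {
  years <- 2001:2012
  set.seed(83)
  series <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(stock_id = sprintf("s%02d", i), year = years,
               B = 100 * rlnorm(12, 0, 0.4), U = 0.2 * rlnorm(12, 0, 0.4),
               catch = 3)
  }))
  panel <- manual_panel(series, data.frame(stock_id = sprintf("s%02d", 1:12),
                                           B_MSY = 100, U_MSY = 0.2))
  sm <- status_summary(panel)
  st <- sm$status$assessment_bmsy
  # direct enumeration over stocks
  r <- make_ratios(panel, "assessment_bmsy")$ratios
  expect_n_below <- 0
  for (s in unique(r$stock_id)) {
    df <- r[r$stock_id == s, ]
    if (df$b[which.max(df$year)] < 1) expect_n_below <- expect_n_below + 1
  }
  row_a <- sm$per_target[sm$per_target$target_kind == "assessment_bmsy", ]
  expect_equal(row_a$pct_below_b, 100 * expect_n_below / 12)
  expect_equal(row_a$pct_b_down, 100 * mean(st$b_slope < 0))
  # across-target maxima are maxima of the per-target values
  expect_equal(unname(sm$maxima["pct_below_b"]), max(sm$per_target$pct_below_b))
  # histogram counts sum to the classified stocks
  hb <- sm$histograms[sm$histograms$target_kind == "assessment_bmsy" &
                        sm$histograms$quantity == "b", ]
  expect_equal(sum(hb$count), 12)
})

test_that("four-stock example: half below biomass target", {
  series <- do.call(rbind, lapply(seq_along(c(0.5, 0.9, 1.1, 2.0)), function(i) {
    data.frame(stock_id = paste0("s", i), year = 2001:2010,
               B = 100 * c(0.5, 0.9, 1.1, 2.0)[i], U = 0.1, catch = 1)
  }))
  panel <- manual_panel(series, data.frame(stock_id = paste0("s", 1:4),
                                           B_MSY = 100, U_MSY = 0.2))
  sm <- status_summary(panel)
  row_a <- sm$per_target[sm$per_target$target_kind == "assessment_bmsy", ]
  expect_equal(row_a$pct_below_b, 50)
  expect_equal(row_a$pct_above_u, 0)
})

test_that("proportion series and extrema arithmetic", {
  # all stocks healthy: below-target proportion identically zero
  healthy <- manual_panel(
    do.call(rbind, lapply(1:5, function(i) {
      data.frame(stock_id = paste0("s", i), year = 1990:2000, B = 150,
                 U = 0.1, catch = 1)
    })),
    data.frame(stock_id = paste0("s", 1:5), B_MSY = 100, U_MSY = 0.2)
  )
  pr <- proportion_series(make_ratios(healthy, "assessment_bmsy"),
                          start_year = 1950, min_stocks_per_year = 5)
  expect_equal(pr$series$prop_within_b, rep(1, nrow(pr$series)))
  expect_equal(pr$extrema$max_prop_below_b, 0)

  # engineered extrema: 57% below in 2007, 48% below at the end -> improvement 9 pts
  n <- 100
  years <- 2000:2010
  below_by_year <- setNames(rep(30, length(years)), years)
  below_by_year["2007"] <- 57
  below_by_year["2010"] <- 48
  series <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(stock_id = sprintf("s%03d", i), year = years,
               B = ifelse(i <= below_by_year[as.character(years)], 50, 150),
               U = 0.1, catch = 1)
  }))
  panel <- manual_panel(series, data.frame(stock_id = sprintf("s%03d", 1:n),
                                           B_MSY = 100, U_MSY = 0.2))
  pr2 <- proportion_series(make_ratios(panel, "assessment_bmsy"),
                           start_year = 1950, min_stocks_per_year = 20)
  expect_equal(pr2$extrema$max_prop_below_b, 0.57)
  expect_equal(pr2$extrema$year_max_below_b, 2007)
  expect_equal(pr2$extrema$final_prop_below_b, 0.48)
  expect_equal(pr2$extrema$improvement_b, 0.09)

  # tie in the argmax year: earliest reported, with a message
  below_by_year["2003"] <- 57
  series2 <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(stock_id = sprintf("s%03d", i), year = years,
               B = ifelse(i <= below_by_year[as.character(years)], 50, 150),
               U = 0.1, catch = 1)
  }))
  panel2 <- manual_panel(series2, data.frame(stock_id = sprintf("s%03d", 1:n),
                                             B_MSY = 100, U_MSY = 0.2))
  expect_message(
    pr3 <- proportion_series(make_ratios(panel2, "assessment_bmsy"),
                             min_stocks_per_year = 20),
    "tie")
  expect_equal(pr3$extrema$year_max_below_b, 2003)

  # too few stocks everywhere
  tiny <- manual_panel(
    data.frame(stock_id = "a", year = 2001:2005, B = 50, U = 0.1, catch = 1),
    data.frame(stock_id = "a", B_MSY = 100, U_MSY = 0.2))
  expect_error(proportion_series(make_ratios(tiny, "assessment_bmsy"),
                                 min_stocks_per_year = 20),
               "min_stocks_per_year")
})

test_that("summary percentages agree with the proportion series on a complete panel", {
  p <- simulate_panel(sim_config(n_stocks = 30, n_years = 25, seed = 47,
                                 missing_recent_fraction = 0,
                                 start_stagger_max = 0))
  sm <- status_summary(p)
  ra <- make_ratios(p, "assessment_bmsy")
  pr <- proportion_series(ra, start_year = 1950, min_stocks_per_year = 10)
  final_year <- max(pr$series$year[!is.na(pr$series$prop_within_b)])
  row_a <- sm$per_target[sm$per_target$target_kind == "assessment_bmsy", ]
  expect_equal(row_a$pct_below_b / 100,
               1 - pr$series$prop_within_b[pr$series$year == final_year])
})

test_that("a stricter (higher) biomass target never lowers the share below target", {
  p <- simulate_panel(sim_config(n_stocks = 25, n_years = 20, seed = 53,
                                 missing_recent_fraction = 0))
  sm <- status_summary(p)
  # per-stock: whenever the half-max target exceeds assessment B_MSY the
  # stock's b can only fall, so flipping below-target status one way only
  sa <- sm$status$assessment_bmsy
  sh <- sm$status$half_max_biomass
  m <- merge(sa[, c("stock_id", "b_last")], sh[, c("stock_id", "b_last")],
             by = "stock_id", suffixes = c("_a", "_h"))
  ref <- merge(m, p$refpoints, by = "stock_id")
  bmax_half <- vapply(split(p$series, p$series$stock_id),
                      function(df) max(df$B, na.rm = TRUE) / 2, numeric(1))
  ref$stricter <- bmax_half[ref$stock_id] >= ref$B_MSY
  strict <- ref[ref$stricter, ]
  expect_true(all(strict$b_last_h <= strict$b_last_a + 1e-12))
})
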