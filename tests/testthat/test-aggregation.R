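test_that("aggregate_year matches hand-worked examples", {
  expect_equal(aggregate_year(c(1, 3))$estimate, 2)
  a <- aggregate_year(c(1, 3), weights = c(1, 0))
  expect_equal(a$estimate, 1)
  expect_equal(a$se, 0)
  expect_error(aggregate_year(c(1, 2), weights = c(-1, 1)), "negative")
  expect_error(aggregate_year(c(1, 2), weights = c(0, 0)), "zero")
  expect_equal(aggregate_year(c(NA, NA))$n, 0)
})

test_that("weighted mean/SE and median SE match independent loop arithmetic", {
  set.seed(71)
  for (rep in 1:5) {
    x <- rlnorm(7); w <- runif(7, 0.1, 3)
    # brute-force loops, written from the formulas directly
    sw <- 0; swx <- 0
    for (i in 1:7) { sw <- sw + w[i]; swx <- swx + w[i] * x[i] }
    m <- swx / sw
    s2 <- 0
    for (i in 1:7) s2 <- s2 + w[i]^2 * (x[i] - m)^2
    a <- aggregate_year(x, w)
    expect_equal(a$estimate, m)
    expect_equal(a$se, sqrt(s2) / sw)

    md <- aggregate_year(x, method = "median")
    xs <- sort(x)
    expect_equal(md$estimate, (xs[4]))
    sm <- 0
    for (i in 1:7) sm <- sm + (x[i] - mean(x))^2
    expect_equal(md$se, 1.2533 * sqrt(sm) / 7)
  }
})

test_that("run_method reproduces simple weighted examples", {
  years <- 2001:2010
  series <- rbind(
    data.frame(stock_id = "lo", year = years, B = 100 * 1, U = 0.2 * 1, catch = 1),
    data.frame(stock_id = "hi", year = years, B = 100 * 3, U = 0.2 * 3, catch = 3)
  )
  panel <- manual_panel(series, data.frame(stock_id = c("lo", "hi"),
                                           B_MSY = 100, U_MSY = 0.2))
  r <- make_ratios(panel, "assessment_bmsy")
  un <- run_method(r, "b", "unweighted_mean", min_stocks_per_year = 2)
  cw <- run_method(r, "b", "catch_weighted", min_stocks_per_year = 2)
  expect_equal(un$estimate, rep(2.0, 10))
  expect_equal(cw$estimate, rep(2.5, 10))
  # biomass weights are mean B: (1*100 + 3*300)/400 = 2.5 as well
  bw <- run_method(r, "b", "biomass_weighted", min_stocks_per_year = 2)
  expect_equal(bw$estimate, rep(2.5, 10))
})

test_that("a panel with all ratios at 1 yields flat trajectories with zero SE", {
  p <- simulate_panel(msy_fixed_point_config(n_stocks = 8, n_years = 12))
  r <- make_ratios(p, "assessment_bmsy")
  for (m in c("unweighted_mean", "biomass_weighted", "catch_weighted", "median")) {
    tr <- run_method(r, "b", m, min_stocks_per_year = 2)
    expect_equal(tr$estimate, rep(1, nrow(tr)), tolerance = 1e-12)
    expect_equal(tr$se, rep(0, nrow(tr)), tolerance = 1e-12)
  }
})

test_that("equal weights collapse the weighted methods onto the unweighted mean", {
  years <- 2001:2012
  set.seed(8)
  series <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(stock_id = paste0("s", i), year = years,
               B = 100 * rlnorm(length(years), 0, 0.3),
               U = 0.2 * rlnorm(length(years), 0, 0.3), catch = 5)
  }))
  panel <- manual_panel(series, data.frame(stock_id = paste0("s", 1:6),
                                           B_MSY = 100, U_MSY = 0.2))
  r <- make_ratios(panel, "assessment_bmsy")
  r$weights$w_biomass <- 3.7   # force exactly equal weights
  r$weights$w_catch <- 0.4
  un <- run_method(r, "b", "unweighted_mean", min_stocks_per_year = 2)
  bw <- run_method(r, "b", "biomass_weighted", min_stocks_per_year = 2)
  cw <- run_method(r, "b", "catch_weighted", min_stocks_per_year = 2)
  expect_equal(bw$estimate, un$estimate)
  expect_equal(cw$estimate, un$estimate)
  expect_equal(bw$se, un$se)
})

test_that("stock order never changes a trajectory", {
  p <- simulate_panel(sim_config(n_stocks = 12, n_years = 20, seed = 13))
  r <- make_ratios(p, "assessment_bmsy")
  r2 <- r
  set.seed(1)
  perm <- sample(nrow(r2$ratios))
  r2$ratios <- r2$ratios[perm, ]
  r2$weights <- r2$weights[sample(nrow(r2$weights)), ]
  for (m in c("unweighted_mean", "catch_weighted", "median")) {
    expect_equal(run_method(r2, "b", m, min_stocks_per_year = 2),
                 run_method(r, "b", m, min_stocks_per_year = 2))
  }
})

test_that("the median trajectory resists a 100x outlier stock better than the mean", {
  p <- simulate_panel(sim_config(n_stocks = 15, n_years = 20, seed = 19,
                                 missing_recent_fraction = 0))
  r <- make_ratios(p, "assessment_bmsy")
  r_out <- r
  first <- r_out$ratios$stock_id == r_out$ratios$stock_id[1]
  r_out$ratios$b[first] <- r_out$ratios$b[first] * 100
  shift <- function(m) {
    a <- run_method(r, "b", m, min_stocks_per_year = 2)$estimate
    b <- run_method(r_out, "b", m, min_stocks_per_year = 2)$estimate
    mean(abs(b - a), na.rm = TRUE)
  }
  expect_lt(shift("median"), shift("unweighted_mean"))
})

test_that("all five methods recover a common trajectory within 3 SE", {
  years <- 1991:2010
  traj <- 0.6 + 0.03 * seq_along(years)
  panel <- common_trajectory_panel(n_stocks = 40, years = years, traj = traj,
                                   noise_sd = 0.08, seed = 5)
  r <- make_ratios(panel, "assessment_bmsy")
  for (m in c("unweighted_mean", "biomass_weighted", "catch_weighted",
              "median", "state_space")) {
    tr <- run_method(r, "b", m, min_stocks_per_year = 5)
    ok <- !is.na(tr$estimate)
    # lognormal noise inflates the arithmetic mean by ~exp(sd^2/2) (< 0.4%)
    z <- abs(tr$estimate[ok] - traj[ok]) / pmax(tr$se[ok], 1e-9)
    expect_lt(max(head(z[-1], -1)), 3.5)
  }
})

test_that("years with too few stocks are masked in every member", {
  p <- simulate_panel(sim_config(n_stocks = 30, n_years = 30, start_year = 1987,
                                 start_stagger_max = 20, seed = 23))
  r <- make_ratios(p, "assessment_bmsy")
  counts <- table(r$ratios$year[!is.na(r$ratios$b)])
  thin_year <- as.integer(names(counts)[counts < 25][1])
  expect_false(is.na(thin_year))  # staggered starts guarantee a thin early year
  for (m in c("unweighted_mean", "median")) {
    tr <- run_method(r, "b", m, min_stocks_per_year = 25)
    expect_true(is.na(tr$estimate[tr$year == thin_year]))
  }
})

test_that("missing catch weights error with the affected stocks named", {
  series <- rbind(
    data.frame(stock_id = "a", year = 2001:2005, B = 100, U = 0.1, catch = 2),
    data.frame(stock_id = "nocatch", year = 2001:2005, B = 100, U = 0.1,
               catch = NA_real_)
  )
  panel <- manual_panel(series, data.frame(stock_id = c("a", "nocatch"),
                                           B_MSY = 100, U_MSY = 0.2))
  r <- make_ratios(panel, "assessment_bmsy")
  expect_error(run_method(r, "b", "catch_weighted", min_stocks_per_year = 2),
               "nocatch")
})

test_that("build_ensemble produces 10 members per quantity that bracket the mean", {
  p <- simulate_panel(sim_config(n_stocks = 40, n_years = 40, start_year = 1977,
                                 seed = 7, start_stagger_max = 10))
  ens <- build_ensemble(filter_panel(p, 10, TRUE), min_stocks_per_year = 10,
                        window_start = 1985)
  for (q in c("b", "u")) {
    mem <- ens$members[ens$members$quantity == q, ]
    expect_equal(length(unique(paste(mem$method, mem$target_kind))), 10)
    joined <- merge(
      aggregate(estimate ~ year, mem, function(x) c(mn = min(x), mx = max(x))),
      ens$ensemble[ens$ensemble$quantity == q, ], by = "year")
    expect_true(all(joined$estimate[, "mn"] <= joined$mean + 1e-12))
    expect_true(all(joined$estimate[, "mx"] >= joined$mean - 1e-12))
    expect_true(all(is.na(joined$lo) | (joined$lo <= joined$mean &
                                          joined$mean <= joined$hi)))
  }
})

test_that("identical members give a zero-width ensemble interval", {
  members <- expand.grid(method = c("m1", "m2"), target_kind = c("t1", "t2"),
                         quantity = "b", year = 2001:2003,
                         stringsAsFactors = FALSE)
  members$estimate <- 1.3
  members$se <- 0.1
  members$n_stocks <- 50L
  fake <- structure(list(members = tibble::as_tibble(members),
                         window = c(2001, 2003)), class = "ensemble_result")
  ens <- dplyr::summarise(dplyr::group_by(fake$members, quantity, year),
                          mean = mean(estimate), sd = sd(estimate),
                          .groups = "drop")
  expect_equal(ens$mean, rep(1.3, 3))
  expect_equal(ens$sd, rep(0, 3))
})

test_that("recovery classification follows the target-line rules", {
  members <- expand.grid(method = c("m1", "m2", "m3", "m4", "m5"),
                         target_kind = c("t1", "t2"), quantity = c("b", "u"),
                         year = 2016, stringsAsFactors = FALSE)
  members$estimate <- ifelse(members$quantity == "b", 1.2, 0.8)
  members$se <- 0.1
  # one member below target in b, one overfishing in u, one undetermined
  members$estimate[members$method == "m2" & members$target_kind == "t1" &
                     members$quantity == "b"] <- 0.99
  members$estimate[members$method == "m3" & members$target_kind == "t2" &
                     members$quantity == "u"] <- 1.4
  members$estimate[members$method == "m4" & members$target_kind == "t1" &
                     members$quantity == "b"] <- NA
  members$n_stocks <- 100L
  ens_tab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(members[!is.na(members$estimate), ]),
                    quantity, year),
    mean = mean(estimate), sd = sd(estimate), n_members = dplyr::n(),
    .groups = "drop")
  ens_tab$lo <- ens_tab$mean - 1.96 * ens_tab$sd
  ens_tab$hi <- ens_tab$mean + 1.96 * ens_tab$sd
  fake <- structure(list(members = tibble::as_tibble(members),
                         ensemble = ens_tab, window = c(1980, 2016)),
                    class = "ensemble_result")
  rec <- classify_recovery(fake, 2016)
  expect_equal(sum(rec$counts), 10)
  expect_equal(unname(rec$counts["undetermined"]), 1)
  expect_equal(unname(rec$counts["not_recovered"]), 2)  # strict b > 1 fails at 0.99
  expect_equal(unname(rec$counts["recovered"]), 7)
  # straddle rule: 1 in estimate +/- 1.96 SE
  m2 <- rec$members[rec$members$method == "m2" & rec$members$target_kind == "t1", ]
  expect_true(m2$straddle_b)   # 0.99 +/- 0.196 straddles 1
  m1 <- rec$members[rec$members$method == "m1" & rec$members$target_kind == "t1", ]
  expect_false(m1$straddle_b)  # 1.2 +/- 0.196 does not
  expect_error(classify_recovery(fake, 1950), "window")
})
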