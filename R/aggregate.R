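#' Aggregate one year of status ratios
#'
#' Weighted mean with weighted standard error, or sample median with a
#' normal-theory standard error. The weighted mean is
#' `sum(w * x) / sum(w)` with SE `sqrt(sum(w^2 * (x - xbar)^2)) / sum(w)`
#' (which reduces to the usual `sd * sqrt((n-1)/n) / sqrt(n)` under equal
#' weights). The median is weight-agnostic, with SE
#' `1.2533 * SE_mean` (the asymptotic efficiency factor of the median under
#' normality); a bootstrap SE is available behind `se_method = "bootstrap"`.
#'
#' @param values numeric ratio values (NAs dropped pairwise with weights)
#' @param weights non-negative weights aligned with `values`; `NULL` for
#'   equal weights
#' @param method `"mean"` or `"median"`
#' @param se_method for the median: `"normal"` (default) or `"bootstrap"`
#' @param boot_n bootstrap replicates when `se_method = "bootstrap"`
#' @return list with `estimate`, `se`, `n`
#' @export
#' @examples
#' aggregate_year(c(1, 3))                       # mean 2
#' aggregate_year(c(1, 3), weights = c(1, 0))    # mean 1, SE 0
aggregate_year <- function(values, weights = NULL, method = c("mean", "median"),
                           se_method = c("normal", "bootstrap"), boot_n = 500L) {
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) {
    stop("`weights` must align with `values`", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(weights)
  x <- values[keep]; w <- weights[keep]
  if (length(x) == 0L) return(list(estimate = NA_real_, se = NA_real_, n = 0L))
  if (any(w < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (sum(w) == 0) stop("weights sum to zero", call. = FALSE)
  n <- length(x)
  if (method == "mean") {
    est <- sum(w * x) / sum(w)
    se <- sqrt(sum(w^2 * (x - est)^2)) / sum(w)
  } else {
    est <- median(x)
    if (se_method == "normal") {
      xbar <- mean(x)
      se <- 1.2533 * sqrt(sum((x - xbar)^2)) / n
    } else {
      reps <- vapply(seq_len(boot_n),
                     function(i) median(x[sample.int(n, n, replace = TRUE)]),
                     numeric(1))
      se <- sd(reps)
    }
  }
  list(estimate = est, se = se, n = n)
}

agg_methods <- function() {
  c("unweighted_mean", "biomass_weighted", "catch_weighted", "median",
    "state_space")
}

#' Run one averaging method over a ratio panel
#'
#' Produces the yearly global trajectory of one quantity (`b` = B/BMSY or
#' `u` = U/UMSY) under one averaging method. Weights are time-invariant
#' per-stock summaries: the stock's mean observed biomass
#' (`biomass_weighted`), mean catch (`catch_weighted`), or 1 (unweighted
#' mean and median). The `state_space` method fits the hierarchical
#' random-walk smoother ([fit_ss()]) to the log ratios and returns its
#' back-transformed trajectory with model-based SEs. An optional
#' `geometric_mean` method (mean on the log scale, back-transformed) is
#' available but not part of the standard ensemble.
#'
#' Years in which fewer than `min_stocks_per_year` stocks report are masked
#' (estimate and SE set to `NA`).
#'
#' @param ratios a `ratio_panel` from [make_ratios()]
#' @param quantity `"b"` or `"u"`
#' @param method one of `"unweighted_mean"`, `"biomass_weighted"`,
#'   `"catch_weighted"`, `"median"`, `"state_space"`, `"geometric_mean"`
#' @param window integer length-2 year range (default: the panel's range)
#' @param min_stocks_per_year mask years with fewer reporting stocks
#' @param ss_control list passed to [fit_ss()] (`x0_var`, `control`, ...)
#' @return tibble `year`, `estimate`, `se`, `n_stocks`, `method`,
#'   `quantity`, `target_kind`
#' @export
run_method <- function(ratios, quantity = c("b", "u"),
                       method = c("unweighted_mean", "biomass_weighted",
                                  "catch_weighted", "median", "state_space",
                                  "geometric_mean"),
                       window = NULL, min_stocks_per_year = 20,
                       ss_control = list()) {
  stopifnot(inherits(ratios, "ratio_panel"))
  quantity <- match.arg(quantity)
  method <- match.arg(method)
  df <- ratios$ratios[, c("stock_id", "year")]
  df$value <- ratios$ratios[[quantity]]
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0L) stop(sprintf("no `%s` data in ratio panel", quantity), call. = FALSE)
  if (is.null(window)) window <- range(df$year)
  years <- seq(window[1], window[2])
  df <- df[df$year >= window[1] & df$year <= window[2], , drop = FALSE]
  counts <- table(factor(df$year, levels = years))
  n_year <- as.integer(counts)

  if (method == "state_space") {
    fit <- do.call(fit_ss, c(list(data = df, window = window), ss_control))
    traj <- ss_smoother_trajectory(fit)
    est <- traj$estimate; se <- traj$se
  } else if (method == "geometric_mean") {
    agg <- per_year_aggregate(df, years, weights = NULL, method = "mean",
                              transform = log)
    est <- exp(agg$est); se <- exp(agg$est) * agg$se  # delta method
  } else {
    w_col <- switch(method,
                    unweighted_mean = NULL, median = NULL,
                    biomass_weighted = "w_biomass", catch_weighted = "w_catch")
    weights <- NULL
    if (!is.null(w_col)) {
      wtab <- ratios$weights
      w <- wtab[[w_col]][match(df$stock_id, wtab$stock_id)]
      if (anyNA(w)) {
        bad <- sort(unique(df$stock_id[is.na(w)]))
        stop(sprintf("%s weights unavailable for stock(s): %s", method,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      weights <- w
    }
    agg <- per_year_aggregate(df, years, weights = weights,
                              method = if (method == "median") "median" else "mean")
    est <- agg$est; se <- agg$se
  }

  mask <- n_year < min_stocks_per_year
  est[mask] <- NA_real_; se[mask] <- NA_real_
  tibble::tibble(year = years, estimate = est, se = se, n_stocks = n_year,
                 method = method, quantity = quantity,
                 target_kind = ratios$target_kind)
}

# year-by-year aggregate_year over a long data frame
per_year_aggregate <- function(df, years, weights, method, transform = identity) {
  est <- rep(NA_real_, length(years)); se <- est
  vals <- transform(df$value)
  yr_idx <- match(df$year, years)
  for (k in seq_along(years)) {
    sel <- yr_idx == k
    if (!any(sel)) next
    a <- aggregate_year(vals[sel],
                        weights = if (is.null(weights)) NULL else weights[sel],
                        method = method)
    est[k] <- a$estimate; se[k] <- a$se
  }
  list(est = est, se = se)
}

#' Build the 10-member ensemble of global status diagnostics
#'
#' Crosses the five averaging methods with the two rebuilding-target
#' definitions, for both quantities (B/BMSY and U/UMSY), over a common
#' reporting window. The window starts at `window_start` and ends at the
#' latest year in which at least `last_year_frac` of the filtered stocks
#' still report (recent assessment years are incomplete). The ensemble
#' summary per year is the unweighted mean across available member
#' estimates with a normal-approximation 95% interval,
#' mean +/- 1.96 * SD across members (undefined with fewer than two
#' members).
#'
#' Stocks without absolute biomass cannot support the half-max target and
#' are dropped from the half-max members only. The exploitation ratio is
#' identical under both targets, so the u members of the second target are
#' re-used from the first when the contributing stock set is unchanged.
#'
#' @param panel a filtered `stock_panel`
#' @param min_stocks_per_year mask years with fewer reporting stocks
#' @param window_start first reporting year of the ensemble window
#' @param last_year_frac fraction of stocks required to define the last
#'   reporting year
#' @param ss_control list passed to [fit_ss()]
#' @return object of class `ensemble_result`: list with `members` (long
#'   tibble over quantity, method, target_kind, year), `ensemble` (tibble
#'   `quantity`, `year`, `mean`, `lo`, `hi`, `n_members`), `window`,
#'   `endpoints`, and `config`
#' @export
build_ensemble <- function(panel, min_stocks_per_year = 20, window_start = 1980,
                           last_year_frac = 0.5, ss_control = list()) {
  stopifnot(inherits(panel, "stock_panel"))
  rp <- list(assessment_bmsy = make_ratios(panel, "assessment_bmsy"),
             half_max_biomass = make_ratios(panel, "half_max_biomass"))

  # last reporting year: latest year where >= last_year_frac of stocks have b
  avail <- rp$assessment_bmsy$ratios
  avail <- avail[!is.na(avail$b), , drop = FALSE]
  n_total <- n_stocks(panel)
  cov_year <- table(avail$year)
  ok_years <- as.integer(names(cov_year))[as.integer(cov_year) >= last_year_frac * n_total]
  if (length(ok_years) == 0L) stop("no year meets the reporting-coverage rule", call. = FALSE)
  last_year <- max(ok_years)
  if (window_start >= last_year) stop("window_start is at or beyond the last reporting year", call. = FALSE)
  window <- c(window_start, last_year)

  same_stocks <- setequal(unique(rp[[1]]$ratios$stock_id),
                          unique(rp[[2]]$ratios$stock_id))
  members <- list()
  for (tk in names(rp)) {
    for (m in agg_methods()) {
      for (q in c("b", "u")) {
        if (q == "u" && tk == "half_max_biomass" && same_stocks) {
          prev <- members[[paste("assessment_bmsy", m, "u")]]
          mem <- prev
          mem$target_kind <- tk
        } else {
          mem <- run_method(rp[[tk]], quantity = q, method = m, window = window,
                            min_stocks_per_year = min_stocks_per_year,
                            ss_control = ss_control)
        }
        members[[paste(tk, m, q)]] <- mem
      }
    }
  }
  members <- dplyr::bind_rows(members)

  ensemble <- members %>%
    dplyr::filter(!is.na(.data$estimate)) %>%
    dplyr::group_by(.data$quantity, .data$year) %>%
    dplyr::summarise(mean = mean(.data$estimate),
                     sd = sd(.data$estimate),
                     n_members = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(lo = ifelse(.data$n_members >= 2, .data$mean - 1.96 * .data$sd, NA_real_),
                  hi = ifelse(.data$n_members >= 2, .data$mean + 1.96 * .data$sd, NA_real_)) %>%
    dplyr::select("quantity", "year", "mean", "lo", "hi", "n_members")

  endpoints <- members[members$year %in% window, , drop = FALSE]

  structure(list(
    members = members, ensemble = ensemble, window = window,
    endpoints = endpoints,
    config = list(min_stocks_per_year = min_stocks_per_year,
                  window_start = window_start, last_year_frac = last_year_frac,
                  interval_rule = "normal approximation, mean +/- 1.96 SD across members",
                  weight_rule = "time-invariant per-stock mean biomass / mean catch")
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d members per quantity, window %d-%d\n",
              length(unique(paste(x$members$method, x$members$target_kind))),
              x$window[1], x$window[2]))
  last <- x$ensemble[x$ensemble$year == x$window[2], ]
  for (i in seq_len(nrow(last))) {
    cat(sprintf("  %s (%d): ensemble %.3f [%.3f, %.3f], %d members\n",
                last$quantity[i], last$year[i], last$mean[i], last$lo[i],
                last$hi[i], last$n_members[i]))
  }
  invisible(x)
}

#' Classify recovery at a reporting year
#'
#' For each of the ten (method, target) members, reports whether the global
#' average is within both targets at `year` — biomass at or above its target
#' (b >= 1) and exploitation at or below its target (u <= 1); values on the
#' target line count as within target, with a small floating-point
#' tolerance. Members missing either estimate at `year` are
#' `"undetermined"`. Also reports, per member, whether the 95% confidence
#' interval (estimate +/- 1.96 SE) straddles the target line for b and for
#' u, and the same diagnostics for the ensemble average using its member
#' spread interval.
#'
#' @param ensemble an `ensemble_result`
#' @param year reporting year (default: last year of the window)
#' @param tol boundary tolerance on the ratio scale
#' @return list with `members` (tibble of verdicts and straddle flags),
#'   `ensemble` (one-row tibble), `counts` (named vector over
#'   recovered / not_recovered / undetermined), `year`
#' @export
classify_recovery <- function(ensemble, year = NULL, tol = 1e-8) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  if (is.null(year)) year <- ensemble$window[2]
  if (year < ensemble$window[1] || year > ensemble$window[2]) {
    stop("`year` outside the reporting window", call. = FALSE)
  }
  at <- ensemble$members[ensemble$members$year == year, , drop = FALSE]
  wide <- tidyr::pivot_wider(at[, c("method", "target_kind", "quantity",
                                    "estimate", "se")],
                             names_from = "quantity",
                             values_from = c("estimate", "se"))
  straddles <- function(est, se) !is.na(est) & !is.na(se) &
    (est - 1.96 * se <= 1) & (est + 1.96 * se >= 1)
  verdict <- ifelse(is.na(wide$estimate_b) | is.na(wide$estimate_u),
                    "undetermined",
                    ifelse(wide$estimate_b >= 1 - tol & wide$estimate_u <= 1 + tol,
                           "recovered", "not_recovered"))
  members <- tibble::tibble(
    method = wide$method, target_kind = wide$target_kind,
    b = wide$estimate_b, b_se = wide$se_b,
    u = wide$estimate_u, u_se = wide$se_u,
    verdict = verdict,
    straddle_b = straddles(wide$estimate_b, wide$se_b),
    straddle_u = straddles(wide$estimate_u, wide$se_u)
  )
  ens <- ensemble$ensemble[ensemble$ensemble$year == year, , drop = FALSE]
  eb <- ens[ens$quantity == "b", ]; eu <- ens[ens$quantity == "u", ]
  ens_row <- tibble::tibble(
    b = if (nrow(eb)) eb$mean else NA_real_,
    u = if (nrow(eu)) eu$mean else NA_real_,
    verdict = if (!nrow(eb) || !nrow(eu)) "undetermined" else {
      if (eb$mean >= 1 - tol && eu$mean <= 1 + tol) "recovered" else "not_recovered"
    },
    straddle_b = nrow(eb) > 0 && !is.na(eb$lo) && eb$lo <= 1 && eb$hi >= 1,
    straddle_u = nrow(eu) > 0 && !is.na(eu$lo) && eu$lo <= 1 && eu$hi >= 1
  )
  counts <- c(recovered = sum(verdict == "recovered"),
              not_recovered = sum(verdict == "not_recovered"),
              undetermined = sum(verdict == "undetermined"))
  list(members = members, ensemble = ens_row, counts = counts, year = year)
}
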