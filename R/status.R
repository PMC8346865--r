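#' Kobe-quadrant classification
#'
#' Classifies a stock's status point (b = B/BMSY, u = U/UMSY):
#' `green` — at or above the biomass target and at or below the
#' exploitation target (b >= 1, u <= 1); `red` — below target and
#' overfished (b < 1, u > 1); `yellow_b` — only the biomass criterion fails
#' (b < 1, u <= 1); `yellow_u` — only the exploitation criterion fails
#' (b >= 1, u > 1). Values exactly on a target line count as satisfying the
#' target.
#'
#' @param b,u non-negative status ratios (vectorised)
#' @return factor with levels green, yellow_b, yellow_u, red (`NA` where
#'   either input is missing)
#' @export
#' @examples
#' kobe_classify(c(1.2, 0.5, 1.0), c(0.8, 1.5, 1.0))
kobe_classify <- function(b, u) {
  if (length(b) != length(u)) stop("`b` and `u` must align", call. = FALSE)
  if (any(b < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE)) {
    stop("status ratios must be non-negative", call. = FALSE)
  }
  out <- rep(NA_character_, length(b))
  ok <- !is.na(b) & !is.na(u)
  out[ok & b >= 1 & u <= 1] <- "green"
  out[ok & b < 1 & u > 1] <- "red"
  out[ok & b < 1 & u <= 1] <- "yellow_b"
  out[ok & b >= 1 & u > 1] <- "yellow_u"
  factor(out, levels = c("green", "yellow_b", "yellow_u", "red"))
}

#' Trend slope over a stock's most recent observed years
#'
#' Ordinary-least-squares slope of the ratio on calendar year over the
#' stock's most recent `window_years` *observed* years (not calendar years:
#' series with recent gaps use their last available decade of data). The
#' slope is undefined when fewer than `min_years` observations fall in that
#' window.
#'
#' @param years calendar years
#' @param values ratio values aligned with `years` (NAs allowed)
#' @param window_years number of most recent observed years to use
#' @param min_years minimum observations required
#' @return list with `slope` (per year; `NA` if undefined), `n` (years
#'   used) and `p` (two-sided OLS p-value of the slope; `NA` when undefined
#'   or with fewer than 3 points)
#' @export
#' @examples
#' trend_slope(2001:2010, 1 + 0.1 * (0:9))  # slope 0.1
trend_slope <- function(years, values, window_years = 10, min_years = 8) {
  keep <- !is.na(values)
  years <- years[keep]; values <- values[keep]
  if (length(years) == 0L) return(list(slope = NA_real_, n = 0L, p = NA_real_))
  ord <- order(years)
  years <- years[ord]; values <- values[ord]
  take <- tail(seq_along(years), window_years)
  years <- years[take]; values <- values[take]
  n <- length(years)
  if (n < min_years || stats::var(years) == 0) {
    return(list(slope = NA_real_, n = n, p = NA_real_))
  }
  fit <- lm(values ~ years)
  # summary.lm warns on exactly collinear (noise-free) input; the slope and
  # its (meaningless) p-value are still well defined for our purposes
  p <- if (n >= 3) {
    suppressWarnings(summary(fit)$coefficients["years", "Pr(>|t|)"])
  } else NA_real_
  list(slope = unname(coef(fit)[2]), n = n, p = p)
}

#' Per-stock status table
#'
#' For every stock with at least one year where both ratios are reported:
#' the most recent such year, the status ratios there, the Kobe quadrant,
#' and OLS trend slopes of b and u over the stock's most recent
#' `window_years` observed years of each series.
#'
#' @param ratios a `ratio_panel`
#' @param window_years,min_trend_years see [trend_slope()]
#' @return tibble with columns `stock_id`, `last_year`, `b_last`, `u_last`,
#'   `quadrant`, `b_slope`, `u_slope`, `slope_n_b`, `slope_n_u`,
#'   `target_kind`; the number of stocks lacking any joint (b, u) year is
#'   in attribute `n_excluded`
#' @export
stock_status_table <- function(ratios, window_years = 10, min_trend_years = 8) {
  stopifnot(inherits(ratios, "ratio_panel"))
  r <- ratios$ratios
  per_stock <- function(df) {
    joint <- df[!is.na(df$b) & !is.na(df$u), , drop = FALSE]
    if (nrow(joint) == 0L) return(NULL)
    last <- joint[which.max(joint$year), ]
    sb <- trend_slope(df$year, df$b, window_years, min_trend_years)
    su <- trend_slope(df$year, df$u, window_years, min_trend_years)
    tibble::tibble(stock_id = df$stock_id[1], last_year = last$year,
                   b_last = last$b, u_last = last$u,
                   b_slope = sb$slope, u_slope = su$slope,
                   slope_n_b = sb$n, slope_n_u = su$n,
                   b_slope_p = sb$p, u_slope_p = su$p)
  }
  parts <- lapply(split(r, r$stock_id), per_stock)
  n_excluded <- sum(vapply(parts, is.null, logical(1)))
  out <- dplyr::bind_rows(parts)
  if (nrow(out) == 0L) stop("no stock has a year with both ratios", call. = FALSE)
  out$quadrant <- kobe_classify(out$b_last, out$u_last)
  out$target_kind <- ratios$target_kind
  out <- out[, c("stock_id", "last_year", "b_last", "u_last", "quadrant",
                 "b_slope", "u_slope", "slope_n_b", "slope_n_u",
                 "b_slope_p", "u_slope_p", "target_kind")]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Distributional status summary under both rebuilding targets
#'
#' Computes, for each target kind, the percentage of stocks below the
#' biomass target (b_last < 1), above the exploitation target (u_last > 1),
#' trending downward in b (slope < 0) and upward in u (slope > 0) over
#' their most recent observed decade, plus the across-target maxima — the
#' "up to" figures. Also returns histogram bin counts of the most recent
#' b and u across stocks (for the overlay of the two target definitions).
#'
#' Trend percentages are computed among stocks with a defined slope; trend
#' classification is by the sign of the raw slope. A significance filter
#' (`trend_p_max`) can optionally restrict "trending" to slopes whose OLS
#' p-value is below the threshold.
#'
#' @param panel a filtered `stock_panel`
#' @param window_years,min_trend_years see [trend_slope()]
#' @param bin_width histogram bin width (ratio units)
#' @param trend_p_max optional p-value threshold for trend classification
#'   (`NULL`, the default, uses raw slope signs)
#' @return list with `per_target` (tibble of percentages by target kind),
#'   `maxima` (named vector of across-target maxima), `histograms` (tibble
#'   of bin counts), and `status` (list of per-stock tables by target kind)
#' @export
status_summary <- function(panel, window_years = 10, min_trend_years = 8,
                           bin_width = 0.1, trend_p_max = NULL) {
  stopifnot(inherits(panel, "stock_panel"))
  kinds <- c("assessment_bmsy", "half_max_biomass")
  status <- lapply(kinds, function(tk) {
    st <- stock_status_table(make_ratios(panel, tk), window_years, min_trend_years)
    st
  })
  names(status) <- kinds

  trend_pct <- function(slopes, pvals, direction) {
    ok <- !is.na(slopes)
    if (!any(ok)) return(NA_real_)
    hit <- if (direction == "down") slopes[ok] < 0 else slopes[ok] > 0
    if (!is.null(trend_p_max)) hit <- hit & !is.na(pvals[ok]) & pvals[ok] <= trend_p_max
    100 * mean(hit)
  }
  per_target <- dplyr::bind_rows(lapply(kinds, function(tk) {
    st <- status[[tk]]
    tibble::tibble(
      target_kind = tk,
      n_stocks = nrow(st),
      pct_below_b = 100 * mean(st$b_last < 1),
      pct_above_u = 100 * mean(st$u_last > 1),
      pct_b_down = trend_pct(st$b_slope, st$b_slope_p, "down"),
      pct_u_up = trend_pct(st$u_slope, st$u_slope_p, "up"),
      n_trend_b = sum(!is.na(st$b_slope)),
      n_trend_u = sum(!is.na(st$u_slope))
    )
  }))
  maxima <- c(pct_below_b = max(per_target$pct_below_b),
              pct_above_u = max(per_target$pct_above_u),
              pct_b_down = max(per_target$pct_b_down, na.rm = TRUE),
              pct_u_up = max(per_target$pct_u_up, na.rm = TRUE))

  hist_counts <- function(x, tk, q) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width  # all values in one bin
    breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
    h <- hist(x, breaks = breaks, plot = FALSE)
    tibble::tibble(target_kind = tk, quantity = q,
                   bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
                   count = h$counts)
  }
  histograms <- dplyr::bind_rows(
    lapply(kinds, function(tk) dplyr::bind_rows(
      hist_counts(status[[tk]]$b_last, tk, "b"),
      hist_counts(status[[tk]]$u_last, tk, "u")
    ))
  )
  list(per_target = per_target, maxima = maxima, histograms = histograms,
       status = status)
}

#' Proportion of stocks within targets over time
#'
#' For every year from `start_year`, the fraction of reporting stocks
#' within the biomass target (b >= 1) and within the exploitation target
#' (u <= 1), each among stocks reporting that quantity, defined only where
#' at least `min_stocks_per_year` report. The extrema report gives the
#' maximum historical proportion below the biomass target and over the
#' exploitation target with their (earliest, on ties) years, the final
#' defined values, and the improvements (maximum minus final, in
#' percentage points).
#'
#' @param ratios a `ratio_panel`
#' @param start_year first year of the series
#' @param min_stocks_per_year minimum reporting stocks for a defined year
#' @return list with `series` (tibble `year`, `prop_within_b`,
#'   `prop_within_u`, `n_b`, `n_u`) and `extrema` (one-row tibble)
#' @export
proportion_series <- function(ratios, start_year = 1950, min_stocks_per_year = 20) {
  stopifnot(inherits(ratios, "ratio_panel"))
  r <- ratios$ratios[ratios$ratios$year >= start_year, , drop = FALSE]
  series <- r %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      n_b = sum(!is.na(.data$b)),
      n_u = sum(!is.na(.data$u)),
      prop_within_b = if (sum(!is.na(.data$b)) > 0) mean(.data$b >= 1, na.rm = TRUE) else NA_real_,
      prop_within_u = if (sum(!is.na(.data$u)) > 0) mean(.data$u <= 1, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      prop_within_b = ifelse(.data$n_b >= min_stocks_per_year, .data$prop_within_b, NA_real_),
      prop_within_u = ifelse(.data$n_u >= min_stocks_per_year, .data$prop_within_u, NA_real_)
    ) %>%
    dplyr::arrange(.data$year)
  if (all(is.na(series$prop_within_b)) && all(is.na(series$prop_within_u))) {
    stop("no year meets min_stocks_per_year", call. = FALSE)
  }

  extremum <- function(prop_within, years) {
    below <- 1 - prop_within
    ok <- !is.na(below)
    if (!any(ok)) return(list(max = NA_real_, year = NA_integer_, final = NA_real_))
    mx <- max(below[ok])
    hit_years <- years[ok][below[ok] == mx]
    if (length(hit_years) > 1L) {
      message(sprintf("tie in extremum year (%s); earliest reported",
                      paste(hit_years, collapse = ", ")))
    }
    final <- below[ok][which.max(years[ok])]
    list(max = mx, year = min(hit_years), final = final)
  }
  eb <- extremum(series$prop_within_b, series$year)
  eu <- extremum(series$prop_within_u, series$year)
  extrema <- tibble::tibble(
    target_kind = ratios$target_kind,
    max_prop_below_b = eb$max, year_max_below_b = eb$year,
    final_prop_below_b = eb$final,
    improvement_b = eb$max - eb$final,
    max_prop_over_u = eu$max, year_max_over_u = eu$year,
    final_prop_over_u = eu$final,
    improvement_u = eu$max - eu$final
  )
  list(series = series, extrema = extrema)
}
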