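#' Build status-ratio panels under a rebuilding-target definition
#'
#' Converts a [stock_panel()] into per-stock B/BMSY (`b`) and U/UMSY (`u`)
#' series under one of two biomass rebuilding targets:
#'
#' * `assessment_bmsy` — the assessment's own reference point: a pre-divided
#'   ratio series when the stock reports one, otherwise `B / B_MSY`.
#' * `half_max_biomass` — the precautionary target of half the historical
#'   maximum: `b = B / (0.5 * max(B))`, the maximum taken over the stock's
#'   non-missing observed biomass. Stocks with no absolute biomass series
#'   cannot support this target and are excluded with a warning.
#'
#' The exploitation ratio `u` is identical under both target kinds (the
#' exploitation target is always the assessment's U_MSY). Switching target
#' kind therefore rescales each stock's `b` series by one positive constant
#' and leaves `u` untouched.
#'
#' Per-stock aggregation weights are computed alongside the ratios: the
#' time-mean observed absolute biomass and the time-mean catch (both
#' time-invariant, so that weighting does not conflate weight trends with
#' status trends).
#'
#' @param panel a `stock_panel`
#' @param target_kind `"assessment_bmsy"` or `"half_max_biomass"`
#' @return object of class `ratio_panel`: list with `ratios` (tibble
#'   `stock_id`, `year`, `b`, `u`), `weights` (tibble `stock_id`,
#'   `w_biomass`, `w_catch`), `target_kind`, and `meta`
#' @export
#' @examples
#' p <- simulate_panel(sim_config(n_stocks = 4, n_years = 12, seed = 3))
#' r <- make_ratios(p, "assessment_bmsy")
#' head(r$ratios)
make_ratios <- function(panel, target_kind = c("assessment_bmsy", "half_max_biomass")) {
  stopifnot(inherits(panel, "stock_panel"))
  target_kind <- match.arg(target_kind)
  s <- dplyr::left_join(panel$series, panel$refpoints, by = "stock_id")

  # exploitation ratio: pre-divided wins, else U / U_MSY (per-stock rule)
  s <- s %>%
    dplyr::group_by(.data$stock_id) %>%
    dplyr::mutate(has_u_ratio = any(!is.na(.data$u_ratio)),
                  has_b_ratio = any(!is.na(.data$b_ratio))) %>%
    dplyr::ungroup()
  u <- ifelse(s$has_u_ratio, s$u_ratio,
              ifelse(!is.na(s$U_MSY) & s$U_MSY > 0, s$U / s$U_MSY, NA_real_))

  if (target_kind == "assessment_bmsy") {
    b <- ifelse(s$has_b_ratio, s$b_ratio,
                ifelse(!is.na(s$B_MSY) & s$B_MSY > 0, s$B / s$B_MSY, NA_real_))
    dropped <- character()
  } else {
    bmax <- s %>%
      dplyr::group_by(.data$stock_id) %>%
      dplyr::summarise(has_B = any(!is.na(.data$B)),
                       B_max = suppressWarnings(max(.data$B, na.rm = TRUE)),
                       .groups = "drop")
    dropped <- bmax$stock_id[!bmax$has_B]
    if (length(dropped)) {
      warning(sprintf(
        "half_max_biomass target: %d stock(s) without absolute biomass excluded",
        length(dropped)), call. = FALSE)
    }
    s <- dplyr::left_join(s, bmax[, c("stock_id", "B_max")], by = "stock_id")
    b <- s$B / (0.5 * s$B_max)
    keep <- !(s$stock_id %in% dropped)
    s <- s[keep, , drop = FALSE]
    b <- b[keep]
    u <- u[keep]
  }

  ratios <- tibble::tibble(stock_id = s$stock_id, year = s$year, b = b, u = u)
  ratios <- ratios[!(is.na(ratios$b) & is.na(ratios$u)), , drop = FALSE]

  weights <- s %>%
    dplyr::group_by(.data$stock_id) %>%
    dplyr::summarise(
      w_biomass = if (any(!is.na(.data$B))) mean(.data$B, na.rm = TRUE) else NA_real_,
      w_catch = if (any(!is.na(.data$catch))) mean(.data$catch, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    )

  structure(list(
    ratios = ratios,
    weights = weights,
    target_kind = target_kind,
    meta = c(panel$meta[c("source", "series_preference")],
             list(n_dropped_half_max = length(dropped)))
  ), class = "ratio_panel")
}

#' @export
print.ratio_panel <- function(x, ...) {
  cat(sprintf("<ratio_panel> target=%s, %d stocks, %d stock-years\n",
              x$target_kind, length(unique(x$ratios$stock_id)), nrow(x$ratios)))
  invisible(x)
}

#' Export a ratio panel as a tidy table
#' @param ratios a `ratio_panel`
#' @return tibble with columns stock_id, year, b, u, target_kind
#' @export
ratio_table <- function(ratios) {
  stopifnot(inherits(ratios, "ratio_panel"))
  tibble::tibble(ratios$ratios, target_kind = ratios$target_kind)
}
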