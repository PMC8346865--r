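#' Assemble a panel of assessed stocks
#'
#' A `stock_panel` bundles annual time series for a collection of assessed
#' fish stocks with their maximum-sustainable-yield (MSY) reference points.
#' Each stock may carry absolute biomass `B`, exploitation rate `U` (the
#' fraction of biomass caught per year), annual `catch`, and/or pre-divided
#' status ratios `b_ratio` (B/BMSY) and `u_ratio` (U/UMSY) as reported by the
#' assessment. Missing values are explicit `NA`s: a (stock, year) pair absent
#' from the input stays missing and is never zero-filled.
#'
#' @param series data frame with columns `stock_id`, `year` and any of
#'   `B`, `U`, `catch`, `b_ratio`, `u_ratio`. One row per stock-year.
#' @param refpoints data frame with columns `stock_id` and any of `B_MSY`,
#'   `U_MSY` (assessment reference points in the units of `B` and `U`).
#' @param truth optional list with elements `stocks` and `series` holding the
#'   generating truth of a simulated panel (see [simulate_panel()]).
#' @param meta named list of provenance metadata (source, series preference,
#'   filters applied, seed).
#'
#' @return An object of class `stock_panel`: a list with elements `series`,
#'   `refpoints`, `truth`, `meta`.
#' @export
#' @examples
#' stock_panel(
#'   series = data.frame(stock_id = "a", year = 2000:2002,
#'                       B = c(10, 20, 16), U = 0.1, catch = NA_real_),
#'   refpoints = data.frame(stock_id = "a", B_MSY = 10, U_MSY = 0.2)
#' )
stock_panel <- function(series, refpoints, truth = NULL, meta = list()) {
  stopifnot(is.data.frame(series), is.data.frame(refpoints))
  series <- tibble::as_tibble(series)
  refpoints <- tibble::as_tibble(refpoints)
  if (!all(c("stock_id", "year") %in% names(series))) {
    stop("`series` must have columns stock_id and year", call. = FALSE)
  }
  if (!"stock_id" %in% names(refpoints)) {
    stop("`refpoints` must have a stock_id column", call. = FALSE)
  }
  for (col in c("B", "U", "catch", "b_ratio", "u_ratio")) {
    if (!col %in% names(series)) series[[col]] <- NA_real_
    series[[col]] <- as.numeric(series[[col]])
  }
  for (col in c("B_MSY", "U_MSY")) {
    if (!col %in% names(refpoints)) refpoints[[col]] <- NA_real_
    refpoints[[col]] <- as.numeric(refpoints[[col]])
  }
  series$stock_id <- as.character(series$stock_id)
  series$year <- as.integer(series$year)
  refpoints$stock_id <- as.character(refpoints$stock_id)
  series <- series[order(series$stock_id, series$year),
                   c("stock_id", "year", "B", "U", "catch", "b_ratio", "u_ratio")]
  refpoints <- refpoints[order(refpoints$stock_id), c("stock_id", "B_MSY", "U_MSY")]
  panel <- structure(
    list(series = series, refpoints = refpoints, truth = truth, meta = meta),
    class = "stock_panel"
  )
  validate_stock_panel(panel)
}

validate_stock_panel <- function(panel) {
  s <- panel$series
  if (nrow(s) == 0L) stop("panel has no series rows", call. = FALSE)
  if (anyDuplicated(s[, c("stock_id", "year")])) {
    stop("duplicate (stock_id, year) rows in panel series", call. = FALSE)
  }
  if (anyDuplicated(panel$refpoints$stock_id)) {
    stop("duplicate stock_id in refpoints", call. = FALSE)
  }
  for (col in c("B", "U", "catch", "b_ratio", "u_ratio")) {
    if (any(s[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative values in series column `%s`", col), call. = FALSE)
    }
  }
  panel
}

#' @export
print.stock_panel <- function(x, ...) {
  yrs <- range(x$series$year)
  cat(sprintf("<stock_panel> %d stocks, years %d-%d, %d series rows\n",
              n_stocks(x), yrs[1], yrs[2], nrow(x$series)))
  if (!is.null(x$truth)) cat("  simulated panel (generating truth attached)\n")
  if (length(x$meta$filters)) {
    cat(sprintf("  filters applied: %s\n",
                paste(names(x$meta$filters), unlist(x$meta$filters),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Number of stocks in a panel
#' @param panel a `stock_panel`
#' @return integer count of distinct stocks
#' @export
n_stocks <- function(panel) length(unique(panel$series$stock_id))

#' Global year axis of a panel
#' @param panel a `stock_panel`
#' @return sorted integer vector, union of all stocks' years
#' @export
panel_years <- function(panel) sort(unique(panel$series$year))

# Per-stock availability of status ratios: a year contributes a b (u) ratio if
# a pre-divided ratio is reported or an absolute series plus reference point
# allows deriving one.
ratio_availability <- function(panel) {
  s <- dplyr::left_join(panel$series, panel$refpoints, by = "stock_id")
  s$b_ok <- !is.na(s$b_ratio) | (!is.na(s$B) & !is.na(s$B_MSY) & s$B_MSY > 0)
  s$u_ok <- !is.na(s$u_ratio) | (!is.na(s$U) & !is.na(s$U_MSY) & s$U_MSY > 0)
  dplyr::summarise(dplyr::group_by(s, .data$stock_id),
                   n_b_years = sum(.data$b_ok),
                   n_u_years = sum(.data$u_ok),
                   .groups = "drop")
}

#' Filter a panel by data requirements
#'
#' Retains stocks with at least `min_years` years of biomass-ratio data
#' (pre-divided or derivable from `B` and `B_MSY`). When
#' `require_both_ratios` is `TRUE`, the same minimum applies to the
#' exploitation ratio as well. Removal counts are recorded in the panel's
#' provenance metadata.
#'
#' @param panel a `stock_panel`
#' @param min_years minimum number of years with ratio data (default 0)
#' @param require_both_ratios require both B/BMSY and U/UMSY availability
#' @return the filtered `stock_panel`; an empty result triggers a warning
#' @export
filter_panel <- function(panel, min_years = 0, require_both_ratios = FALSE) {
  avail <- ratio_availability(panel)
  keep <- avail$n_b_years >= min_years
  if (require_both_ratios) keep <- keep & (avail$n_u_years >= max(1, min_years))
  keep_ids <- avail$stock_id[keep]
  removed <- setdiff(avail$stock_id, keep_ids)
  if (length(keep_ids) == 0L) {
    warning("filter_panel removed every stock", call. = FALSE)
  }
  series <- panel$series[panel$series$stock_id %in% keep_ids, , drop = FALSE]
  refpoints <- panel$refpoints[panel$refpoints$stock_id %in% keep_ids, , drop = FALSE]
  truth <- panel$truth
  if (!is.null(truth)) {
    truth$stocks <- truth$stocks[truth$stocks$stock_id %in% keep_ids, , drop = FALSE]
    truth$series <- truth$series[truth$series$stock_id %in% keep_ids, , drop = FALSE]
  }
  meta <- panel$meta
  meta$filters <- c(meta$filters, list(
    min_years = min_years,
    require_both_ratios = require_both_ratios,
    n_removed = length(removed)
  ))
  if (length(keep_ids) == 0L) {
    # keep structure valid for downstream error messages
    return(structure(list(series = panel$series[0, ], refpoints = refpoints,
                          truth = truth, meta = meta), class = "stock_panel"))
  }
  stock_panel(series, refpoints, truth = truth, meta = meta)
}
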