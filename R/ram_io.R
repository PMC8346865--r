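#' Series-id aliases for RAM-style long tables
#'
#' Stock-assessment compilations name their time series with version-dependent
#' ids (e.g. `TB-MT` for total biomass in metric tons,
#' `TBdivTBmsy-dimensionless` for a pre-divided biomass ratio). The mapping
#' from ids to the roles this package understands ships as an editable YAML
#' file so new vocabularies can be added without touching code.
#'
#' Roles: `total_biomass`, `spawning_biomass`, `b_ratio_total`,
#' `b_ratio_spawning`, `exploitation`, `u_ratio`, `catch` for time series;
#' `b_msy`, `u_msy` for reference-point parameter ids.
#'
#' @param path YAML file mapping roles to character vectors of series ids;
#'   defaults to the copy shipped with the package.
#' @return named list of character vectors
#' @export
ram_series_aliases <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ram_series_aliases.yaml", package = "fishstatus")
  }
  aliases <- yaml::read_yaml(path)
  lapply(aliases, as.character)
}

# map series ids to roles; unknown ids -> NA (ignored)
role_of <- function(ids, aliases, roles) {
  out <- rep(NA_character_, length(ids))
  for (role in roles) {
    out[ids %in% aliases[[role]]] <- role
  }
  out
}

#' Read RAM-style long tables into a stock panel
#'
#' Consumes a long time-series table (columns `stock_id`, `series_id`,
#' `year`, `value`) and a reference-point table (columns `stock_id`,
#' `parameter_id`, `value`), as exported from the RAM Legacy database or by
#' [export_ram_like()]. `series_preference` selects whether total-biomass or
#' spawning-stock-biomass series represent "biomass"; when the preferred
#' family is absent for a stock the other family is used and the fallback is
#' counted in the panel's metadata.
#'
#' Pre-divided ratio series (B/BMSY, U/UMSY reported by the assessment) take
#' precedence over ratios derivable from absolute series and reference
#' points; a warning is issued when both exist and disagree. Rows with
#' negative values are dropped with a warning; duplicate
#' (stock, series, year) rows are an error. Reading is order-independent and
#' never fills missing years.
#'
#' @param timeseries_path,refpoints_path CSV paths (plain or compressed)
#' @param series_preference `"total_biomass"` or `"spawning_biomass"`
#' @param aliases series-id vocabulary, see [ram_series_aliases()]
#' @return a [stock_panel()]
#' @export
read_ram_long <- function(timeseries_path, refpoints_path,
                          series_preference = c("total_biomass", "spawning_biomass"),
                          aliases = ram_series_aliases()) {
  series_preference <- match.arg(series_preference)
  ts <- readr::read_csv(timeseries_path, show_col_types = FALSE, progress = FALSE)
  rp <- readr::read_csv(refpoints_path, show_col_types = FALSE, progress = FALSE)
  need_ts <- c("stock_id", "series_id", "year", "value")
  if (!all(need_ts %in% names(ts))) {
    stop(sprintf("timeseries table must have columns %s",
                 paste(need_ts, collapse = ", ")), call. = FALSE)
  }
  need_rp <- c("stock_id", "parameter_id", "value")
  if (!all(need_rp %in% names(rp))) {
    stop(sprintf("refpoints table must have columns %s",
                 paste(need_rp, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(ts[, c("stock_id", "series_id", "year")])) {
    stop("duplicate (stock_id, series_id, year) rows in timeseries table",
         call. = FALSE)
  }
  neg <- !is.na(ts$value) & ts$value < 0
  if (any(neg)) {
    warning(sprintf("dropping %d negative-valued rows", sum(neg)), call. = FALSE)
    ts <- ts[!neg, , drop = FALSE]
  }
  ts <- ts[!is.na(ts$value), , drop = FALSE]

  ts_roles <- c("total_biomass", "spawning_biomass", "b_ratio_total",
                "b_ratio_spawning", "exploitation", "u_ratio", "catch")
  ts$role <- role_of(ts$series_id, aliases, ts_roles)
  ts <- ts[!is.na(ts$role), , drop = FALSE]

  # biomass family preference with per-stock fallback
  if (series_preference == "total_biomass") {
    fam <- c(abs1 = "total_biomass", abs2 = "spawning_biomass",
             rat1 = "b_ratio_total", rat2 = "b_ratio_spawning")
  } else {
    fam <- c(abs1 = "spawning_biomass", abs2 = "total_biomass",
             rat1 = "b_ratio_spawning", rat2 = "b_ratio_total")
  }
  pick_family <- function(df, first, second) {
    have_first <- unique(df$stock_id[df$role == first])
    out <- df[(df$role == first) |
                (df$role == second & !(df$stock_id %in% have_first)), , drop = FALSE]
    attr(out, "n_fallback") <- length(setdiff(unique(df$stock_id[df$role == second]),
                                              have_first))
    out
  }
  b_abs <- pick_family(ts, fam[["abs1"]], fam[["abs2"]])
  b_rat <- pick_family(ts, fam[["rat1"]], fam[["rat2"]])
  n_fallback <- attr(b_abs, "n_fallback")
  attr(b_abs, "n_fallback") <- NULL
  attr(b_rat, "n_fallback") <- NULL

  wide <- function(df, col) {
    if (nrow(df) == 0L) return(NULL)
    stats::setNames(df[, c("stock_id", "year", "value")], c("stock_id", "year", col))
  }
  parts <- list(
    wide(b_abs, "B"),
    wide(ts[ts$role == "exploitation", ], "U"),
    wide(ts[ts$role == "catch", ], "catch"),
    wide(b_rat, "b_ratio"),
    wide(ts[ts$role == "u_ratio", ], "u_ratio")
  )
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) stop("no recognised series in timeseries table", call. = FALSE)
  series <- Reduce(function(x, y) dplyr::full_join(x, y, by = c("stock_id", "year")),
                   parts)

  rp$role <- role_of(rp$parameter_id, aliases, c("b_msy", "u_msy"))
  rp <- rp[!is.na(rp$role) & !is.na(rp$value), , drop = FALSE]
  refpoints <- tidyr::pivot_wider(
    rp[, c("stock_id", "role", "value")],
    names_from = "role", values_from = "value",
    values_fn = function(x) x[1]
  )
  names(refpoints)[names(refpoints) == "b_msy"] <- "B_MSY"
  names(refpoints)[names(refpoints) == "u_msy"] <- "U_MSY"
  if (nrow(refpoints) == 0L) {
    refpoints <- tibble::tibble(stock_id = character(), B_MSY = numeric(),
                                U_MSY = numeric())
  }

  panel <- stock_panel(series, refpoints,
                       meta = list(source = timeseries_path,
                                   series_preference = series_preference,
                                   n_biomass_fallback = n_fallback))

  # warn when pre-divided and derived biomass ratios disagree materially
  chk <- dplyr::left_join(panel$series, panel$refpoints, by = "stock_id")
  both <- !is.na(chk$b_ratio) & !is.na(chk$B) & !is.na(chk$B_MSY) & chk$B_MSY > 0
  if (any(both)) {
    rel <- abs(chk$b_ratio[both] / (chk$B[both] / chk$B_MSY[both]) - 1)
    if (any(rel > 1e-6)) {
      warning(sprintf(
        "%d stock-years where the pre-divided B/BMSY disagrees with B / B_MSY; pre-divided series used",
        sum(rel > 1e-6)), call. = FALSE)
    }
  }
  panel
}
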