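#' Kobe-style plot of the ensemble trajectories
#'
#' Plots the ten member trajectories in the (B/BMSY, U/UMSY) plane as grey
#' paths with the ensemble average overlaid, and the target lines at ratio
#' 1 on both axes.
#'
#' @param ensemble an `ensemble_result`
#' @return a ggplot object
#' @export
plot_kobe <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_result"))
  wide <- tidyr::pivot_wider(
    ensemble$members[, c("method", "target_kind", "quantity", "year", "estimate")],
    names_from = "quantity", values_from = "estimate")
  wide$member <- paste(wide$method, wide$target_kind)
  ens <- tidyr::pivot_wider(
    ensemble$ensemble[, c("quantity", "year", "mean")],
    names_from = "quantity", values_from = "mean")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$b, y = .data$u)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$member),
                       colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_path(data = ens, colour = "red", linewidth = 1, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "B / BMSY", y = "U / UMSY",
                  title = "Global average stock status: ensemble members") +
    ggplot2::theme_minimal()
}

#' Plot proportion-within-target series
#'
#' @param proportions result of [proportion_series()]
#' @return a ggplot object
#' @export
plot_proportion_series <- function(proportions) {
  s <- proportions$series
  long <- tidyr::pivot_longer(s[, c("year", "prop_within_b", "prop_within_u")],
                              cols = -"year", names_to = "quantity",
                              values_to = "proportion")
  long$quantity <- ifelse(long$quantity == "prop_within_b",
                          "within biomass target", "within exploitation target")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$proportion,
                                     colour = .data$quantity)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c("within biomass target" = "black",
                                            "within exploitation target" = "red")) +
    ggplot2::labs(x = "Year", y = "Proportion of stocks", colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
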