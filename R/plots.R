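# ggplot2 summaries of the main result types.

#' Van Krevelen diagram of assigned formulas
#'
#' @param assignments A tibble with `oc`, `hc` and `class` columns (e.g.
#'   the `fticr$assignments` element of [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_van_krevelen <- function(assignments) {
  dat <- assignments |> filter(!is.na(.data$class))
  ggplot2::ggplot(dat, ggplot2::aes(.data$oc, .data$hc,
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "O:C", y = "H:C", colour = "Compound class") +
    ggplot2::theme_minimal()
}

#' Community growth and mortality rates over time
#'
#' @param community Output of [community_rates()].
#' @return A ggplot object with growth and mortality panels per treatment.
#' @export
plot_community_rates <- function(community) {
  dat <- community |>
    pivot_longer(c("growth", "mortality"),
                 names_to = "rate", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(.data$timepoint_h, .data$value,
                                    colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "Hours after rewetting",
                  y = "Rate (16S copies g⁻¹ d⁻¹)",
                  colour = "Treatment (% MAP)") +
    ggplot2::theme_minimal()
}

#' Normalized community growth efficiency over time
#'
#' @param cge Output of [cge_table()].
#' @return A ggplot object.
#' @export
plot_cge <- function(cge) {
  ggplot2::ggplot(filter(cge, !.data$flagged),
                  ggplot2::aes(.data$timepoint_h, .data$cge,
                               colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hours after rewetting", y = "CGE (normalized)",
                  colour = "Treatment (% MAP)") +
    ggplot2::theme_minimal()
}

#' VIP score plot for a PLS fit
#'
#' Bar plot of the top-ranked predictors' VIP scores, signed by the
#' direction of their regression coefficient.
#'
#' @param object A `pls_cge` fit.
#' @param n_top Number of predictors to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pls_cge
#' @export
autoplot.pls_cge <- function(object, n_top = 25, ...) {
  dat <- select_top(object) |>
    slice_head(n = n_top) |>
    mutate(direction = if_else(.data$sign >= 0, "positive", "negative"))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$vip),
    y = .data$vip, fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP score", fill = "Association") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
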