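#' Plot per-library Brillouin diversity and evenness
#'
#' Bar panels of H_B and V by library, the graphical analogue of the
#' diversity report table.
#'
#' @param data Output of [diversity_table()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(data) {
  long <- data |>
    dplyr::select("library", "h_b", "v") |>
    tidyr::pivot_longer(c("h_b", "v"), names_to = "index",
                        values_to = "value") |>
    dplyr::mutate(index = dplyr::recode(.data$index,
                                        h_b = "H[B]~(nats/individual)",
                                        v = "V~(relative~evenness)"),
                  library = factor(.data$library, levels = unique(.data$library)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~index, scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(x = "Clone library", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot development endpoints as median and range per treatment
#'
#' Point-and-whisker panels (median, observed range) for survivorship,
#' %Copepodites and the development index.
#'
#' @param data Output of [development_endpoints()].
#' @return A ggplot object.
#' @export
plot_endpoints <- function(data) {
  sm <- endpoint_summary(data) |>
    dplyr::mutate(endpoint = factor(.data$endpoint,
                                    levels = c("survivorship",
                                               "pct_copepodites", "di"),
                                    labels = c("Survivorship (%)",
                                               "%Copepodites", "DI")))
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$treatment, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$min, ymax = .data$max)) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = "Treatment", y = "Median and range") +
    ggplot2::theme_minimal()
}

#' Plot the maximal-evenness partition behind a Brillouin result
#'
#' @param object A `"brillouin"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brillouin
#' @export
autoplot.brillouin <- function(object, ...) {
  df <- tibble(part = seq_along(object$partition$composition),
               size = object$partition$composition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$part, y = .data$size)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Phylotype (maximal-evenness partition)",
                  y = "Clones",
                  title = sprintf("H_B = %.3f, V = %s", object$h_b,
                                  ifelse(is.na(object$v), "undefined",
                                         sprintf("%.3f", object$v)))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
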