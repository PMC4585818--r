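#' Plot diversity indices by treatment
#'
#' Boxplots of richness, Shannon and inverse Simpson indices split by
#' treatment and faceted by index.
#'
#' @param object A [diversity_indices()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fmen_diversity <- function(object, ...) {
  long <- object %>%
    select("sample", "treatment", "richness", "shannon", "inv_simpson") %>%
    tidyr::pivot_longer(c("richness", "shannon", "inv_simpson"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$treatment, y = .data$value,
                               fill = .data$treatment)) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Functional gene alpha-diversity by treatment")
}

#' Plot a threshold scan trace
#'
#' Poisson-fit p-value of the nearest-neighbour spacing test against the
#' candidate similarity threshold, with the rejection level and the chosen
#' threshold marked.
#'
#' @param object A [scan_threshold()] result.
#' @param alpha Rejection level to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fmen_scan <- function(object, alpha = 0.05, ...) {
  tr <- filter(object$trace, !is.na(.data$p_value))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$st, y = .data$p_value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$decision)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$chosen_st, colour = "red") +
    ggplot2::labs(x = "similarity threshold", y = "Poisson-fit p-value",
                  title = paste0("RMT threshold scan (chosen S_t = ",
                                 object$chosen_st, ")"))
}

#' Plot a network degree distribution
#'
#' @param object An `fmen_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fmen_network <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$k)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "connectivity k", y = "nodes",
                  title = sprintf("Degree distribution (n = %d, avgK = %.2f)",
                                  object$n, object$avg_k))
}
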