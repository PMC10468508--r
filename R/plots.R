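#' Plot an Rg mixture fit over its sample
#'
#' Histogram (density scale) of the fitted Rg sample with the two weighted
#' Gaussian component curves and their sum.
#'
#' @param object An [fit_rg_mixture()] result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rg_mixture_fit <- function(object, bins = 60, ...) {
  df <- tibble(rg = object$values)
  grid <- tibble(rg = seq(min(df$rg), max(df$rg), length.out = 400))
  curves <- purrr::map_dfr(1:2, function(k) {
    mutate(grid,
           component = paste0("component ", k),
           density = object$weights[k] *
             dnorm(.data$rg, object$means[k], object$sds[k]))
  })
  total <- grid %>%
    mutate(component = "mixture",
           density = object$weights[1] *
             dnorm(.data$rg, object$means[1], object$sds[1]) +
             object$weights[2] *
             dnorm(.data$rg, object$means[2], object$sds[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rg)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = bind_rows(curves, total),
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component,
                                    linetype = .data$component)) +
    ggplot2::labs(x = "Rg (Å)", y = "density",
                  title = "Trimer Rg distribution and two-Gaussian fit") +
    ggplot2::theme_minimal()
}

#' Plot a contact map
#'
#' Tile plot of a boolean or frequency contact map; reference maps carry
#' their side-chain/backbone contact class as fill.
#'
#' @param map Tibble from [snapshot_contact_map()],
#'   [ensemble_contact_frequencies()] or [reference_contact_map()].
#' @return A ggplot object.
#' @export
plot_contact_map <- function(map) {
  if ("class" %in% names(map)) {
    df <- filter(map, .data$contact)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                          fill = .data$class)) +
      ggplot2::geom_tile(colour = "white")
  } else if ("frequency" %in% names(map)) {
    p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$j, y = .data$i,
                                           fill = .data$frequency)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  } else {
    p <- ggplot2::ggplot(filter(map, .data$contact),
                         ggplot2::aes(x = .data$j, y = .data$i)) +
      ggplot2::geom_tile(fill = "grey20")
  }
  p +
    ggplot2::scale_y_reverse(breaks = scales_int) +
    ggplot2::scale_x_continuous(breaks = scales_int, position = "top") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i") +
    ggplot2::theme_minimal()
}

scales_int <- function(lims) {
  seq(ceiling(min(lims)), floor(max(lims)), by = 2)
}

#' Plot per-residue secondary-structure propensities
#'
#' @param ptable Propensity table from [propensity_table()].
#' @return A ggplot object.
#' @export
plot_propensity <- function(ptable) {
  long <- tidyr::pivot_longer(ptable, c("H", "E", "C"), names_to = "state",
                              values_to = "propensity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue,
                                     y = .data$propensity,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(
      values = c(H = "#d62728", E = "#1f77b4", C = "grey50"),
      labels = c(H = "α-helix", E = "β-strand", C = "coil")
    ) +
    ggplot2::labs(x = "residue", y = "propensity") +
    ggplot2::theme_minimal()
}

#' Plot a final score table
#'
#' Bar chart of the final multiplicative score per force field, ordered by
#' rank.
#'
#' @param object An `ff_score_table` from [final_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ff_score_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(force_field = stats::reorder(.data$force_field, -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$final,
                                   y = .data$force_field)) +
    ggplot2::geom_col(fill = "#1f77b4") +
    ggplot2::labs(x = "final score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
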