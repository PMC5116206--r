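# ggplot2 views of trajectories, dose maps and PRCC tables.

#' Plot a simulated disease course
#'
#' Faceted time series of all species (or a selection), on a log10
#' concentration axis by default since the state spans ten orders of
#' magnitude.
#'
#' @param object an `ad_trajectory`.
#' @param species character vector of species to show (default all).
#' @param log10 logical; log-scale the value axis.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ad_trajectory <- function(object, species = NULL, log10 = TRUE, ...) {
  long <- tidy(object)
  if (!is.null(species)) long <- dplyr::filter(long, .data$species %in% !!species)
  if (log10) long <- dplyr::filter(long, .data$value > 0)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$years, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (years)", y = "concentration / density (g/ml)") +
    ggplot2::theme_minimal()
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot an efficacy map
#'
#' @param object an `ad_efficacy_map` from [efficacy_map()].
#' @param measure `"E_N"`, `"E_Abeta"` or `"death_reduction"`.
#' @param ... unused.
#' @return A ggplot heat map over the (f, h) dose plane.
#' @export
autoplot.ad_efficacy_map <- function(object, measure = c("E_N", "E_Abeta",
                                                         "death_reduction"),
                                     ...) {
  measure <- match.arg(measure)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f, y = .data$h,
                                       fill = .data[[measure]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = measure) +
    ggplot2::labs(x = "etanercept fold f", y = "aducanumab fold h") +
    ggplot2::theme_minimal()
}

#' Plot a synergy map
#'
#' Cells where the index is undefined (zero-dose row and column) are blank.
#'
#' @param object an `ad_synergy_map` from [synergy_map()].
#' @param ... unused.
#' @return A ggplot heat map of `sigma_N` with the neutral level at 1.
#' @export
autoplot.ad_synergy_map <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$defined),
                  ggplot2::aes(x = .data$f, y = .data$g, fill = .data$sigma_N)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, name = expression(sigma[N])) +
    ggplot2::labs(x = "etanercept fold f", y = "aducanumab fold g") +
    ggplot2::theme_minimal()
}

#' Plot PRCC results
#'
#' @param object an `ad_sensitivity` from [run_sensitivity()].
#' @param ... unused.
#' @return A ggplot bar chart of PRCC per factor, faceted by output.
#' @export
autoplot.ad_sensitivity <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$factor, y = .data$estimate,
                                    fill = .data$estimate > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~output) +
    ggplot2::labs(x = NULL, y = "PRCC") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
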