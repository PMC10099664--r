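#' Plot bootstrap sampling distributions of sexual dimorphism
#'
#' One panel per scope (population or pooled treatment) showing the
#' bootstrap sampling distribution of the male minus female mean
#' sucrose:yeast ratio, with zero marked.
#'
#' @param object A `"dimorph_est"` table from [dimorphism_estimates()] (or a
#'   single `"dimorph_boot"` row).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dimorph_est <- function(object, bins = 60, ...) {
  df <- tidyr::unnest(
    dplyr::select(as_tibble(object), "scope", "draws"), "draws")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draws)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~scope, scales = "free_y") +
    ggplot2::labs(x = "male - female mean sucrose:yeast",
                  y = "bootstrap replicates") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dimorph_est
#' @export
autoplot.dimorph_boot <- autoplot.dimorph_est

#' Plot posterior densities of the bivariate-model fixed effects
#'
#' @param object A `"bivariate_mm"` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bivariate_mm <- function(object, ...) {
  df <- as_tibble(object$draws$beta) %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "term",
                        values_to = "draw")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "effect (µg)", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot mean-fitness trajectories
#'
#' Recruitment per female across generations, one line per population.
#'
#' @param fitness Output of [mean_fitness()].
#' @return A ggplot object.
#' @export
plot_fitness <- function(fitness) {
  ggplot2::ggplot(fitness,
                  ggplot2::aes(x = .data$generation, y = .data$mean_fitness,
                               group = .data$population,
                               colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation", y = "recruits per female") +
    ggplot2::theme_minimal()
}

#' Plot evolutionary rates by sex and trait
#'
#' @param rates Output of [haldane_rates()].
#' @return A ggplot object.
#' @export
plot_rates <- function(rates) {
  ggplot2::ggplot(rates,
                  ggplot2::aes(x = .data$sex, y = .data$rate,
                               shape = .data$treatment)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(y = "evolutionary rate (Haldanes)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a dimorphism-estimate table
#'
#' Drops the list-column of bootstrap draws, leaving the flat per-scope
#' summary.
#'
#' @param x A `"dimorph_est"` or `"dimorph_boot"` table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dimorph_est <- function(x, ...) {
  dplyr::select(as_tibble(x), -"draws")
}

#' @rdname tidy.dimorph_est
#' @export
tidy.dimorph_boot <- tidy.dimorph_est
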