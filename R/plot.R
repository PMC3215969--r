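#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a production envelope
#'
#' Ribbon of attainable product flux against growth rate.
#'
#' @param object an `efba_envelope` from [production_envelope()].
#' @param ... passed to [ggplot2::geom_ribbon()].
#' @return A ggplot.
#' @export
#' @method autoplot efba_envelope
autoplot.efba_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$growth_rate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$product_min, ymax = .data$product_max),
      fill = "steelblue", alpha = 0.35, ...) +
    ggplot2::geom_line(ggplot2::aes(y = .data$product_max),
                       colour = "steelblue4") +
    ggplot2::geom_line(ggplot2::aes(y = .data$product_min),
                       colour = "steelblue4", linetype = "dashed") +
    ggplot2::labs(
      x = "growth rate (1/hr)",
      y = paste0(attr(object, "product_id"), " flux (mmol/gDW-hr)"),
      title = sprintf("Production envelope (electron uptake ≤ %g)",
                      attr(object, "electron_uptake_max"))) +
    ggplot2::theme_minimal()
}

#' Compare two production envelopes
#'
#' Overlays the enhanced and base envelopes, the direct visualization of
#' "electrical enhancement enlarges the production envelope".
#'
#' @param base,enhanced `efba_envelope` objects for the same product.
#' @return A ggplot.
#' @export
plot_envelope_comparison <- function(base, enhanced) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(base),
                  case = sprintf("electron uptake ≤ %g",
                                 attr(base, "electron_uptake_max"))),
    dplyr::mutate(tibble::as_tibble(enhanced),
                  case = sprintf("electron uptake ≤ %g",
                                 attr(enhanced, "electron_uptake_max")))
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$growth_rate,
                                     fill = .data$case)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$product_min, ymax = .data$product_max),
      alpha = 0.35) +
    ggplot2::labs(x = "growth rate (1/hr)",
                  y = paste0(attr(base, "product_id"),
                             " flux (mmol/gDW-hr)"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a SPEEQ yield-improvement grid
#'
#' Percent theoretical yield improvement against the substrate-product
#' electron equivalence quotient; pairs helped by CO2-refixing pathways sit
#' above the monotone trend.
#'
#' @param object an `efba_speeq_grid` from [yield_improvement_grid()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot efba_speeq_grid
autoplot.efba_speeq_grid <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$feasible)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$speeq,
                                    y = 100 * .data$improvement,
                                    colour = .data$product)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "SPEEQ (degree of reduction, substrate / product)",
                  y = "theoretical yield improvement (%)",
                  colour = "product") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
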