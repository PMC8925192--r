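# ggplot2 views of the main result types.

#' Plot the B-vs-A isoform concentration plane
#'
#' The screening scatter: each milk sample positioned by its A and B channel
#' signals, coloured by genotype call, with low-B outliers visually
#' separable below the main AB cluster.
#'
#' @param calls Output of [classify_genotype()].
#' @return A ggplot object.
#' @export
plot_isoform_plane <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$A_units, y = .data$B_units,
                                      colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "BLG A isoform (arb units)", y = "BLG B isoform (arb units)",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Histogram and fitted components of a segregation mixture
#'
#' @param object A `blg_mixture` from [fit_segregation_mixture()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blg_mixture <- function(object, bins = 30, ...) {
  x <- object$data
  grid <- seq(min(x), max(x), length.out = 400)
  dens <- purrr::map_dfr(1:2, function(k) {
    tibble::tibble(
      x = grid,
      density = object$weights[k] * stats::dnorm(grid, object$means[k],
                                                 object$sds[k]),
      component = factor(k)
    )
  })
  ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "observation", y = "density", colour = "component") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an association scan
#'
#' @param scan A `blg_scan` from [assoc_scan()].
#' @return A ggplot object with the significance threshold drawn.
#' @export
plot_manhattan <- function(scan) {
  th <- attr(scan, "threshold")
  dat <- dplyr::mutate(scan, index = dplyr::row_number(),
                       logp = -log10(.data$p))
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = .data$logp,
                                          colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "variant index", y = expression(-log[10](p)),
                  colour = "chromosome") +
    ggplot2::theme_minimal()
  if (!is.null(th)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(th), linetype = 2)
  }
  gg
}
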