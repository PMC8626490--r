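# ggplot2 presentation methods for the result types.

strain_long <- function(x) {
  d1 <- tibble::tibble(row = as.vector(row(x$eps_p1)),
                       col = as.vector(col(x$eps_p1)),
                       channel = "eps_p1", value = as.vector(x$eps_p1))
  d2 <- dplyr::mutate(d1, channel = "eps_p2",
                      value = as.vector(x$eps_p2))
  dplyr::bind_rows(d1, d2)
}

#' Plot a principal strain map pair
#'
#' Renders eps_p1 and eps_p2 as rasters with the fixed diverging color
#' scale over \[-0.5, 0.5\].
#'
#' @param object a `principal_strain`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.principal_strain <- function(object, ...) {
  ggplot2::ggplot(strain_long(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-0.5, 0.5),
                                  oob = scales_squish, name = "strain") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency)
scales_squish <- function(x, range = c(-0.5, 0.5)) pmin(pmax(x, range[1]),
                                                        range[2])

#' Scatter plot of a strain comparison
#'
#' Estimated versus reference strain with the identity line; points far
#' from the diagonal mark over/under-estimation.
#'
#' @param object a `strain_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.strain_comparison <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(channel = "eps_p1", est = object$scatter$est_p1,
                   ref = object$scatter$ref_p1),
    tibble::tibble(channel = "eps_p2", est = object$scatter$est_p2,
                   ref = object$scatter$ref_p2))
  lab <- sprintf("R = %.3f / %.3f", object$R[["eps_p1"]],
                 object$R[["eps_p2"]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ref, y = .data$est,
                                  colour = .data$channel)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(eps_p1 = "#b2182b",
                                            eps_p2 = "#2166ac")) +
    ggplot2::coord_fixed(xlim = c(-0.5, 0.5), ylim = c(-0.5, 0.5)) +
    ggplot2::labs(x = "reference strain", y = "estimated strain",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-bin absolute strain errors
#'
#' Median absolute error per 0.05 reference-strain bin with IQR whiskers.
#'
#' @param object an `error_histogram`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.error_histogram <- function(object, ...) {
  d <- dplyr::mutate(object, mid = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$median_abs_err,
                                  fill = .data$channel)) +
    ggplot2::geom_col(width = 0.04) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$median_abs_err - .data$iqr_abs_err / 2,
                               0),
                   ymax = .data$median_abs_err + .data$iqr_abs_err / 2),
      width = 0.015) +
    ggplot2::facet_wrap(~channel, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(eps_p1 = "#b2182b",
                                          eps_p2 = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = "reference strain bin", y = "absolute error") +
    ggplot2::theme_minimal()
}

#' Training and validation loss curves
#'
#' @param object a fitted `strain_mapper`.
#' @param ... unused.
#' @return a ggplot of per-epoch pixelwise loss.
#' @export
autoplot.strain_mapper <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$L_G,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "pixelwise loss L_G") +
    ggplot2::theme_minimal()
}
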