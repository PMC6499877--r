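#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

vf_image_df <- function(img, grid) {
  ax <- grid_axes(grid)
  tibble::tibble(
    x = rep(ax$x, each = grid$n_rows),
    y = rep(ax$y, times = grid$n_cols),
    value = as.vector(img)
  )
}

#' Plot a visual-field image
#'
#' @param object A `vf_image` (reconstruction or letter raster).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vf_image
#' @export
autoplot.vf_image <- function(object, ...) {
  grid <- attr(object, "grid")
  ggplot2::ggplot(vf_image_df(unclass(object), grid),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vf_image
#' @method autoplot vf_letter
#' @export
autoplot.vf_letter <- autoplot.vf_image

#' Plot fitted pRF centres
#'
#' Centres in the visual field, sized by pRF sigma and coloured by fit
#' score.
#'
#' @param object A `prf_fits` tibble from [fit_prf()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prf_fits
#' @export
autoplot.prf_fits <- function(object, ...) {
  ggplot2::ggplot(object[object$valid, ],
                  ggplot2::aes(x = .data$x0, y = .data$y0,
                               size = .data$sigma, colour = .data$score)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", size = expression(sigma),
                  colour = "fit r") +
    ggplot2::theme_minimal()
}

#' Plot a decoding permutation test
#'
#' Histogram of the null accuracies with the observed accuracy (solid)
#' and the 95th-percentile threshold (dashed).
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy.permutation_result(object),
                  ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "classification accuracy", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot the autoencoder loss trajectory
#'
#' @param object A trained `denoising_ae`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot denoising_ae
#' @export
autoplot.denoising_ae <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "optimizer step", y = "mean squared restoration error") +
    ggplot2::theme_minimal()
}
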