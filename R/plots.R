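# Plotting: a section viewer with its ground-truth / measured overlays and
# a forest-style display of the routed group comparisons.

#' Plot a synthetic or measured mucosa section
#'
#' Renders the calibrated image as a grey raster with the annotation
#' geometry overlaid: villous outlines, base chords, crypt axes and the
#' muscularis mucosae baseline.
#'
#' @param image a `calibrated_image`.
#' @param annotation optional `mucosa_annotation` overlay.
#' @return a ggplot object.
#' @export
plot_mucosa <- function(image, annotation = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  upp <- image$um_per_pixel
  ny <- nrow(px)
  df <- expand.grid(c = seq_len(ncol(px)), r = seq_len(ny))
  df$x <- (df$c - 0.5) * upp
  df$y <- (ny - df$r + 0.5) * upp
  df$intensity <- as.vector(t(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "grey10", high = "grey95", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u03bcm)", y = "y (\u03bcm)") +
    ggplot2::theme_minimal()
  if (!is.null(annotation)) {
    poly_df <- purrr::imap_dfr(annotation$villus_polygons, function(m, i) {
      tibble::tibble(x = m[, 1], y = m[, 2], id = i)
    })
    p <- p +
      ggplot2::geom_polygon(data = poly_df,
                            ggplot2::aes(group = .data$id),
                            fill = NA, colour = "steelblue", linewidth = 0.4) +
      ggplot2::geom_path(
        data = tibble::tibble(x = annotation$muscularis_polyline[, 1],
                              y = annotation$muscularis_polyline[, 2]),
        colour = "white", linewidth = 0.6)
    crypt_df <- purrr::imap_dfr(annotation$crypt_polylines, function(m, i) {
      tibble::tibble(x = m[, 1], y = m[, 2], id = i)
    })
    if (nrow(crypt_df)) {
      p <- p + ggplot2::geom_path(data = crypt_df,
                                  ggplot2::aes(group = .data$id),
                                  colour = "cyan3", linewidth = 0.4)
    }
  }
  p
}

#' Forest-style plot of routed group comparisons
#'
#' @param object a `villi_analysis` from [route_and_compare()].
#' @param ... unused.
#' @return a ggplot object: estimate and 95% CI per variable, faceted by
#'   HIV stratum.
#' @exportS3Method ggplot2::autoplot
autoplot.villi_analysis <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$variable)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$test), size = 2) +
    ggplot2::facet_wrap(~ stratum, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "MM \u2212 placebo (variable units)", y = NULL,
                  shape = "test") +
    ggplot2::theme_minimal()
}
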