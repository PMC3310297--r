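#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_raster geom_path
#'   coord_equal labs theme_minimal facet_wrap scale_size_area
#' @export
ggplot2::autoplot

#' Dot plot of an indicator matrix
#'
#' Draws a black dot wherever `u[h, k] = 1`: the classic sequence dot
#' plot. Periodicity appears as stripes parallel to the diagonal, symbol
#' persistence as filled squares.
#'
#' @param object An [indicator_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot indicator_matrix
#' @export
autoplot.indicator_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(k = seq_len(ncol(object)),
                           h = seq_len(nrow(object)))  # h varies fastest,
  df$value <- as.vector(unclass(object))               # matching column-major
  df <- df[df$value == 1L, ]
  ggplot(df, aes(x = .data$k, y = .data$h)) +
    geom_raster(fill = "black") +
    coord_equal() +
    labs(x = "k", y = "h",
         title = sprintf("Dot plot of '%s'", attr(object, "sequence_ref"))) +
    theme_minimal()
}

#' Spiral distribution plot
#'
#' One panel per symbol, showing where along the rectangular spiral each
#' symbol falls. For a uniform random sequence the four nucleotide panels
#' are statistically indistinguishable.
#'
#' @param object A [spiral_layout()].
#' @param ... Unused.
#' @return A ggplot faceted by symbol.
#' @method autoplot spiral_layout
#' @export
autoplot.spiral_layout <- function(object, ...) {
  ggplot(object, aes(x = a, y = b)) +
    geom_point(size = 0.8) +
    facet_wrap(~symbol) +
    coord_equal() +
    labs(x = "a", y = "b",
         title = sprintf("Spiral distribution of '%s'",
                         attr(object, "id"))) +
    theme_minimal()
}

#' Walk trajectory plot
#'
#' @param object A [dna_walk()] tibble.
#' @param ... Unused.
#' @return A ggplot of the walk in the complex plane.
#' @method autoplot dna_walk
#' @export
autoplot.dna_walk <- function(object, ...) {
  ggplot(object, aes(x = re, y = im)) +
    geom_path() +
    coord_equal() +
    labs(x = "Re z", y = "Im z",
         title = sprintf("Walk of '%s'", attr(object, "id"))) +
    theme_minimal()
}

#' Coefficient-cluster plot
#'
#' One panel per wavelet coefficient, plotting the distinct
#' (real-channel, imaginary-channel) pairs with point size proportional
#' to multiplicity — the cluster view in which unit-root signals show
#' their finite, symmetric coefficient sets.
#'
#' @param object An [coefficient_clusters()] result.
#' @param ... Unused.
#' @return A ggplot faceted by coefficient.
#' @method autoplot sw_clusters
#' @export
autoplot.sw_clusters <- function(object, ...) {
  ggplot(object, aes(x = re, y = im, size = count)) +
    geom_point(alpha = 0.7) +
    scale_size_area(max_size = 4) +
    facet_wrap(~coefficient) +
    coord_equal() +
    labs(x = "real channel", y = "imaginary channel",
         title = sprintf("Wavelet coefficient clusters of '%s' (p = %d)",
                         attr(object, "id"), attr(object, "window"))) +
    theme_minimal()
}
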