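#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a short Haar transform
#'
#' @param x A [short_haar()] result.
#' @param ... Unused.
#' @return A long tibble with one row per segment and coefficient:
#'   `segment`, `coefficient`, `re`, `im`.
#' @method tidy short_haar
#' @export
tidy.short_haar <- function(x, ...) {
  labels <- colnames(x$coeffs_real)
  tibble(
    segment = rep(seq_len(x$n_segments), times = length(labels)),
    coefficient = factor(rep(labels, each = x$n_segments), levels = labels),
    re = as.vector(x$coeffs_real),
    im = as.vector(x$coeffs_imag)
  ) |>
    dplyr::arrange(segment, coefficient)
}

#' Glance at a short Haar transform
#'
#' @param x A [short_haar()] result.
#' @param ... Unused.
#' @return A one-row tibble: window, number of segments, convention,
#'   signal length used, and total coefficient energy per channel.
#' @method glance short_haar
#' @export
glance.short_haar <- function(x, ...) {
  tibble(
    id = x$id, window = x$window, n_segments = x$n_segments,
    convention = x$convention, length_used = x$length_used,
    energy_real = sum(x$coeffs_real^2),
    energy_imag = sum(x$coeffs_imag^2)
  )
}
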