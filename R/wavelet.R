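#' Orthonormal Haar matrix
#'
#' Builds the N x N discrete Haar transform matrix for `N = 2^M`. Row 1 is
#' the constant scaling row `N^(-1/2)`; the detail row for level `n` and
#' shift `k` (n = 0..M-1, k = 0..2^n - 1) is supported on a block of
#' length `N / 2^n` and takes the value `-1/sqrt(L)` on the earlier half
#' and `+1/sqrt(L)` on the later half (`L` the block length), so every
#' detail coefficient is a "later minus earlier" finite difference. The
#' matrix is orthonormal: `W %*% t(W)` is the identity.
#'
#' @param order Matrix order, a power of two >= 2.
#' @return A numeric matrix of class `haar_matrix`; row names label the
#'   coefficients (`alpha`, `beta_k^n`).
#' @examples
#' haar_matrix(4)
#' @export
haar_matrix <- function(order) {
  n <- as.integer(order)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L) {
    abort("`order` must be a power of two, at least 2.")
  }
  m_levels <- as.integer(round(log2(n)))
  w <- matrix(0, n, n)
  w[1L, ] <- 1 / sqrt(n)
  labels <- "alpha"
  row <- 1L
  for (lev in 0:(m_levels - 1L)) {
    block <- n %/% 2L^lev
    half <- block %/% 2L
    for (k in 0:(2L^lev - 1L)) {
      row <- row + 1L
      start <- k * block
      w[row, (start + 1L):(start + half)] <- -1 / sqrt(block)
      w[row, (start + half + 1L):(start + block)] <- 1 / sqrt(block)
      labels <- c(labels, sprintf("beta_%d^%d", k, lev))
    }
  }
  rownames(w) <- labels
  structure(w, class = c("haar_matrix", "matrix", "array"))
}

#' Short (windowed) Haar wavelet transform
#'
#' Splits a complex signal into consecutive non-overlapping windows of
#' length `p` (the trailing partial window is discarded) and applies the
#' `p`-point Haar transform to the real and imaginary channels of each
#' window independently. Under the default `"orthonormal"` convention the
#' transform conserves energy per window and inverts exactly; under
#' `"eq57_average"` the first coefficient is replaced by the plain window
#' mean (the remaining detail rows keep the orthonormal scaling).
#'
#' For root-encoded sequences at `p = 4` the detail coefficients take
#' values in small finite sets (differences of unit-root coordinates
#' scaled by powers of `1/sqrt(2)`) — the discreteness that
#' [coefficient_clusters()] exposes and that washes out as `p` grows.
#'
#' @param x A `complex_signal`, a [dna_walk()] tibble, or a plain
#'   complex/numeric vector.
#' @param p Window length: 4, 8, 16 or 32.
#' @param convention `"orthonormal"` (default) or `"eq57_average"`.
#' @return An object of class `short_haar`: a list with `window`,
#'   `n_segments`, `convention`, coefficient matrices `coeffs_real` and
#'   `coeffs_imag` (segments x coefficients, columns labelled `alpha`,
#'   `beta_k^n`), and the identifier of the source.
#' @examples
#' short_haar(encode_roots(symbol_seq("ACGTACGT")), p = 4)
#' @export
short_haar <- function(x, p = 4L, convention = c("orthonormal", "eq57_average")) {
  convention <- match.arg(convention)
  p <- as.integer(p)
  if (!p %in% c(4L, 8L, 16L, 32L)) {
    abort("`p` must be one of 4, 8, 16, 32.")
  }
  id <- ""
  if (inherits(x, "dna_walk")) {
    # the walk series itself is the signal to transform
    id <- attr(x, "id") %||% ""
    x <- complex(real = x$re, imaginary = x$im)
  } else if (inherits(x, "complex_signal")) {
    id <- attr(x, "id") %||% ""
    x <- unclass(x)
  }
  z <- as.complex(x)
  if (length(z) < p) {
    abort(sprintf("Signal length %d is shorter than the window %d.",
                  length(z), p))
  }
  sigma <- length(z) %/% p
  z <- z[seq_len(sigma * p)]
  w <- unclass(haar_matrix(p))
  if (convention == "eq57_average") w[1L, ] <- 1 / p
  seg <- matrix(z, nrow = p)  # one column per window
  cr <- t(w %*% Re(seg))
  ci <- t(w %*% Im(seg))
  colnames(cr) <- colnames(ci) <- rownames(haar_matrix(p))
  structure(
    list(window = p, n_segments = sigma, convention = convention,
         coeffs_real = cr, coeffs_imag = ci, id = id,
         length_used = sigma * p),
    class = "short_haar"
  )
}

#' @export
print.short_haar <- function(x, ...) {
  cat(sprintf(
    "<short_haar '%s': window %d, %d segments, %s convention>\n",
    x$id, x$window, x$n_segments, x$convention
  ))
  invisible(x)
}

#' Invert a short Haar transform
#'
#' Reconstructs the windowed portion of the input signal (the trailing
#' partial window that the forward transform discarded is not recovered).
#' Exact to floating-point accuracy under both conventions — the
#' `eq57_average` scaling of the first row is stored in the result and
#' undone here.
#'
#' @param result A [short_haar()] result.
#' @return A `complex_signal` of length `n_segments * window`.
#' @export
inverse_short_haar <- function(result) {
  p <- result$window
  w <- unclass(haar_matrix(p))
  if (result$convention == "eq57_average") w[1L, ] <- 1 / p
  winv <- solve(w)
  re <- winv %*% t(result$coeffs_real)
  im <- winv %*% t(result$coeffs_imag)
  new_complex_signal(as.vector(complex(real = re, imaginary = im)),
                     id = result$id)
}

#' Coefficient-pair clusters of a short Haar transform
#'
#' For each coefficient index, collects the distinct (real-channel,
#' imaginary-channel) coefficient pairs across all segments, with their
#' multiplicities. For unit-root signals at `p = 4` each detail cluster is
#' a small finite point set; plotting the clusters (see
#' [autoplot.sw_clusters()]) shows the symmetric lattice patterns that
#' distinguish root-encoded sequences from arbitrary signals.
#'
#' @param result A [short_haar()] result.
#' @param digits Values are rounded to this many digits before grouping
#'   (default 10), so that floating-point ties collapse.
#' @return A tibble of class `sw_clusters` with columns `coefficient`,
#'   `re`, `im`, `count`; per coefficient the counts sum to the number of
#'   segments.
#' @examples
#' coefficient_clusters(short_haar(random_unit_complex(400, seed = 1)))
#' @export
coefficient_clusters <- function(result, digits = 10L) {
  if (result$n_segments < 1L) abort("No segments in the transform result.")
  labels <- colnames(result$coeffs_real)
  long <- tibble(
    segment = rep(seq_len(result$n_segments), times = length(labels)),
    coefficient = rep(labels, each = result$n_segments),
    re = round(as.vector(result$coeffs_real), digits),
    im = round(as.vector(result$coeffs_imag), digits)
  )
  out <- long |>
    dplyr::count(coefficient, re, im, name = "count") |>
    dplyr::mutate(coefficient = factor(coefficient, levels = labels)) |>
    dplyr::arrange(coefficient, re, im)
  structure(out, id = result$id, window = result$window,
            n_segments = result$n_segments,
            class = c("sw_clusters", class(tibble())))
}
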