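#' Rectangular (Ulam-style) spiral coordinates
#'
#' Maps 1-based sequence indices to integer lattice points along a
#' counterclockwise rectangular spiral starting at the origin: arm lengths
#' run 1, 1, 2, 2, 3, 3, ... with directions cycling +x, +y, -x, -y, so the
#' first points are (0,0), (1,0), (1,1), (0,1), (-1,1), (-1,0), (-1,-1),
#' (0,-1), (1,-1), (2,-1), (2,0), ... The map is injective, so every
#' lattice point identifies at most one index ([spiral_index()] inverts
#' it).
#'
#' @param n Vector of 1-based indices.
#' @return A tibble with columns `n`, `a`, `b` (`a + i b` being the complex
#'   lattice point of index `n`).
#' @examples
#' spiral_coords(1:11)
#' @export
spiral_coords <- function(n) {
  n <- as.integer(n)
  if (length(n) == 0L || any(n < 1L)) {
    abort("Spiral indices must be integers >= 1.")
  }
  pts <- spiral_points(max(n))
  tibble(n = n, a = pts$a[n], b = pts$b[n])
}

## first n_max spiral points, vectorized arm construction
spiral_points <- function(n_max) {
  # arm r (r = 1, 2, ...) has length ceiling(r / 2) and direction
  # (+x, +y, -x, -y)[(r - 1) %% 4 + 1]; enough arms to cover n_max steps
  arms <- 0L
  total <- 1L
  while (total < n_max) {
    arms <- arms + 1L
    total <- total + (arms + 1L) %/% 2L
  }
  lens <- (seq_len(max(arms, 1L)) + 1L) %/% 2L
  dirs <- c(1, 1i, -1, -1i)[(seq_len(max(arms, 1L)) - 1L) %% 4L + 1L]
  steps <- rep(dirs, lens)
  z <- c(0+0i, cumsum(steps))[seq_len(n_max)]
  list(a = as.integer(round(Re(z))), b = as.integer(round(Im(z))))
}

#' Invert the spiral map
#'
#' @param a,b Integer lattice coordinates (vectors of equal length).
#' @return Integer vector of 1-based indices (`NA` if a point is not
#'   reachable — it always is for finite coordinates, searched out to the
#'   enclosing ring).
#' @examples
#' spiral_index(2, 0)
#' @export
spiral_index <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ring <- max(abs(c(a, b))) + 1L
  n_max <- (2L * ring + 1L)^2L
  pts <- spiral_points(n_max)
  key <- paste(pts$a, pts$b)
  idx <- match(paste(a, b), key)
  as.integer(idx)
}

#' Spiral layout of a symbolic sequence
#'
#' Places symbol `h` of the sequence at the `h`-th point of the rectangular
#' spiral. Filtering the result by symbol gives the one-plot-per-nucleotide
#' spiral distributions; the per-symbol point sets partition the first N
#' spiral points.
#'
#' @param seq A [symbol_seq()].
#' @return A tibble of class `spiral_layout` with columns `n`, `a`, `b`,
#'   `symbol`.
#' @examples
#' spiral_layout(symbol_seq("ATGG"))
#' @export
spiral_layout <- function(seq) {
  tokens <- unclass(seq)
  out <- spiral_coords(seq_along(tokens))
  out$symbol <- tokens
  structure(out, id = seq_id(seq),
            class = c("spiral_layout", class(tibble())))
}
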