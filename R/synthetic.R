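#' Pseudorandom and pseudoperiodic control sequences
#'
#' `pseudorandom_sequence()` draws each symbol independently and uniformly
#' from the alphabet. `pseudoperiodic_sequence()` draws one pseudorandom
#' block of length `period` and concatenates identical copies of it, so
#' that `x[i] == x[i + period]` everywhere; when `length` is not a multiple
#' of `period` it is trimmed down to the largest multiple. With
#' `period = 1` the literal construction gives a constant sequence (one
#' repeated 1-block).
#'
#' These are the controls against which genomic sequences are compared:
#' the pseudorandom sequence is the maximum-disorder reference and the
#' pseudoperiodic one the maximum-order reference (diagonal stripes at lag
#' `period` in the dot plot).
#'
#' @param length Number of symbols to generate.
#' @param alphabet An [alphabet()]; defaults to nucleotides.
#' @param seed Integer seed; when given, the draw is reproducible and the
#'   caller's RNG state is left untouched. `NULL` uses the session RNG.
#' @param period Repeat period (pseudoperiodic only).
#' @return A [symbol_seq()].
#' @examples
#' pseudorandom_sequence(12, seed = 1)
#' pseudoperiodic_sequence(12, period = 4, seed = 1)
#' @export
pseudorandom_sequence <- function(length, alphabet = nucleotide_alphabet(),
                                  seed = NULL) {
  length <- as.integer(length)
  if (length < 1L) abort("`length` must be at least 1.")
  draw <- function() sample(unclass(alphabet), length, replace = TRUE)
  tokens <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  symbol_seq(tokens, alphabet = alphabet,
             id = sprintf("pseudorandom_n%d", length))
}

#' @rdname pseudorandom_sequence
#' @export
pseudoperiodic_sequence <- function(length, period,
                                    alphabet = nucleotide_alphabet(),
                                    seed = NULL) {
  length <- as.integer(length)
  period <- as.integer(period)
  if (period < 1L) abort("`period` must be at least 1.")
  if (period > length) abort("`period` may not exceed `length`.")
  k <- length %/% period
  length <- k * period
  draw <- function() sample(unclass(alphabet), period, replace = TRUE)
  block <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  symbol_seq(rep(block, k), alphabet = alphabet,
             id = sprintf("pseudoperiodic_n%d_p%d", length, period))
}

#' Pseudorandom unit-modulus complex sequence
#'
#' Generates terms `(-1)^r * i^s` with `r` uniform on \{0, 1\} and `s`
#' uniform on \{0, 1, 2, 3\}, so every term is one of the 4th roots of
#' unity \{1, i, -1, -i\}, each with probability 1/4. This is the white
#' noise reference signal on the unit circle.
#'
#' @param n Number of terms.
#' @param seed Integer seed (see [pseudorandom_sequence()]).
#' @return A complex vector of class `complex_signal` with unit modulus.
#' @examples
#' abs(random_unit_complex(5, seed = 1))
#' @export
random_unit_complex <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be at least 1.")
  draw <- function() {
    r <- sample(0:1, n, replace = TRUE)
    s <- sample(0:3, n, replace = TRUE)
    (-1)^r * (1i)^s
  }
  terms <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_complex_signal(terms, alphabet = NULL, id = sprintf("random_unit_n%d", n))
}
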