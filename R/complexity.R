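#' Randomness index of a prefix
#'
#' One minus a spread statistic of the per-symbol frequencies over the
#' first `n` positions: 1 when all alphabet symbols occur equally often
#' (the random reference), smaller the more skewed the composition. The
#' default spread is the population variance of the frequency vector;
#' `spread = "std"` uses the population standard deviation, which
#' penalises skew on a more visible scale.
#'
#' @param seq A [symbol_seq()] over any alphabet.
#' @param n Prefix length (default: whole sequence).
#' @param spread `"variance"` (default) or `"std"`.
#' @return A single number <= 1.
#' @examples
#' randomness_index(symbol_seq("ACGT"))
#' @export
randomness_index <- function(seq, n = length(seq),
                             spread = c("variance", "std")) {
  spread <- match.arg(spread)
  v <- prefix_freqs(seq, n)
  pop_var <- mean((v - mean(v))^2)
  1 - switch(spread, variance = pop_var, std = sqrt(pop_var))
}

prefix_freqs <- function(seq, n) {
  n <- as.integer(n)
  if (n < 1L || n > length(seq)) {
    abort(sprintf("Prefix length must lie in [1, %d].", length(seq)))
  }
  ab <- unclass(seq_alphabet(seq))
  tokens <- unclass(seq)[seq_len(n)]
  counts <- vapply(ab, function(s) sum(tokens == s), integer(1L))
  counts / n
}

#' Multinomial complexity of a prefix
#'
#' The per-symbol natural logarithm of the multinomial coefficient of the
#' symbol counts over the first `n` positions,
#' `K = log(n! / prod(counts!)) / n` in nats per symbol. K is 0 for a
#' constant sequence and maximal (about `log(M)` for large `n`) near equal
#' counts. Computed via log-gamma, so it is exact for any practical `n`.
#'
#' @inheritParams randomness_index
#' @return A single non-negative number (nats/symbol).
#' @examples
#' complexity_k(symbol_seq("ACGT"))  # log(24)/4
#' @export
complexity_k <- function(seq, n = length(seq)) {
  n <- as.integer(n)
  counts <- prefix_freqs(seq, n) * n
  (lgamma(n + 1) - sum(lgamma(counts + 1))) / n
}

#' Normalized Shannon entropy of a prefix
#'
#' `H = -sum(p * log(p)) / log(M)` with `p` the per-symbol frequencies
#' over the first `n` positions, `M` the alphabet cardinality, and the
#' convention `0 * log(0) = 0`. H lies in [0, 1]: 0 for a constant
#' sequence, 1 for exactly equal counts.
#'
#' @inheritParams randomness_index
#' @return A single number in [0, 1].
#' @examples
#' shannon_entropy(symbol_seq("AACG"))
#' @export
shannon_entropy <- function(seq, n = length(seq)) {
  p <- prefix_freqs(seq, n)
  m <- length(p)
  if (m < 2L) return(0)
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

#' Box-counting fractal dimension of an indicator matrix
#'
#' Estimates the dot plot's box-counting dimension from contiguous square
#' minors: for each minor size `n` in `n_range`, `p(n)` is the mean number
#' of ones over `minors_per_size` uniformly sampled `n x n` contiguous
#' submatrices (or over all of them with `exhaustive = TRUE`), and the
#' summary is taken over the terms `log(p(n)) / log(n)`. With
#' `normalization = "mean"` (default) the summary is their mean, which is
#' 2 for a saturated (all-ones) plot; `"sum_half"` divides the plain sum
#' by `2 * N` (`N` = matrix order) instead. Minor sizes with `p(n) = 0`
#' are skipped with a warning rather than propagating `-Inf`.
#'
#' Counting uses a summed-area table, so exhaustive enumeration is cheap.
#'
#' @param mat An [indicator_matrix()] (any binary matrix works).
#' @param n_range Integer vector of minor sizes (each >= 2 and at most the
#'   matrix order). Default `2:floor(N/2)`.
#' @param minors_per_size Number of random minors per size (default 100).
#' @param seed Integer seed for minor sampling.
#' @param normalization `"mean"` (default) or `"sum_half"`.
#' @param exhaustive If `TRUE`, use every contiguous minor of each size.
#' @return A single number; in [0, 2] whenever every `p(n) >= 1`.
#' @examples
#' m <- indicator_matrix(pseudorandom_sequence(60, seed = 1))
#' fractal_dimension(m, n_range = 2:20, seed = 1)
#' @export
fractal_dimension <- function(mat, n_range = NULL, minors_per_size = 100L,
                              seed = NULL,
                              normalization = c("mean", "sum_half"),
                              exhaustive = FALSE) {
  normalization <- match.arg(normalization)
  mat <- unclass(mat)
  nn <- nrow(mat)
  if (is.null(n_range)) n_range <- 2:max(2L, nn %/% 2L)
  n_range <- as.integer(n_range)
  if (any(n_range < 2L)) abort("Minor sizes must be >= 2 (log n > 0).")
  if (max(n_range) > nn) {
    abort(sprintf("Largest minor size %d exceeds the matrix order %d.",
                  max(n_range), nn))
  }
  # summed-area table with zero padding: ones in the n x n minor with top
  # left (i, j) is sat[i+n, j+n] - sat[i-1+n ...] in padded indexing
  sat <- matrix(0, nn + 1L, nn + 1L)
  sat[-1L, -1L] <- apply(apply(mat, 2L, cumsum), 1L, cumsum)
  sat <- t(sat)  # row-cumsum of col-cumsum, transposed back
  minor_sum <- function(i, j, n) {
    sat[cbind(i + n, j + n)] - sat[cbind(i, j + n)] -
      sat[cbind(i + n, j)] + sat[cbind(i, j)]
  }
  compute <- function() {
    vapply(n_range, function(n) {
      k <- nn - n + 1L
      if (exhaustive) {
        pos <- expand.grid(i = seq_len(k), j = seq_len(k))
        i <- pos$i; j <- pos$j
      } else {
        i <- sample.int(k, minors_per_size, replace = TRUE)
        j <- sample.int(k, minors_per_size, replace = TRUE)
      }
      mean(minor_sum(i, j, n))
    }, numeric(1L))
  }
  p <- if (is.null(seed)) compute() else withr::with_seed(seed, compute())
  zero <- p == 0
  if (any(zero)) {
    warn(sprintf("Skipping %d minor size(s) with p(n) = 0.", sum(zero)))
    p <- p[!zero]
    n_range <- n_range[!zero]
    if (length(p) == 0L) abort("All minor sizes had p(n) = 0.")
  }
  terms <- log(p) / log(n_range)
  switch(normalization, mean = mean(terms), sum_half = sum(terms) / (2 * nn))
}

#' All four complexity indices of a sequence
#'
#' Bundles the randomness index, multinomial complexity K, box-counting
#' fractal dimension D of the dot plot, and normalized Shannon entropy H
#' into one row. Default windows follow the conventions used throughout
#' the package: randomness over the first 10000 symbols, K, D and H over
#' the first 100 (all capped at the sequence length).
#'
#' @param seq A [symbol_seq()].
#' @param window_r,window_k,window_h,window_d Prefix lengths for the four
#'   indices.
#' @param spread Spread statistic for the randomness index.
#' @param n_range,minors_per_size Passed to [fractal_dimension()]; the
#'   default `n_range` is `2:floor(window_d / 2)`.
#' @param seed Integer seed for the minor sampling inside D.
#' @return A one-row tibble: `id`, `n`, `randomness`, `complexity_k`,
#'   `fractal_dimension`, `entropy`, plus the windows used.
#' @examples
#' complexity_report(pseudorandom_sequence(500, seed = 1), seed = 1)
#' @export
complexity_report <- function(seq, window_r = 10000L, window_k = 100L,
                              window_h = 100L, window_d = 100L,
                              spread = c("variance", "std"),
                              n_range = NULL, minors_per_size = 100L,
                              seed = NULL) {
  spread <- match.arg(spread)
  nN <- length(seq)
  wr <- min(window_r, nN); wk <- min(window_k, nN)
  wh <- min(window_h, nN); wd <- min(window_d, nN)
  if (is.null(n_range)) n_range <- 2:max(2L, wd %/% 2L)
  d <- fractal_dimension(indicator_matrix(seq[seq_len(wd)]),
                         n_range = n_range,
                         minors_per_size = minors_per_size, seed = seed)
  tibble(
    id = seq_id(seq), n = nN,
    randomness = randomness_index(seq, wr, spread = spread),
    complexity_k = complexity_k(seq, wk),
    fractal_dimension = d,
    entropy = shannon_entropy(seq, wh),
    window_r = wr, window_k = wk, window_d = wd, window_h = wh
  )
}
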