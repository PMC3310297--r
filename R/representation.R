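new_complex_signal <- function(terms, alphabet = NULL, id = "",
                               imag_convention = "CT") {
  structure(terms, alphabet = alphabet, id = id,
            imag_convention = imag_convention, class = "complex_signal")
}

#' @export
print.complex_signal <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<complex_signal '%s': %d unit-modulus terms>\n",
              attr(x, "id") %||% "", n))
  print(head(unclass(x), 8L))
  if (n > 8L) cat("...\n")
  invisible(x)
}

#' Complex unit-root map of an alphabet
#'
#' Maps the `M` symbols of an alphabet (in their fixed order) onto the
#' `M`-th roots of unity: the symbol with index `j` goes to
#' `exp(2i * pi * (j - 1) / M)`. For nucleotides ordered A, C, G, T this
#' gives A -> 1, C -> i, G -> -1, T -> -i; for the 20-letter amino-acid
#' alphabet M -> 1, and so on around the unit circle.
#'
#' The imaginary-axis convention for nucleotides is configurable: the
#' default `"CT"` is the constructive assignment above (C on +i, T on -i);
#' `"TC"` conjugates the map (T on +i, C on -i), under which the walk
#' satisfies `Re(z) = a - g`, `Im(z) = t - c` in terms of running
#' nucleotide counts. The two conventions differ only by complex
#' conjugation of the signal.
#'
#' @param alphabet An [alphabet()].
#' @param imag_convention `"CT"` (default) or `"TC"`; only meaningful for
#'   the 4-letter nucleotide alphabet.
#' @return A named complex vector, one unit root per symbol.
#' @examples
#' root_map(nucleotide_alphabet())
#' root_map(amino_acid_alphabet())[["M"]]
#' @export
root_map <- function(alphabet, imag_convention = c("CT", "TC")) {
  imag_convention <- match.arg(imag_convention)
  m <- alphabet_size(alphabet)
  roots <- exp(2i * pi * (seq_len(m) - 1) / m)
  roots <- setNames(roots, unclass(alphabet))
  if (imag_convention == "TC") {
    if (!is_nucleotide_alphabet(alphabet)) {
      abort("`imag_convention = \"TC\"` applies to the nucleotide alphabet only.")
    }
    roots <- Conj(roots)
  }
  roots
}

#' Encode a sequence as a unit-root complex signal
#'
#' Replaces each token by its unit root under [root_map()], giving a
#' unit-modulus complex signal of the same length.
#'
#' @param seq A [symbol_seq()].
#' @param imag_convention Passed to [root_map()].
#' @return A `complex_signal`.
#' @examples
#' encode_roots(symbol_seq("ACGT"))
#' @export
encode_roots <- function(seq, imag_convention = c("CT", "TC")) {
  imag_convention <- match.arg(imag_convention)
  ab <- seq_alphabet(seq)
  rm_ <- root_map(ab, imag_convention = imag_convention)
  tokens <- unclass(seq)
  bad <- which(!tokens %in% names(rm_))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Token '%s' at position %d has no unit root (not in the alphabet).",
      tokens[bad[1L]], bad[1L]
    ))
  }
  new_complex_signal(unname(rm_[tokens]), alphabet = ab, id = seq_id(seq),
                     imag_convention = imag_convention)
}

#' Decode a complex signal back to symbols
#'
#' Nearest-root decoding: each term is assigned the alphabet symbol whose
#' unit root is closest. Exact on signals produced by [encode_roots()].
#'
#' @param signal A `complex_signal` carrying its alphabet.
#' @param alphabet Override alphabet (required if the signal has none).
#' @param imag_convention Passed to [root_map()].
#' @return A [symbol_seq()].
#' @export
decode_roots <- function(signal, alphabet = NULL,
                         imag_convention = c("CT", "TC")) {
  ab <- alphabet %||% attr(signal, "alphabet")
  if (is.null(ab)) abort("No alphabet available for decoding.")
  conv <- attr(signal, "imag_convention")
  imag_convention <-
    if (missing(imag_convention) && !is.null(conv)) conv
    else match.arg(imag_convention)
  rm_ <- root_map(ab, imag_convention = imag_convention)
  idx <- vapply(unclass(signal), function(z) {
    which.max(Re(Conj(rm_) * z))
  }, integer(1L))
  symbol_seq(names(rm_)[idx], alphabet = ab, id = attr(signal, "id") %||% "")
}

#' Indicator matrix of a symbolic sequence
#'
#' The N x N binary matrix with `u[h, k] = 1` exactly when the symbols at
#' positions `h` and `k` are equal. It is symmetric with unit diagonal and
#' its image is the dot plot (a special case of a recurrence plot):
#' periodicity shows as stripes parallel to the main diagonal, symbol
#' persistence as filled square islands. Works identically for nucleotide
#' and amino-acid (word) sequences.
#'
#' @param seq A [symbol_seq()].
#' @return An integer 0/1 matrix of class `indicator_matrix` with attribute
#'   `sequence_ref` (the sequence identifier).
#' @examples
#' indicator_matrix(symbol_seq("AGA"))
#' @export
indicator_matrix <- function(seq) {
  tokens <- unclass(seq)
  m <- outer(tokens, tokens, "==")
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  structure(m, sequence_ref = seq_id(seq),
            class = c("indicator_matrix", "matrix", "array"))
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("<indicator_matrix %dx%d of '%s': %d ones (density %.3f)>\n",
              nrow(x), ncol(x), attr(x, "sequence_ref") %||% "",
              sum(x), mean(x)))
  if (nrow(x) <= 12L) print(unclass(x)) else print(unclass(x)[1:12, 1:12])
  invisible(x)
}

#' Cumulative-sum walk of a signal
#'
#' The walk is the running sum `z[n] = y[1] + ... + y[n]` of a unit-root
#' signal: an all-A stretch marches along the positive real axis, a
#' balanced composition stays near the origin (the four nucleotide roots
#' sum to zero). When the input is (or encodes) a nucleotide sequence the
#' running counts of A, C, G, T are included, so the identities between
#' walk coordinates and count differences can be read off directly.
#'
#' @param x A [symbol_seq()] (encoded internally) or a `complex_signal`.
#' @param imag_convention Passed to [encode_roots()] when `x` is a
#'   sequence. Under `"TC"`, `Re(z) = a - g` and `Im(z) = t - c`; under the
#'   default `"CT"`, `Re(z) = a - g` and `Im(z) = c - t`.
#' @return A tibble of class `dna_walk` with columns `n`, `re`, `im`,
#'   `mod` and, for nucleotide sources, running counts `a`, `c`, `g`, `t`.
#' @examples
#' dna_walk(symbol_seq("ATGG"))
#' @export
dna_walk <- function(x, imag_convention = c("CT", "TC")) {
  imag_convention <- match.arg(imag_convention)
  counts <- NULL
  if (inherits(x, "symbol_seq")) {
    if (is_nucleotide_alphabet(seq_alphabet(x))) {
      tokens <- unclass(x)
      counts <- tibble(
        a = cumsum(tokens == "A"), c = cumsum(tokens == "C"),
        g = cumsum(tokens == "G"), t = cumsum(tokens == "T")
      )
    }
    x <- encode_roots(x, imag_convention = imag_convention)
  } else if (!inherits(x, "complex_signal")) {
    abort("`x` must be a symbol_seq or a complex_signal.")
  }
  if (length(x) == 0L) abort("Empty signal.")
  z <- cumsum(unclass(x))
  out <- tibble(n = seq_along(z), re = Re(z), im = Im(z), mod = Mod(z))
  if (!is.null(counts)) out <- dplyr::bind_cols(out, counts)
  structure(out, id = attr(x, "id") %||% "",
            imag_convention = attr(x, "imag_convention") %||% imag_convention,
            class = c("dna_walk", class(tibble())))
}

#' Nucleotide and group frequencies of a prefix
#'
#' Counts A, C, G, T over the first `h` positions and derives the ligand
#' group frequencies: purine \{A, G\}, pyrimidine \{C, T\}, amino \{A, C\},
#' keto \{G, T\}, weak hydrogen bonds \{A, T\} and strong \{G, C\}.
#'
#' @param seq A nucleotide [symbol_seq()].
#' @param h Prefix length, between 1 and `length(seq)`; defaults to the
#'   whole sequence.
#' @return A tibble with columns `set`, `count`, `freq` and constant `h`;
#'   the single-nucleotide rows always satisfy `sum(count) == h`.
#' @examples
#' group_frequencies(symbol_seq("ACGT"))
#' @export
group_frequencies <- function(seq, h = length(seq)) {
  if (!is_nucleotide_alphabet(seq_alphabet(seq))) {
    abort("`group_frequencies()` needs a nucleotide sequence.")
  }
  h <- as.integer(h)
  if (h < 1L || h > length(seq)) {
    abort(sprintf("`h` must lie in [1, %d].", length(seq)))
  }
  tokens <- unclass(seq)[seq_len(h)]
  cnt <- c(A = sum(tokens == "A"), C = sum(tokens == "C"),
           G = sum(tokens == "G"), T = sum(tokens == "T"))
  groups <- c(
    purine = cnt[["A"]] + cnt[["G"]], pyrimidine = cnt[["C"]] + cnt[["T"]],
    amino = cnt[["A"]] + cnt[["C"]], keto = cnt[["G"]] + cnt[["T"]],
    weak = cnt[["A"]] + cnt[["T"]], strong = cnt[["G"]] + cnt[["C"]]
  )
  all_counts <- c(cnt, groups)
  tibble(
    set = names(all_counts),
    count = as.integer(all_counts),
    freq = as.numeric(all_counts) / h,
    h = h
  )
}
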