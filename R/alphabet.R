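#' Symbol alphabets
#'
#' An alphabet is an ordered set of distinct tokens over which symbolic
#' sequences are defined. The order is significant: it fixes the index `j`
#' used by the complex unit-root map ([root_map()]), where the symbol with
#' index `j` is sent to `exp(2i * pi * (j - 1) / M)` for an `M`-symbol
#' alphabet. `word_length` records how many nucleotides each token stands
#' for (1 for plain nucleotides, 3 for codon-translated amino acids).
#'
#' @param symbols Character vector of distinct tokens, in a fixed order.
#' @param word_length Integer, the nucleotide length of each token.
#'
#' @return An object of class `sw_alphabet`: a character vector of symbols
#'   with attributes `word_length` and `cardinality`.
#'
#' @examples
#' nucleotide_alphabet()
#' amino_acid_alphabet()
#' @export
alphabet <- function(symbols, word_length = 1L) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) {
    abort("An alphabet needs at least one symbol.")
  }
  if (anyDuplicated(symbols)) {
    abort("Alphabet symbols must be distinct.")
  }
  word_length <- as.integer(word_length)
  if (word_length < 1L) {
    abort("`word_length` must be a positive integer.")
  }
  if (length(symbols) > 4L^word_length) {
    abort(sprintf(
      "An alphabet of %d-length words admits at most %d symbols, got %d.",
      word_length, 4L^word_length, length(symbols)
    ))
  }
  structure(
    symbols,
    word_length = word_length,
    cardinality = length(symbols),
    class = "sw_alphabet"
  )
}

#' @rdname alphabet
#' @export
nucleotide_alphabet <- function() {
  alphabet(c("A", "C", "G", "T"), word_length = 1L)
}

#' @rdname alphabet
#' @details
#' The amino-acid alphabet lists the 20 one-letter codes in the order
#' M, E, Q, D, R, T, N, H, V, G, L, S, P, F, I, C, A, K, Y, W, so that
#' methionine gets root index 1 (and root value 1).
#' @export
amino_acid_alphabet <- function() {
  alphabet(
    c("M", "E", "Q", "D", "R", "T", "N", "H", "V", "G",
      "L", "S", "P", "F", "I", "C", "A", "K", "Y", "W"),
    word_length = 3L
  )
}

#' @export
print.sw_alphabet <- function(x, ...) {
  cat(sprintf(
    "<alphabet: %d symbols, word length %d>\n%s\n",
    attr(x, "cardinality"), attr(x, "word_length"),
    paste(unclass(x), collapse = " ")
  ))
  invisible(x)
}

alphabet_size <- function(ab) attr(ab, "cardinality")

is_nucleotide_alphabet <- function(ab) {
  identical(as.vector(unclass(ab)), c("A", "C", "G", "T"))
}
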