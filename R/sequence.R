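#' Symbolic sequences
#'
#' A `symbol_seq` is a finite ordered sequence of tokens over a fixed
#' alphabet — a DNA sequence over \{A, C, G, T\} or a translated protein
#' sequence over the 20 one-letter amino-acid codes. It is the universal
#' input of the package: encodings, walks, indicator matrices, spiral
#' layouts and complexity indices all start from it.
#'
#' @param x Either a character vector of tokens or a single string (split
#'   into single characters when the alphabet has one-character tokens).
#' @param alphabet An [alphabet()]; defaults to the nucleotide alphabet.
#' @param id Free-text identifier carried along into results.
#' @param validate If `TRUE` (default), reject tokens outside the alphabet.
#'   Readers set this to `FALSE` so that [validate_nucleotides()] can apply
#'   an explicit policy afterwards.
#'
#' @return An object of class `symbol_seq`: a character vector of tokens
#'   with attributes `alphabet` and `id`.
#'
#' @examples
#' s <- symbol_seq("ACGTTGCA", id = "demo")
#' length(s)
#' @export
symbol_seq <- function(x, alphabet = nucleotide_alphabet(), id = "",
                       validate = TRUE) {
  if (length(x) == 1L && nchar(x) > 1L &&
      all(nchar(unclass(alphabet)) == 1L)) {
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  }
  x <- toupper(as.character(x))
  if (length(x) == 0L) {
    abort("A symbol sequence must contain at least one token.")
  }
  if (validate) {
    bad <- which(!x %in% unclass(alphabet))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Token(s) outside the alphabet at position(s) %s (first offender: %s).",
        paste(head(bad, 5L), collapse = ", "), x[bad[1L]]
      ))
    }
  }
  structure(x, alphabet = alphabet, id = as.character(id),
            class = "symbol_seq")
}

#' @export
print.symbol_seq <- function(x, ...) {
  n <- length(x)
  shown <- paste(head(unclass(x), 60L), collapse = "")
  if (n > 60L) shown <- paste0(shown, "...")
  cat(sprintf("<symbol_seq '%s': %d tokens over %d-symbol alphabet>\n%s\n",
              attr(x, "id"), n, alphabet_size(attr(x, "alphabet")), shown))
  invisible(x)
}

#' @export
`[.symbol_seq` <- function(x, i, ...) {
  structure(unclass(x)[i], alphabet = attr(x, "alphabet"),
            id = attr(x, "id"), class = "symbol_seq")
}

seq_alphabet <- function(x) attr(x, "alphabet")

seq_id <- function(x) attr(x, "id") %||% ""

#' Coerce a symbolic sequence to a tibble
#'
#' @param x A `symbol_seq`.
#' @param ... Unused.
#' @return A tibble with columns `n` (1-based position) and `symbol`.
#' @method as_tibble symbol_seq
#' @export
as_tibble.symbol_seq <- function(x, ...) {
  tibble(n = seq_along(x), symbol = unclass(x))
}
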