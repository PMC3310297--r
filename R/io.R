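#' Read sequences from FASTA
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file and returns one
#' [symbol_seq()] per record. Sequence characters are uppercased; the
#' identifier is taken from the header line. No alphabet validation is done
#' at read time — apply [validate_nucleotides()] with an explicit policy.
#'
#' @param path Path to a FASTA file.
#' @return A list of `symbol_seq` objects (nucleotide alphabet).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acgt"), f)
#' read_fasta(f)[[1]]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    abort(sprintf("No FASTA records in %s", path))
  }
  widths <- Biostrings::width(recs)
  if (any(widths == 0L)) {
    abort(sprintf("FASTA record '%s' has no sequence characters.",
                  names(recs)[which(widths == 0L)[1L]]))
  }
  ids <- sub("\\s.*$", "", names(recs))
  out <- purrr::map2(unname(as.character(recs)), ids, function(s, id) {
    symbol_seq(strsplit(toupper(s), "", fixed = TRUE)[[1]],
               alphabet = nucleotide_alphabet(), id = id, validate = FALSE)
  })
  setNames(out, ids)
}

#' Read one sequence from plain text
#'
#' Reads a plain-text sequence file (no header); all whitespace is ignored
#' and the characters are uppercased.
#'
#' @param path Path to a text file.
#' @param id Identifier to attach; defaults to the file name.
#' @return A `symbol_seq` (nucleotide alphabet, unvalidated).
#' @export
read_seq_txt <- function(path, id = basename(path)) {
  if (!file.exists(path)) {
    abort(sprintf("Sequence file not found: %s", path))
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\s+", "", txt)
  if (nchar(txt) == 0L) {
    abort(sprintf("No sequence characters in %s", path))
  }
  symbol_seq(strsplit(toupper(txt), "", fixed = TRUE)[[1]],
             alphabet = nucleotide_alphabet(), id = id, validate = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs A `symbol_seq` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "symbol_seq")) seqs <- list(seqs)
  strings <- vapply(seqs, function(s) paste(unclass(s), collapse = ""), "")
  ids <- vapply(seqs, seq_id, "")
  ids[ids == ""] <- paste0("seq", seq_along(ids))[ids == ""]
  set <- Biostrings::BStringSet(setNames(strings, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Validate a nucleotide sequence
#'
#' Checks every token against \{A, C, G, T\}. Ambiguity codes (N, R, Y, ...)
#' are never encoded silently: under `policy = "error"` the first offending
#' position is reported; under `policy = "drop"` offenders are removed with
#' a warning giving the count.
#'
#' @param seq A `symbol_seq`.
#' @param policy `"error"` (default) or `"drop"`.
#' @return A validated `symbol_seq` over the nucleotide alphabet.
#' @export
validate_nucleotides <- function(seq, policy = c("error", "drop")) {
  policy <- match.arg(policy)
  tokens <- unclass(seq)
  bad <- which(!tokens %in% c("A", "C", "G", "T"))
  if (length(bad) == 0L) {
    return(symbol_seq(tokens, alphabet = nucleotide_alphabet(),
                      id = seq_id(seq)))
  }
  if (policy == "error") {
    abort(sprintf(
      "Non-ACGT token '%s' at position %d (%d offending token(s) in total).",
      tokens[bad[1L]], bad[1L], length(bad)
    ))
  }
  warn(sprintf("Dropped %d non-ACGT token(s) from '%s'.",
               length(bad), seq_id(seq)))
  symbol_seq(tokens[-bad], alphabet = nucleotide_alphabet(),
             id = seq_id(seq))
}

#' The codon table
#'
#' Loads the packaged standard genetic code: 61 sense codons mapping to the
#' 20 one-letter amino-acid codes plus the three stop codons TAA, TAG, TGA.
#'
#' @return A tibble with columns `codon`, `aa` (one-letter code, `"*"` for
#'   stop) and `name`.
#' @export
codon_table <- function() {
  path <- system.file("extdata", "codon_table.tsv", package = "seqwave",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Translate codons to amino acids
#'
#' Translates a nucleotide sequence in reading frame 1 (no ORF scanning;
#' the trailing partial codon is discarded) into a sequence over the
#' 20-letter amino-acid alphabet. Stop codons are skipped by default or,
#' with `stop_policy = "symbol"`, emitted as the distinguished token `"*"`
#' (which has no unit root and is excluded from encodings).
#'
#' @param seq A nucleotide `symbol_seq`.
#' @param table Codon table as returned by [codon_table()].
#' @param stop_policy `"skip"` (default) or `"symbol"`.
#' @return A `symbol_seq` over [amino_acid_alphabet()] (with `"*"` tokens
#'   allowed under `stop_policy = "symbol"`).
#' @examples
#' translate_codons(symbol_seq("ATGCGTGAA"))
#' @export
translate_codons <- function(seq, table = codon_table(),
                             stop_policy = c("skip", "symbol")) {
  stop_policy <- match.arg(stop_policy)
  tokens <- unclass(seq)
  if (length(tokens) < 3L) {
    abort("Sequence shorter than one codon (3 nucleotides).")
  }
  n_codon <- length(tokens) %/% 3L
  codons <- vapply(seq_len(n_codon), function(i) {
    paste(tokens[(3L * i - 2L):(3L * i)], collapse = "")
  }, "")
  map <- setNames(table$aa, table$codon)
  aa <- unname(map[codons])
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    abort(sprintf("Unknown codon '%s' at codon position %d.",
                  codons[bad], bad))
  }
  if (stop_policy == "skip") {
    aa <- aa[aa != "*"]
    if (length(aa) == 0L) {
      abort("Translation is empty after skipping stop codons.")
    }
  }
  symbol_seq(aa, alphabet = amino_acid_alphabet(), id = seq_id(seq),
             validate = FALSE)
}
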