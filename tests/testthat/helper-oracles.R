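# Independent oracles used across the suite. Each re-derives its quantity
# by a different route than the package implementation.

# Haar matrix built by sampling the scaling/wavelet step functions on the
# dyadic grid (phi constant; psi = -1 on the earlier half-interval, +1 on
# the later, L2-normalized) — independent of the package's block-fill
# construction.
oracle_haar <- function(n) {
  m <- as.integer(round(log2(n)))
  grid <- (seq_len(n) - 0.5) / n
  rows <- matrix(1 / sqrt(n), nrow = 1L, ncol = n)
  for (lev in 0:(m - 1L)) {
    for (k in 0:(2L^lev - 1L)) {
      lo <- k / 2^lev; mid <- (k + 0.5) / 2^lev; hi <- (k + 1) / 2^lev
      psi <- ifelse(grid >= lo & grid < mid, -1,
                    ifelse(grid >= mid & grid < hi, 1, 0))
      rows <- rbind(rows, 2^(lev / 2) * psi / sqrt(n))
    }
  }
  unname(rows)
}

# All attainable coefficient pairs for p-length windows of 4th-root
# signals, by exhaustive enumeration over the 4^p window types. Returns a
# list (one element per coefficient row) of matrices with distinct
# (real-channel, imag-channel) rows.
oracle_cluster_support <- function(p, digits = 10L) {
  roots <- c(1 + 0i, 0 + 1i, -1 + 0i, 0 - 1i)
  idx <- as.matrix(expand.grid(rep(list(1:4), p)))
  windows <- matrix(roots[idx], nrow = nrow(idx))  # one window per row
  w <- oracle_haar(p)
  cr <- Re(windows) %*% t(w)
  ci <- Im(windows) %*% t(w)
  lapply(seq_len(p), function(j) {
    unique(round(cbind(re = cr[, j], im = ci[, j]), digits))
  })
}

# Mean ones-count over all contiguous n x n minors, by direct double loop.
oracle_mean_minor_ones <- function(mat, n) {
  k <- nrow(mat) - n + 1L
  tot <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      tot <- tot + sum(mat[i:(i + n - 1L), j:(j + n - 1L)])
    }
  }
  tot / k^2
}

# Canonical string form of a distinct-point set, for set equality checks.
point_set_key <- function(m) {
  sort(paste(m[, 1], m[, 2], sep = ","))
}

# The standard genetic code, frozen independently of the packaged TSV
# (keyed codon -> one-letter code, "*" = stop).
oracle_genetic_code <- c(
  ATG = "M",
  GAA = "E", GAG = "E", CAA = "Q", CAG = "Q", GAT = "D", GAC = "D",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R", AGA = "R", AGG = "R",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N",
  CAT = "H", CAC = "H", GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G",
  TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S", AGT = "S", AGC = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P", TTT = "F", TTC = "F",
  ATT = "I", ATC = "I", ATA = "I", TGT = "C", TGC = "C",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", AAA = "K", AAG = "K",
  TAT = "Y", TAC = "Y", TGG = "W",
  TAA = "*", TAG = "*", TGA = "*"
)

# Strip seqwave classes/attributes for plain-value comparisons (keeps dim).
bare <- function(x) {
  x <- unclass(x)
  for (at in c("alphabet", "id", "imag_convention", "sequence_ref",
               "word_length", "cardinality", "window", "n_segments")) {
    attr(x, at) <- NULL
  }
  x
}
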