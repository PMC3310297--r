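test_that("unit-root maps place symbols on the unit circle in order", {
  rm4 <- root_map(nucleotide_alphabet())
  expect_equal(rm4[["A"]], 1 + 0i)
  expect_equal(rm4[["C"]], 0 + 1i)
  expect_equal(rm4[["G"]], -1 + 0i)
  expect_equal(rm4[["T"]], 0 - 1i)
  rm20 <- root_map(amino_acid_alphabet())
  expect_equal(rm20[["M"]], 1 + 0i)
  expect_equal(Mod(rm20), rep(1, 20), ignore_attr = TRUE)
  # TC convention conjugates the nucleotide map
  rmTC <- root_map(nucleotide_alphabet(), imag_convention = "TC")
  expect_equal(rmTC[["T"]], 0 + 1i)
  expect_equal(rmTC[["C"]], 0 - 1i)
  expect_error(root_map(amino_acid_alphabet(), imag_convention = "TC"),
               "nucleotide")
})

test_that("encoding maps tokens to roots and decoding inverts it", {
  expect_equal(bare(encode_roots(symbol_seq("ACGT"))),
               c(1 + 0i, 0 + 1i, -1 + 0i, 0 - 1i))
  expect_equal(bare(encode_roots(symbol_seq("AAAA"))), rep(1 + 0i, 4))
  expect_equal(bare(encode_roots(symbol_seq("ATGG"))),
               c(1 + 0i, 0 - 1i, -1 + 0i, -1 + 0i))
  # stop tokens have no root
  tr <- translate_codons(symbol_seq("ATGTAAATG"), stop_policy = "symbol")
  expect_error(encode_roots(tr), "no unit root")

  for (seed in 1:5) {
    s <- pseudorandom_sequence(200, seed = seed)
    expect_identical(bare(decode_roots(encode_roots(s))), bare(s))
    sTC <- encode_roots(s, imag_convention = "TC")
    expect_identical(bare(decode_roots(sTC)), bare(s))
    aa <- translate_codons(s)
    expect_identical(bare(decode_roots(encode_roots(aa))), bare(aa))
  }
})

test_that("indicator matrices are binary, symmetric, unit-diagonal", {
  expect_identical(bare(indicator_matrix(symbol_seq("AGA"))),
                   matrix(c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L), 3L))
  expect_identical(bare(indicator_matrix(symbol_seq("AAAA"))),
                   matrix(1L, 4L, 4L))
  for (seed in 1:5) {
    s <- pseudorandom_sequence(80, seed = seed)
    u <- bare(indicator_matrix(s))
    expect_identical(u, t(u))
    expect_identical(diag(u), rep(1L, 80L))
    expect_true(all(u %in% c(0L, 1L)))
  }
  # amino-acid (word) sequences work identically
  ua <- bare(indicator_matrix(translate_codons(pseudorandom_sequence(300, seed = 6))))
  expect_identical(ua, t(ua))
  expect_true(all(diag(ua) == 1L))
})

test_that("pseudoperiodic indicator matrices stripe at the period lag", {
  for (period in c(4L, 7L)) {
    s <- pseudoperiodic_sequence(70, period = period, seed = period)
    u <- bare(indicator_matrix(s))
    h <- seq_len(length(s) - period)
    expect_true(all(u[cbind(h, h + period)] == 1L))
  }
})

test_that("walks are cumulative sums tied to running counts", {
  w <- dna_walk(symbol_seq("ATGG"))
  expect_equal(complex(real = w$re, imaginary = w$im),
               c(1 + 0i, 1 - 1i, 0 - 1i, -1 - 1i))
  expect_equal(dna_walk(symbol_seq("ACGT"))$mod[4], 0)  # roots sum to zero
  wA <- dna_walk(symbol_seq(strrep("A", 9)))
  expect_equal(wA$re, 1:9)
  expect_equal(wA$im, rep(0, 9))

  for (seed in 1:5) {
    s <- pseudorandom_sequence(300, seed = seed)
    tok <- bare(s)
    a <- cumsum(tok == "A"); c_ <- cumsum(tok == "C")
    g <- cumsum(tok == "G"); t_ <- cumsum(tok == "T")
    expect_equal(a + c_ + g + t_, 1:300)
    # count-difference identities under both conventions
    wTC <- dna_walk(s, imag_convention = "TC")
    expect_equal(wTC$re, a - g)
    expect_equal(wTC$im, t_ - c_)
    wCT <- dna_walk(s)
    expect_equal(wCT$re, a - g)
    expect_equal(wCT$im, c_ - t_)
    expect_identical(wCT$a, a)
    expect_identical(wCT$t, t_)
  }
})

test_that("group frequencies count prefixes and ligand groups", {
  gf <- group_frequencies(symbol_seq("ACGT"), h = 4)
  counts <- setNames(gf$count, gf$set)
  expect_identical(counts[c("A", "C", "G", "T")],
                   c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(gf$freq[gf$set == "weak"], 0.5)
  expect_equal(gf$freq[gf$set == "strong"], 0.5)

  gfA <- group_frequencies(symbol_seq("AAAA"), h = 4)
  expect_equal(gfA$freq[gfA$set == "A"], 1)
  expect_equal(sum(gfA$count[gfA$set %in% c("C", "G", "T")]), 0L)

  for (seed in 1:5) {
    s <- pseudorandom_sequence(50, seed = seed)
    h <- 10L + seed
    gfr <- group_frequencies(s, h = h)
    base <- gfr$count[gfr$set %in% c("A", "C", "G", "T")]
    expect_identical(sum(base), h)
    for (pair in list(c("purine", "pyrimidine"), c("amino", "keto"),
                      c("weak", "strong"))) {
      expect_identical(sum(gfr$count[gfr$set %in% pair]), h)
    }
  }
  expect_error(group_frequencies(symbol_seq("ACGT"), h = 5), "lie in")
})
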