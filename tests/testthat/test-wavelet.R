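test_that("Haar matrices are orthonormal and match the step-function oracle", {
  expect_equal(bare(haar_matrix(2)),
               matrix(c(1, -1, 1, 1) / sqrt(2), 2L), ignore_attr = TRUE)
  w4 <- bare(haar_matrix(4))
  expect_equal(w4, rbind(
    c(1, 1, 1, 1) / 2,
    c(-1, -1, 1, 1) / 2,
    c(-1, 1, 0, 0) / sqrt(2),
    c(0, 0, -1, 1) / sqrt(2)
  ), ignore_attr = TRUE)
  for (n in c(2L, 4L, 8L, 16L, 32L)) {
    w <- bare(haar_matrix(n))
    expect_lt(max(abs(w %*% t(w) - diag(n))), 1e-12)
    expect_equal(w, oracle_haar(n), ignore_attr = TRUE)
    expect_equal(w[1L, ], rep(1 / sqrt(n), n))
  }
  expect_error(haar_matrix(6), "power of two")
  expect_error(haar_matrix(1), "power of two")
})

test_that("the four-point transform reproduces the worked coefficients", {
  # window (1, i, -1, -i): both channels give beta_0^0 = -1
  r <- short_haar(encode_roots(symbol_seq("ACGT")), p = 4)
  expect_identical(r$n_segments, 1L)
  expect_equal(r$coeffs_real[1, "beta_0^0"], -1, ignore_attr = TRUE)
  expect_equal(r$coeffs_imag[1, "beta_0^0"], -1, ignore_attr = TRUE)
  expect_equal(r$coeffs_real[1, "alpha"], 0, ignore_attr = TRUE)

  # constant windows have vanishing details in both conventions
  const <- encode_roots(symbol_seq("AAAAAAAA"))
  for (conv in c("orthonormal", "eq57_average")) {
    rc <- short_haar(const, p = 4, convention = conv)
    expect_equal(max(abs(rc$coeffs_real[, -1])), 0)
    expect_equal(max(abs(rc$coeffs_imag[, -1])), 0)
  }
  # eq57 average: first coefficient is the plain window mean
  ra <- short_haar(encode_roots(symbol_seq("AACG")), p = 4,
                   convention = "eq57_average")
  expect_equal(ra$coeffs_real[1, "alpha"], mean(c(1, 1, -1, 0)),
               ignore_attr = TRUE)

  expect_identical(short_haar(random_unit_complex(4000, seed = 1))$n_segments,
                   1000L)
  expect_error(short_haar(random_unit_complex(8, seed = 1), p = 5), "one of")
  expect_error(short_haar(random_unit_complex(3, seed = 1), p = 4),
               "shorter")
})

test_that("windowed transform equals direct Haar-matrix multiplication", {
  for (p in c(4L, 8L)) {
    sig <- random_unit_complex(40 * p, seed = p)
    r <- short_haar(sig, p = p)
    w <- oracle_haar(p)
    for (s in seq_len(r$n_segments)) {
      win <- bare(sig)[((s - 1L) * p + 1L):(s * p)]
      expect_equal(unname(r$coeffs_real[s, ]), as.vector(w %*% Re(win)))
      expect_equal(unname(r$coeffs_imag[s, ]), as.vector(w %*% Im(win)))
    }
  }
})

test_that("the orthonormal transform conserves energy and inverts exactly", {
  sig <- random_unit_complex(4001, seed = 17)
  r <- short_haar(sig, p = 4)
  seg <- matrix(bare(sig)[1:4000], nrow = 4)
  expect_lt(max(abs(rowSums(r$coeffs_real^2) + rowSums(r$coeffs_imag^2) -
                      colSums(Mod(seg)^2))), 1e-12)
  back <- inverse_short_haar(r)
  expect_lt(max(Mod(bare(back) - bare(sig)[1:4000])), 1e-10)
  expect_length(back, 4000L)

  # walks round-trip too, and so does the rescaled eq57 convention
  wk <- dna_walk(pseudorandom_sequence(160, seed = 18))
  r8 <- short_haar(wk, p = 8)
  z <- complex(real = wk$re, imaginary = wk$im)
  expect_lt(max(Mod(bare(inverse_short_haar(r8)) - z)), 1e-10)
  ra <- short_haar(sig, p = 4, convention = "eq57_average")
  expect_lt(max(Mod(bare(inverse_short_haar(ra)) -
                      bare(sig)[1:4000])), 1e-10)
})

test_that("coefficient clusters count distinct pairs per coefficient", {
  sig <- random_unit_complex(400, seed = 23)
  r <- short_haar(sig, p = 4)
  cl <- coefficient_clusters(r)
  sums <- tapply(cl$count, cl$coefficient, sum)
  expect_true(all(sums == r$n_segments))

  const <- short_haar(encode_roots(symbol_seq(strrep("G", 40))), p = 4)
  ccl <- coefficient_clusters(const)
  details <- ccl[ccl$coefficient != "alpha", ]
  expect_identical(nrow(details), 3L)
  expect_true(all(details$re == 0 & details$im == 0))
})

test_that("detail clusters of root signals live in small finite sets", {
  sig <- random_unit_complex(2000, seed = 29)
  cl <- coefficient_clusters(short_haar(sig, p = 4))
  # beta_1^1 real-channel values are scaled differences of {1, 0, -1}
  b11 <- cl[cl$coefficient == "beta_1^1", ]
  allowed <- c(0, 1, -1, 2, -2) / sqrt(2)
  expect_true(all(vapply(b11$re, function(v) any(abs(v - allowed) < 1e-9),
                         TRUE)))
  # beta_0^1 channel pairs: at most 25 distinct points
  expect_lte(nrow(cl[cl$coefficient == "beta_0^1", ]), 25L)
})

test_that("observed p=4 clusters equal the exhaustively enumerated support", {
  support <- oracle_cluster_support(4L)
  sig <- random_unit_complex(16384, seed = 37)
  cl <- coefficient_clusters(short_haar(sig, p = 4))
  labels <- c("alpha", "beta_0^0", "beta_0^1", "beta_1^1")
  for (j in seq_along(labels)) {
    obs <- cl[cl$coefficient == labels[j], c("re", "im")]
    expect_identical(point_set_key(as.matrix(obs)),
                     point_set_key(support[[j]]))
  }
})

test_that("attainable detail values grow with the window length", {
  count_detail_values <- function(p) {
    support <- oracle_cluster_support(p)
    pts <- do.call(rbind, support[-1L])  # all detail coefficients pooled
    nrow(unique(pts))
  }
  expect_gte(count_detail_values(8L), count_detail_values(4L))
})
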