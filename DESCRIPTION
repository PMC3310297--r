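Package: seqwave
Title: Unit-Root Encoding, Complexity Indices and Short Haar Wavelet
    Analysis of Symbolic Biological Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the numerical analysis of symbolic biological
    sequences (nucleotides and codon-translated amino acids). Sequences are
    mapped onto the complex roots of unity, giving unit-modulus signals whose
    cumulative sums are DNA walks. The package computes indicator-matrix dot
    plots, rectangular-spiral (Ulam-style) layouts of per-nucleotide
    distributions, four scalar complexity indices (a frequency-spread
    randomness index, the per-symbol log-multinomial complexity, a
    box-counting fractal dimension of the dot plot, and normalized Shannon
    entropy), and short (windowed) Haar wavelet transforms of encoded signals
    and walks together with cluster analysis of the coefficient pairs.
    Pseudorandom and pseudoperiodic control generators are included. Results
    are returned as tibbles with broom-style tidiers and ggplot2 autoplot
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
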