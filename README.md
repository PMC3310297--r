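# seqwave

Numerical analysis of symbolic biological sequences: complex unit-root
encoding, dot plots, spiral layouts, DNA walks, complexity indices, and
short Haar wavelet cluster analysis.

## The problem

A DNA sequence is a symbolic series over the alphabet {A, C, G, T} (or,
after codon translation, over the 20 one-letter amino-acid codes). At
first glance the nucleotides of most genomes — including those of
extremophile archaea — look randomly distributed: their dot plots and
walks resemble those of uniform random sequences. `seqwave` implements
the analysis stack that makes the difference measurable:

- **Unit-root encoding.** An ordered M-symbol alphabet is mapped onto
  the M-th roots of unity, ρ(x_j) = exp(2πi(j−1)/M). For A, C, G, T
  this gives 1, i, −1, −i; every encoded signal has unit modulus.
- **DNA walk.** The cumulative sum z_n = Σ_{k≤n} y_k of the encoded
  signal. Its real and imaginary parts are differences of running
  nucleotide counts (e.g. Re z = a_n − g_n).
- **Indicator matrix / dot plot.** u_hk = 1 iff x_h = x_k: a binary,
  symmetric, unit-diagonal N×N matrix — a recurrence plot in which
  periodicity shows as diagonal stripes.
- **Rectangular spiral layout.** An Ulam-style arrangement of the
  sequence on the integer lattice, one panel per nucleotide, for
  visualising compositional structure (e.g. weak {A,T} vs strong {G,C}
  hydrogen-bond content).
- **Complexity indices.** Randomness ℛ = 1 − σ(v_A, v_C, v_G, v_T)
  (σ a spread statistic of prefix frequencies); multinomial complexity
  K = (1/n)·ln(n!/(a_n! c_n! g_n! t_n!)); a box-counting fractal
  dimension D of the dot plot; and normalized Shannon entropy
  H = −(1/ln M)·Σ p_x ln p_x.
- **Short Haar wavelet transform.** The p-point orthonormal Haar
  transform (p = 4, 8, 16, 32) applied to consecutive non-overlapping
  windows of the signal or walk, real and imaginary channels
  separately. For unit-root signals at p = 4, every detail coefficient
  can only take a handful of values, so the (real-channel,
  imaginary-channel) coefficient pairs fall into small, symmetric,
  finite clusters — a sharp structural signature that washes out as the
  window grows.

Pseudorandom and pseudoperiodic control generators (seeded and
reproducible) provide the reference points for all of these.

## Worked example

```r
library(seqwave)
library(dplyr)

seqs <- list(
  pseudorandom_sequence(10000, seed = 1),
  pseudoperiodic_sequence(10000, period = 4, seed = 2)
)
purrr::map2(seqs, 10:11, ~complexity_report(.x, seed = .y)) |>
  purrr::list_rbind() |>
  select(id, randomness, complexity_k, fractal_dimension, entropy)
#> # A tibble: 2 × 5
#>   id                       randomness complexity_k fractal_dimension entropy
#>   <chr>                         <dbl>        <dbl>             <dbl>   <dbl>
#> 1 pseudorandom_n10000           1.000        1.30               1.50   0.989
#> 2 pseudoperiodic_n10000_p4      0.969        0.993              1.63   0.75
```

The pseudorandom control sits at the disorder extreme: randomness
essentially 1 (equal prefix frequencies), K near its four-letter
maximum of ln(4) ≈ 1.386 nats/symbol (1.30 at the default 100-symbol
window), entropy near 1. The period-4 control carries the same four
symbols in a rigid repeat, so its composition-based indices drop.

The wavelet clusters show the discreteness of unit-root coefficients:

```r
cl <- coefficient_clusters(short_haar(encode_roots(seqs[[1]]), p = 4))
count(as_tibble(cl), coefficient)
#> # A tibble: 4 × 2
#>   coefficient     n
#>   <fct>       <int>
#> 1 alpha          25
#> 2 beta_0^0       25
#> 3 beta_0^1        9
#> 4 beta_1^1        9
```

Across 2500 windows of a 10000-symbol random signal, each detail
coefficient visits only 9–25 distinct (real, imaginary) channel pairs —
exactly the sets obtained by enumerating all 4^4 possible windows.
`autoplot(cl)` draws the cluster panels; `autoplot(dna_walk(s))`,
`autoplot(indicator_matrix(s))` and `autoplot(spiral_layout(s))` draw
the walk, dot-plot and spiral views.

A thin command-line wrapper over these functions is installed at
`inst/scripts/seqwave-cli.R` (subcommands `generate`, `complexity`,
`report`).

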