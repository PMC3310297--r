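---
title: "Methods: unit-root encodings, complexity indices and short Haar clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unit-root encodings, complexity indices and short Haar clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, which
conventions it fixes where more than one reading is defensible, and what
its tests do and do not establish.

## Sequences, alphabets and the unit-root encoding

A `symbol_seq` is an ordered finite sequence over an `alphabet` — the
nucleotides A, C, G, T, or the 20 one-letter amino-acid codes obtained
by frame-1 codon translation. The alphabet's **order matters**: the
symbol with index $j$ in an $M$-symbol alphabet is encoded as the unit
root

$$\rho(x_j) = e^{2\pi i (j-1)/M},$$

so A, C, G, T map to $1, i, -1, -i$ and M (methionine, index 1 of the
amino-acid alphabet) maps to 1. Every encoded signal lies on the unit
circle, which makes windows of different sequences directly comparable
and gives the wavelet coefficients their finite value sets (below).

Two conventions exist in the field for which pyrimidine sits on $+i$.
The constructive order A, C, G, T puts C on $+i$ and T on $-i$, making
the walk satisfy $\mathrm{Im}\,z_n = c_n - t_n$; the conjugate
convention (flag `imag_convention = "TC"`) puts T on $+i$, giving
$\mathrm{Im}\,z_n = t_n - c_n$. The two differ only by complex
conjugation of the signal, so all modulus-based and cluster-geometry
results are identical; we default to `"CT"` (the constructive order)
and expose the flag because both identities appear in the literature.

Translation choices: reading frame 1 of the given strand, no ORF
scanning, trailing partial codon discarded. Stop codons are not amino
acids and have no unit root, so the default skips them;
`stop_policy = "symbol"` keeps them as a distinguished `"*"` token for
counting purposes, and encoding such a sequence is an error by design.
Ambiguity codes (N, R, Y, ...) are never encoded silently: validation
policies are `error` (default) and `drop` (with a reported count),
because a silently mis-encoded token corrupts the unit-root signal.

## The control generators

`pseudorandom_sequence()` draws each symbol i.i.d. uniformly from the
alphabet; `pseudoperiodic_sequence()` draws one random block of length
$\pi$ and tiles it, so $x_i = x_{i+\pi}$ exactly, trimming the length
down to a multiple of $\pi$. These emulate the two idealised extremes a
genomic sequence is compared against: maximal disorder and rigid
repetition. They do **not** emulate real genomic features — no GC bias,
no codon usage, no short-range Markov dependence, no repeat families —
so a test passing on the controls shows the machinery is correct at the
extremes, not that real genomes behave like either control.

Taken literally, the tiling construction with $\pi = 1$ repeats a
1-block: a **constant** sequence. (A natural alternative reading would
treat $\pi = 1$ as "no constraint", i.e. fully random; we implement the
literal construction and document it loudly.) `random_unit_complex()`
draws $(-1)^r i^s$ with $r$ uniform on $\{0,1\}$ and $s$ uniform on
$\{0,1,2,3\}$ — the minimal distribution making the terms uniform on
the 4th roots of unity with unit modulus.

All generators take an integer `seed`; seeded calls restore the
caller's RNG state, and every stochastic component in the package
(generation, minor sampling) is seeded from a single run seed where
orchestration is involved.

## Complexity indices

All four indices are computed on a prefix ("window") of the sequence.

- **Randomness** $\mathcal{R} = 1 - \sigma(v_A, v_C, v_G, v_T)$ with
  $v_x$ the prefix frequencies. $\sigma$ is the **population variance**
  by default (the literal reading of "variance"); the population
  standard deviation is available via `spread = "std"`. On uniform
  frequencies both give $\mathcal{R} = 1$. The variance of four
  frequencies is tiny for near-uniform compositions, so on a
  10000-symbol random prefix $\mathcal{R}$ is indistinguishable from 1
  at three decimals. Default window: 10000 symbols.
- **Multinomial complexity**
  $K = \frac1n \ln \binom{n}{a_n,\,c_n,\,g_n,\,t_n}$ in nats per
  symbol, computed through `lgamma` so any window size is exact in
  floating point. The natural logarithm is the only base consistent
  with the near-maximal value ($\ln(100!/(25!)^4)/100 \approx 1.317$)
  that uniform sequences attain at the default 100-symbol window;
  base-10 or base-4 would cap $K$ far lower.
- **Normalized Shannon entropy**
  $H = -\frac{1}{\ln M}\sum_x p_x \ln p_x$ with $0\ln 0 := 0$.
  Normalizing by the alphabet **cardinality** $M$ (not the word length)
  is the only choice that makes $H \in [0,1]$ for every alphabet,
  including single-character ones. For uniform sequences
  $K \to H\ln 4$ as the window grows (Stirling); the suite asserts
  $|K - H\ln 4| < 0.05$ at $n = 10^4$.
- **Box-counting fractal dimension** of the dot plot. For each minor
  size $n$ in `n_range`, $p(n)$ is the mean count of ones over
  `minors_per_size` uniformly sampled contiguous $n \times n$ minors of
  the indicator matrix (or over all minors with `exhaustive = TRUE`;
  counting is $O(1)$ per minor via a summed-area table). The default
  summary is the mean of $\log p(n)/\log n$ over the range, which is
  exactly 2 for a saturated plot; `normalization = "sum_half"` divides
  the plain sum by $2N$ instead. Minor sizes with $p(n) = 0$ are
  skipped with a warning rather than propagating $-\infty$. Defaults:
  `n_range = 2:floor(N/2)`, 100 minors per size, dot plot of the first
  100 symbols.

### A caution on the fractal dimension of periodic dot plots

This estimator is a **mass** estimator: $p(n)$ grows with the ones
density of the plot. A period-$\pi$ sequence's indicator matrix has
density $\tfrac14 + \tfrac34 P(h \equiv k \bmod \pi) \ge \tfrac14$ —
periodic dot plots are strictly denser than random ones (the stripes
come on top of the random background). Consequently every term
$\log p(n)/\log n$, and hence $D$ under any count-of-ones protocol and
either normalization, is systematically *larger* for a pseudoperiodic
control than for a pseudorandom one; for $\pi = 2$ the gap is large
(density $\ge 1/2$ vs $1/4$). The intuition that periodic (line-like)
plots should score a *lower* dimension than random (area-filling) ones
requires an occupancy-at-scale estimator over a sparse support, not a
mass estimator over a constant-density plot; with this estimator the
reverse ordering is a mathematical consequence, not a sampling
artifact. The acceptance suite states the random-above-periodic
expectation and records its failure; we did not adjust the estimator or
the generator to mask this.

## Short Haar wavelet transform and coefficient clusters

`haar_matrix(p)` builds the orthonormal $p \times p$ Haar matrix
($p = 2^M$): a constant scaling row $p^{-1/2}$ and detail rows that are
$-1/\sqrt{L}$ on the earlier half and $+1/\sqrt{L}$ on the later half
of their support block. The "later minus earlier" sign is applied at
**every** level for internal consistency (printed four-point formulas
in the literature occasionally flip the sign of the finest level; the
cluster geometry is invariant under that flip, since window reversal
negates any detail coefficient). Orthonormality is asserted to
$10^{-12}$.

`short_haar()` cuts the signal (an encoded sequence, a walk series, or
any complex vector) into non-overlapping, left-aligned windows of
length $p \in \{4, 8, 16, 32\}$, discards the trailing remainder, and
transforms the real and imaginary channels independently (the matrix is
real, so this equals the complex-linear transform). The default
`orthonormal` convention conserves energy per window and inverts
exactly (`inverse_short_haar()`, round-trip asserted to $10^{-10}$);
`eq57_average` replaces the first coefficient by the plain window mean
— a scaling many authors use because it reads as "the average of the
window" — and since the convention is stored, inversion rescales and
remains exact.

`coefficient_clusters()` tabulates, per coefficient, the distinct
(real-channel, imaginary-channel) pairs across windows, with
multiplicities (rounded to 10 digits before grouping so floating-point
ties collapse; the attainable values are sums of roots scaled by powers
of $2^{-1/2}$, separated by far more than $10^{-10}$). For 4th-root
signals at $p = 4$ the attainable sets are finite and small —
enumerating all $4^4$ windows gives 25 points for $\alpha$ and
$\beta_0^0$ and 9 for $\beta_0^1$ and $\beta_1^1$ — and the suite
checks that the observed clusters on a long random signal coincide
exactly with the enumerated support. The attainable detail sets grow
with $p$ (checked by enumeration at $p = 8$), which is the quantitative
form of "the discreteness washes out on longer windows".

## Spiral layout

Indices $1, 2, 3, \dots$ are placed on a counterclockwise rectangular
spiral from the origin with arm lengths $1, 1, 2, 2, 3, 3, \dots$ and
directions cycling $+x, +y, -x, -y$; the first eleven points are
$(0,0), (1,0), (1,1), (0,1), (-1,1), (-1,0), (-1,-1), (0,-1), (1,-1),
(2,-1), (2,0)$. Only these eleven points are fixed by convention in the
literature we follow; the arm-length/direction rule above is the unique
continuation of the pattern they establish. The map is injective
(asserted for $n \le 10^4$) with unit axis steps, and `spiral_index()`
inverts it by construction.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on generated
inputs at sizes chosen to make sampling error negligible relative to
the tolerances while keeping runs fast: 200 seeds of 100-symbol
sequences for the stochastic index means, $10^4$ symbols for
randomness/entropy asymptotics and spiral injectivity, $16384$-term
signals (4096 windows) for cluster-support equality — long enough that
every one of the 256 window types is observed with near certainty —
and 30 seed pairs for ordering comparisons. All stochastic steps take
explicit seeds, so every reported number is reproducible bit-for-bit.

## Known limitations

- The indicator matrix is dense ($O(N^2)$ memory); dot-plot analyses
  are intended for windows of $10^2$–$10^4$ symbols, not whole genomes.
- The box-counting estimator measures mass scaling of a constant-density
  plot (see the caution above); it is comparable across sequences only
  at identical `n_range`, `minors_per_size` and normalization.
- The controls are compositional idealisations; no Markov or
  repeat-family generators are provided.
- Translation is frame-1 only; no reverse-complement or six-frame
  scanning.
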