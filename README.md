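# lrcseq

Long-range correlation analysis of symbolic sequences — word streams,
transcripts, and generative-model output — by rare-word interval
autocorrelation, together with the generative models that explain where
the correlation comes from.

## What it measures and for whom

A sequence is *long-range correlated* (LRC) when its autocorrelation
function decays as a power law rather than exponentially. Natural
language shows this property robustly: rare words cluster at all scales.
`lrcseq` is for quantitative linguists, cognitive scientists and
complex-systems researchers who want to (a) measure this on their own
corpora and (b) compare it against the standard generative models of
vocabulary growth.

The measurement pipeline: designate the rarest `1/N` of word occurrences
as extreme events (default `N = 16`), record the gaps
`r_1, ..., r_{M_N}` between successive events (`M_N ≈ M/N − 1`), and
compute

```
C(s) = 1/((M_N − s) σ²) · Σ_{i=1}^{M_N−s} (r_i − μ)(r_{i+s} − μ)
```

with μ, σ the gap mean and standard deviation. Long-range correlation
means `C(s) ∝ s^(−γ)`; γ (fitted by least squares in log-log
coordinates) is the headline statistic, reported with its slope standard
error `erb` and per-point residual `err`. The companion scaling laws are
Zipf's law `F(u) ∝ u^(−ξ)` for rank-frequency and Heaps' law
`V(m) ∝ m^ζ` for vocabulary growth.

Three generative models are implemented exactly, plus null baselines
(i.i.d. Zipf streams, word shuffling, bigram Markov chains):

* **Simon** — new type with constant probability α, else a uniform draw
  from the entire history. LRC, but vocabulary grows linearly (ζ = 1).
* **Pitman-Yor** — new type with probability `(aK+b)/(t+b)`, reuse with
  `(S_i−a)/(t+b)`. Realistic vocabulary growth (ζ ≈ a for small b), but
  no LRC.
* **conjunct** — Pitman-Yor's innovation rate with Simon's uniform
  reuse: both realistic growth and LRC.

## Worked example

Generate a million-token Simon sequence, analyze it, and compare with
its own shuffled null:

```r
library(lrcseq)

seq <- simon_generate(alpha = 0.1, M = 1e6, seed = 42)
analyze_sequence(seq, N = 16)
#> <lrc_analysis> N = 16, M_N = 62500 intervals
#>   gamma = 0.1503 (erb = 0.01018, err = 0.002549)
#>   long-range correlated: TRUE

rank_frequency(seq)
#> <rank_frequency> 100334 types, 1000000 tokens; xi = 0.9784 (err = 0.005596)
type_token_curve(seq)
#> <type_token_curve> V(M) = 100334 types at M = 1000000; zeta = 1.0193

analyze_sequence(shuffle_tokens(seq, seed = 43), N = 16)
#> <lrc_analysis> N = 16, M_N = 62500 intervals
#>   gamma = 0.2369 (erb = 0.1947, err = 0.4297)
#>   long-range correlated: FALSE
```

Reading the numbers: the Simon sequence has a clean interval power law
(γ ≈ 0.15 with small residuals) alongside unit Zipf and Heaps exponents.
Shuffling preserves both scaling laws exactly but destroys the word
arrangement: negative `C(s)` values appear at short offsets, the LRC
decision flips, and the hundredfold larger `err` shows the remaining
positive points are scatter, not a power law.

Corpus input works the same way via `tokenize_text()`, `read_tokens()`
(one token per line), or `read_chat()` (CHAT transcripts with speaker
filtering, e.g. `chat_filter("CHI")` for child tiers). A command-line
interface is installed as `exec/lrcseq` with subcommands `tokenize`,
`generate`, `intervals`, `analyze`, `scaling`, `replicate`, and `sweep`.

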