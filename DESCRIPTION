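Package: lrcseq
Title: Long-Range Correlation Analysis of Symbolic Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies long-range correlation in symbolic (e.g., word)
    sequences by extreme-event interval analysis: the gaps between
    occurrences of the rarest 1/N of tokens are extracted, their
    autocorrelation function is computed, and its power-law decay
    C(s) ~ s^-gamma is fitted by least squares in log-log coordinates.
    Also computes rank-frequency (Zipf) and type-token (Heaps) curves
    with their exponents, and generates sequences from the Simon
    preferential-attachment model, the Pitman-Yor process, a conjunct
    model combining the Pitman-Yor innovation rate with Simon-style
    uniform history sampling, and three null baselines (i.i.d. Zipf
    streams, word shuffling, bigram Markov chains). Includes a
    replicate-run and parameter-sweep harness and readers for plain
    text, token-stream files, and CHAT transcripts with speaker
    filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
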