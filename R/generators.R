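#' Simon model sequence generator
#'
#' The "rich get richer" preferential-attachment process. The seed element
#' occupies position 1; each subsequent token is, with constant probability
#' `alpha`, a brand-new type, and otherwise a uniform draw from the entire
#' past history (equivalently, an existing type i with probability
#' proportional to its past frequency `S_i`). New types are labelled by
#' integer creation order. The rank-frequency distribution of the output
#' asymptotically follows Zipf's law and the vocabulary grows linearly
#' (Heaps exponent 1); the rare-word interval sequence is strongly
#' long-range correlated, with gamma decreasing as alpha grows.
#'
#' @param alpha new-type probability, in `[0, 1)`; `alpha = 0` is allowed
#'   as the degenerate constant sequence.
#' @param M sequence length (number of tokens).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the draw is reproducible. When NULL the current RNG stream is used.
#' @return A [token_sequence()] of integer type labels.
#' @examples
#' simon_generate(alpha = 0.1, M = 100, seed = 1)
#' @export
simon_generate <- function(alpha, M, seed = NULL) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha >= 0, alpha < 1)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  token_sequence(.simon_generate_cpp(alpha, M))
}

#' Pitman-Yor process sequence generator
#'
#' Two-parameter generalization of the Chinese restaurant process. With
#' `K` types seen and counts `S_i` after `t` tokens, the next token is a
#' new type with probability `(a K + b) / (t + b)` and an existing type i
#' with probability `(S_i - a) / (t + b)`; the per-step probabilities sum
#' to one exactly. The discount `a` subtracts mass from every seen type and
#' routes it to innovation, which makes the vocabulary grow as `t^a`
#' (Heaps exponent close to a for small b) — but destroys the long-range
#' correlation that the Simon model's uniform sampling produces. At
#' `a = 0` the model reduces to the Chinese restaurant process.
#'
#' Internally, reuse draws are realized by proposing a uniform position
#' from the history and accepting with probability `(S_i - a) / S_i`; the
#' realized per-step law equals the closed form exactly (see
#' [pitman_yor_step_distribution()]).
#'
#' @param a discount, in `[0, 1)`.
#' @param b strength, `>= 0`.
#' @inheritParams simon_generate
#' @return A [token_sequence()] of integer type labels.
#' @examples
#' pitman_yor_generate(a = 0.68, b = 0.8, M = 100, seed = 1)
#' @export
pitman_yor_generate <- function(a, b, M, seed = NULL) {
  stopifnot(length(a) == 1L, is.finite(a), a >= 0, a < 1,
            length(b) == 1L, is.finite(b), b >= 0)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  token_sequence(.pitman_yor_generate_cpp(a, b, M))
}

#' Conjunct model sequence generator
#'
#' Combines the Pitman-Yor innovation rate with Simon-style uniform
#' sampling: the next token is a new type with probability
#' `eta = (a K + b) / (t + b)` (exactly the Pitman-Yor rate), and
#' otherwise a uniform draw from the history (type i with probability
#' `(1 - eta) S_i / t`). The result keeps a natural-language-like
#' vocabulary growth rate (set by a) while preserving long-range
#' correlation. Should `eta` ever exceed 1 (impossible for `a < 1` since
#' `K <= t`), it is clamped to 1.
#'
#' @inheritParams pitman_yor_generate
#' @return A [token_sequence()] of integer type labels.
#' @examples
#' conjunct_generate(a = 0.68, b = 0.8, M = 100, seed = 1)
#' @export
conjunct_generate <- function(a, b, M, seed = NULL) {
  stopifnot(length(a) == 1L, is.finite(a), a >= 0, a < 1,
            length(b) == 1L, is.finite(b), b >= 0)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  token_sequence(.conjunct_generate_cpp(a, b, M))
}

#' Closed-form Pitman-Yor single-step distribution
#'
#' Given per-type counts after some history, returns the exact probability
#' of emitting a new type and of reusing each seen type at the next step.
#' Useful for checking the sampler against the model definition.
#'
#' @param counts integer vector of per-type occurrence counts `S_i` (all
#'   `>= 1`).
#' @inheritParams pitman_yor_generate
#' @return list with `p_new` and `p_reuse` (vector aligned with `counts`);
#'   `p_new + sum(p_reuse)` is exactly 1.
#' @export
pitman_yor_step_distribution <- function(counts, a, b) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 1L), a >= 0, a < 1, b >= 0)
  t <- sum(counts)
  K <- length(counts)
  list(p_new = (a * K + b) / (t + b),
       p_reuse = (counts - a) / (t + b))
}

#' Draw one Pitman-Yor step from an explicit state
#'
#' Samples the next emission for the state given by `counts`, using the
#' same accept-reject scheme as [pitman_yor_generate()].
#'
#' @inheritParams pitman_yor_step_distribution
#' @return 0 for a new type, otherwise the index of the reused type.
#' @export
pitman_yor_step <- function(counts, a, b) {
  counts <- as.integer(counts)
  stopifnot(all(counts >= 1L), a >= 0, a < 1, b >= 0)
  .pitman_yor_step_cpp(counts, a, b)
}

#' i.i.d. sequence with an exact Zipf rank-frequency table
#'
#' Builds the deterministic frequency profile `f(u)` proportional to
#' `u^-exponent` over `vocab_size` types, rounded to total exactly `M` by
#' the largest-remainder method, and emits a uniform random permutation of
#' the resulting multiset. The rank-frequency table of the output therefore
#' follows Zipf's law exactly while the sequence carries zero sequential
#' structure: a null model separating the marginal distribution from word
#' arrangement. Types whose target frequency rounds to zero are absent, so
#' the realized vocabulary can fall slightly below `vocab_size`.
#'
#' @param vocab_size number of candidate types V.
#' @param M sequence length, `>= vocab_size` recommended.
#' @param exponent Zipf exponent of the target profile (default 1).
#' @inheritParams simon_generate
#' @return A [token_sequence()] of integer labels (1 = most frequent).
#' @export
iid_zipf_generate <- function(vocab_size, M, exponent = 1, seed = NULL) {
  vocab_size <- as.integer(vocab_size)
  M <- as.integer(M)
  stopifnot(vocab_size >= 1L, M >= 1L, is.finite(exponent))
  if (!is.null(seed)) set.seed(seed)
  w <- (seq_len(vocab_size))^(-exponent)
  target <- M * w / sum(w)
  f <- floor(target)
  rem <- M - sum(f)
  if (rem > 0) {
    # largest remainders win the leftover tokens; ties to the lower rank
    extra <- order(target - f, decreasing = TRUE)[seq_len(rem)]
    f[extra] <- f[extra] + 1
  }
  pool <- rep.int(seq_len(vocab_size), f)
  token_sequence(pool[sample.int(length(pool))])
}

#' Shuffle a token sequence at the word level
#'
#' Uniform random permutation. The multiset of tokens — hence the
#' rank-frequency table and type count — is preserved exactly, while all
#' sequential structure (and so any long-range correlation) is destroyed.
#'
#' @param seq a [token_sequence()] or token vector.
#' @inheritParams simon_generate
#' @return A [token_sequence()].
#' @export
shuffle_tokens <- function(seq, seed = NULL) {
  seq <- as_token_sequence(seq)
  if (!is.null(seed)) set.seed(seed)
  token_sequence(seq$tokens[sample.int(seq$M)])
}

#' Bigram (first-order Markov) sequence generator
#'
#' Estimates maximum-likelihood bigram transition probabilities from a
#' training sequence and generates a new sequence of length `M`.
#' Generation starts from a uniformly chosen training token; a dead end (a
#' token that only occurs sequence-finally) restarts from a uniform token.
#' Reuse of local transition statistics preserves short-range structure
#' but no long-range correlation.
#'
#' @param training a [token_sequence()] or token vector, length `>= 2`.
#' @param M output length.
#' @inheritParams simon_generate
#' @return A [token_sequence()].
#' @export
bigram_markov_generate <- function(training, M, seed = NULL) {
  training <- as_token_sequence(training)
  stopifnot(training$M >= 2L)
  M <- as.integer(M)
  stopifnot(M >= 1L)
  if (!is.null(seed)) set.seed(seed)
  types <- unique(training$tokens)
  ids <- match(training$tokens, types)
  n <- length(ids)
  # successor lists: sampling uniformly among a token's observed successors
  # realizes the ML transition probabilities
  succ <- split(ids[-1L], ids[-n])
  succ_of <- vector("list", length(types))
  succ_of[as.integer(names(succ))] <- succ
  out <- integer(M)
  cur <- ids[sample.int(n, 1L)] # uniform training token
  out[1L] <- cur
  if (M > 1L) {
    for (k in 2:M) {
      nxt <- succ_of[[cur]]
      if (is.null(nxt) || length(nxt) == 0L) {
        cur <- ids[sample.int(n, 1L)] # dead end: restart
      } else if (length(nxt) == 1L) {
        cur <- nxt
      } else {
        cur <- nxt[sample.int(length(nxt), 1L)]
      }
      out[k] <- cur
    }
  }
  token_sequence(types[out])
}
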