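#' Select the rare-token set covering the rarest 1/N of word occurrences
#'
#' Token types are sorted by ascending corpus frequency and added to the
#' rare set until their cumulative occurrence count first reaches
#' `floor(M / N)`. Whole types are always included, so the realized count
#' may overshoot the budget by at most one frequency-class member.
#'
#' Ties within the boundary frequency class are broken by a deterministic
#' label hash. This matters: breaking ties by occurrence position (e.g.,
#' first-occurrence order) selects boundary types whose occurrences
#' cluster at one end of the sequence, which makes the rare-event density
#' nonstationary and injects spurious positive autocorrelation — enough to
#' flip shuffled (null) sequences to "long-range correlated". A
#' position-independent hash keeps the selection effectively a fixed
#' arbitrary subset of the frequency class.
#'
#' @param seq a [token_sequence()] (or a plain token vector).
#' @param N rarity denominator: the rarest 1/N of word occurrences are
#'   treated as extreme events. Default 16.
#' @return An object of class `rare_set`: list with `types` (token
#'   identifiers designated rare), `token_budget` (`floor(M/N)`), and
#'   `occurrences` (realized total frequency of the rare types).
#' @examples
#' s <- token_sequence(c("a", "b", "a", "c", "b", "a", "a", "d"))
#' select_rare_set(s, N = 2)$types # c, d, b
#' @export
select_rare_set <- function(seq, N = 16) {
  seq <- as_token_sequence(seq)
  N <- as.integer(N)
  stopifnot(length(N) == 1L, N >= 1L)
  if (seq$M < N) stop("sequence too short for N")
  budget <- seq$M %/% N
  types <- unique(seq$tokens)            # first-occurrence order
  freq <- tabulate(match(seq$tokens, types), nbins = length(types))
  ord <- order(freq, type_scramble(types)) # ascending frequency, hashed ties
  cum <- cumsum(freq[ord])
  k <- which(cum >= budget)[1]
  if (is.na(k)) k <- length(ord)         # budget unreachable only if N = 1 rounding; take all
  sel <- ord[seq_len(k)]
  structure(list(types = types[sel],
                 token_budget = budget,
                 occurrences = cum[k]),
            class = "rare_set")
}

# Deterministic position-independent ordering key for tie-breaks among
# equal-frequency types: integer labels are scrambled by a multiplicative
# congruential step (MINSTD), strings by a polynomial rolling hash. All
# intermediates stay below 2^53, so double arithmetic is exact.
type_scramble <- function(types) {
  p <- 2147483647
  g <- 48271
  if (is.numeric(types)) {
    h <- as.numeric(types) %% p
  } else {
    h <- vapply(types, function(s) {
      acc <- 0
      for (v in utf8ToInt(s)) acc <- (acc * 131 + v) %% p
      acc
    }, numeric(1), USE.NAMES = FALSE)
  }
  # three multiplicative rounds: a single round is close to monotone over
  # a contiguous label range (few wraps), which would leave the ordering
  # position-correlated for creation-ordered integer labels
  for (i in 1:3) h <- (h * g) %% p
  h
}

#' @export
print.rare_set <- function(x, ...) {
  cat(sprintf("<rare_set> %d types, %d occurrences (budget %d)\n",
              length(x$types), x$occurrences, x$token_budget))
  invisible(x)
}

#' Interval sequence of rare-token occurrences
#'
#' Converts a token sequence into the numerical sequence of gaps between
#' successive occurrences of rare-set tokens: `r[i]` is the difference of
#' the (1-based) word positions of the i-th and (i+1)-th rare occurrence,
#' so adjacent rare words give a gap of 1. In the clause
#' "Oh Romeo Romeo wherefore art thou Romeo" the target word *Romeo* yields
#' the interval sequence `[1, 4]`; the two rarest words {*Romeo*,
#' *wherefore*} yield `[1, 1, 3]`. When the rare set holds the rarest 1/N
#' of all word occurrences, the interval count is `M/N - 1` (up to the
#' whole-type inclusion rule of [select_rare_set()]).
#'
#' @param seq a [token_sequence()].
#' @param rare a [select_rare_set()] result, or a character/integer vector
#'   of token types to treat as the target set.
#' @return An object of class `interval_sequence`: list with integer gaps
#'   `r`, interval count `M_N`, rarity denominator `N` (NA when an explicit
#'   target set was given), and the moments `mu_N`, `sigma_N` (population
#'   standard deviation, denominator `M_N`).
#' @examples
#' s <- tokenize_text("Oh Romeo Romeo wherefore art thou Romeo")
#' to_intervals(s, "romeo")$r               # 1 4
#' to_intervals(s, c("romeo", "wherefore"))$r # 1 1 3
#' @export
to_intervals <- function(seq, rare) {
  seq <- as_token_sequence(seq)
  N <- NA_integer_
  if (inherits(rare, "rare_set")) {
    types <- rare$types
  } else {
    types <- rare
  }
  pos <- which(seq$tokens %in% types)
  if (length(pos) < 2L) stop("no intervals: fewer than 2 rare occurrences")
  r <- diff(pos)
  new_interval_sequence(r, N)
}

new_interval_sequence <- function(r, N = NA_integer_) {
  r <- as.integer(r)
  M_N <- length(r)
  mu <- mean(r)
  sigma <- sqrt(mean((r - mu)^2))
  structure(list(r = r, M_N = M_N, N = N, mu_N = mu, sigma_N = sigma),
            class = "interval_sequence")
}

#' @export
print.interval_sequence <- function(x, ...) {
  cat(sprintf("<interval_sequence> M_N = %d gaps (N = %s), mu = %.3f, sigma = %.3f\n",
              x$M_N, ifelse(is.na(x$N), "explicit set", x$N), x$mu_N, x$sigma_N))
  invisible(x)
}

#' @export
length.interval_sequence <- function(x) x$M_N

#' Rare-word interval sequence for rarity level N
#'
#' Convenience composition of [select_rare_set()] and [to_intervals()]:
#' the interval sequence of the rarest 1/N of word occurrences.
#'
#' @inheritParams select_rare_set
#' @return An `interval_sequence` with its `N` field set.
#' @export
rare_intervals <- function(seq, N = 16) {
  seq <- as_token_sequence(seq)
  rs <- select_rare_set(seq, N = N)
  iv <- to_intervals(seq, rs)
  iv$N <- as.integer(N)
  iv
}
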