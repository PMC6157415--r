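#' Rank-frequency (Zipf) table and exponent
#'
#' Counts token types, ranks them by descending frequency (ties broken by
#' first occurrence), and fits the Zipf exponent xi of `F(u) ~ u^-xi` by
#' ordinary least squares in log-log coordinates. Natural-language corpora
#' give xi close to 1. The table is invariant under any permutation of the
#' sequence.
#'
#' @param seq a [token_sequence()] or token vector.
#' @param rank_range length-2 numeric, inclusive rank window for the fit.
#'   Default: the full table.
#' @return An object of class `rank_frequency`: list with `table`
#'   (data.frame of `u`, `F`, `type`) and `fit` (a `powerlaw_fit` whose
#'   exponent is xi).
#' @examples
#' rank_frequency(c("a", "a", "b", "b"))$fit$exponent # 0
#' @export
rank_frequency <- function(seq, rank_range = NULL) {
  seq <- as_token_sequence(seq)
  types <- unique(seq$tokens)
  freq <- tabulate(match(seq$tokens, types), nbins = length(types))
  ord <- order(-freq, seq_along(types))
  tab <- data.frame(u = seq_along(ord), F = freq[ord],
                    type = as.character(types[ord]),
                    stringsAsFactors = FALSE)
  if (is.null(rank_range)) rank_range <- c(1, nrow(tab))
  keep <- tab$u >= rank_range[1] & tab$u <= rank_range[2]
  fit <- powerlaw_ols(tab$u[keep], tab$F[keep], rank_range)
  structure(list(table = tab, fit = fit), class = "rank_frequency")
}

#' @export
print.rank_frequency <- function(x, ...) {
  cat(sprintf("<rank_frequency> %d types, %d tokens; xi = %.4f (err = %.4g)\n",
              nrow(x$table), sum(x$table$F), x$fit$exponent, x$fit$err))
  invisible(x)
}

#' Type-token (Heaps) curve and exponent
#'
#' Evaluates the vocabulary size `V(m)` at geometrically spaced prefix
#' lengths m and fits the Heaps exponent zeta of `V(m) ~ m^zeta` by
#' ordinary least squares in log-log coordinates. Natural language has
#' zeta < 1; the Simon model grows with zeta = 1, and a Pitman-Yor
#' process with small strength b grows with zeta close to its discount a.
#'
#' @param seq a [token_sequence()] or token vector with at least 10 tokens.
#' @param n_points number of geometrically spaced evaluation prefixes
#'   (default 50), from `m_min` to `M`.
#' @param m_min smallest prefix length (default 10).
#' @return An object of class `type_token_curve`: list with `table`
#'   (data.frame of `m`, `V`) and `fit` (a `powerlaw_fit` whose exponent
#'   is zeta).
#' @examples
#' type_token_curve(as.character(1:1000))$fit$exponent # 1: all distinct
#' @export
type_token_curve <- function(seq, n_points = 50, m_min = 10) {
  seq <- as_token_sequence(seq)
  M <- seq$M
  if (M < 10L) stop("sequence too short for a type-token curve")
  m_min <- max(2L, min(m_min, M - 1L))
  m <- unique(round(exp(seq(log(m_min), log(M), length.out = n_points))))
  V_cum <- cumsum(!duplicated(seq$tokens))
  tab <- data.frame(m = m, V = V_cum[m])
  # V is constant over stretches with no new types; a constant sequence
  # has zeta = 0 by convention (log V is flat, slope 0).
  fit <- powerlaw_ols(tab$m, tab$V, c(m_min, M))
  fit$exponent <- -fit$exponent # growth curve: zeta is the slope itself
  structure(list(table = tab, fit = fit), class = "type_token_curve")
}

#' @export
print.type_token_curve <- function(x, ...) {
  cat(sprintf("<type_token_curve> V(M) = %d types at M = %d; zeta = %.4f\n",
              max(x$table$V), max(x$table$m), x$fit$exponent))
  invisible(x)
}
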