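#' Autocorrelation function of a numerical sequence
#'
#' For a sequence `R = r_1, ..., r_M` with mean `mu` and standard deviation
#' `sigma` (population convention, denominator M), the autocorrelation at
#' offset `s` is the covariance between the sequence and its s-shifted self
#' over the `M - s` overlapping pairs, normalized by the global variance:
#'
#'   C(s) = 1 / ((M - s) sigma^2) * sum_{i=1}^{M-s} (r_i - mu)(r_{i+s} - mu)
#'
#' `C(0) = 1` by definition. A long-range-correlated sequence shows
#' power-law decay `C(s) ~ s^-gamma` (see [fit_powerlaw()]); an
#' uncorrelated one fluctuates around zero with mixed signs.
#'
#' @param r numeric vector, or an `interval_sequence` from
#'   [to_intervals()]/[rare_intervals()] (its gaps, moments and length are
#'   then used, so the interval-analysis convention of substituting
#'   `M_N`, `mu_N`, `sigma_N` is automatic).
#' @param s_max largest offset computed; the curve holds s = 0..s_max.
#'   Default 1000.
#' @return An object of class `autocorr_curve`: list with `s`, `C`, and the
#'   source moments `M`, `mu`, `sigma`.
#' @examples
#' autocorrelation(c(1, 2, 1, 2, 1, 2), s_max = 2)$C # 1 -1 1
#' @export
autocorrelation <- function(r, s_max = 1000) {
  if (inherits(r, "interval_sequence")) r <- r$r
  r <- as.numeric(r)
  s_max <- as.integer(s_max)
  stopifnot(s_max >= 1L)
  M <- length(r)
  if (M < s_max + 2L) stop("sequence too short for s_max")
  mu <- mean(r)
  sig2 <- mean((r - mu)^2)
  if (sig2 == 0) stop("degenerate sequence: zero variance")
  d <- r - mu
  C <- vapply(0:s_max, function(s) {
    n <- M - s
    sum(d[seq_len(n)] * d[seq.int(s + 1L, M)]) / (n * sig2)
  }, numeric(1))
  structure(list(s = 0:s_max, C = C, M = M, mu = mu, sigma = sqrt(sig2)),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf(
    "<autocorr_curve> s = 0..%d over M = %d values (mu = %.3f, sigma = %.3f)\n",
    max(x$s), x$M, x$mu, x$sigma))
  neg <- sum(x$C[x$s > 0] < 0)
  cat(sprintf("  negative C(s) at %d of %d positive offsets\n",
              neg, sum(x$s > 0)))
  invisible(x)
}

#' Fit the power-law decay of an autocorrelation curve
#'
#' Ordinary least squares of `log10 C(s)` on `log10 s` over offsets in
#' `s_range` with strictly positive `C(s)` (negative values have no
#' logarithm and are excluded; they still count against the long-range
#' correlation decision, see [is_long_range_correlated()]). The reported
#' exponent is the negated slope, `erb` its OLS standard error, and `err`
#' the mean squared residual per used point in log10 space.
#'
#' By default the fit is evaluated at geometrically spaced offsets
#' (`spacing = "geometric"`), which weights every decade of s equally —
#' the convention a straight line drawn through a log-log plot realizes.
#' Because empirical autocorrelation curves are slightly convex in log-log
#' coordinates, a fit over *all* integer offsets (`spacing = "all"`) is
#' dominated by the last decade, where most integers live, and reports a
#' steeper slope.
#'
#' @param curve an `autocorr_curve`, or any data with numeric fields `s`
#'   and `C` (e.g., a rank-frequency table, which is why the same fitter
#'   backs several power laws).
#' @param s_range length-2 numeric, inclusive fit window on s. Default
#'   `c(1, 1000)`.
#' @param spacing `"geometric"` (default) evaluates at `n_points`
#'   log-spaced offsets in `s_range`; `"all"` uses every integer offset.
#' @param n_points number of candidate log-spaced offsets (deduplicated
#'   after rounding, so the realized count is smaller). Default 50.
#' @return An object of class `powerlaw_fit`: list with `exponent`, `erb`,
#'   `err`, `s_range`, `n_points`.
#' @examples
#' cv <- structure(list(s = 1:100, C = (1:100)^-0.5),
#'                 class = "autocorr_curve")
#' fit_powerlaw(cv, s_range = c(1, 100))$exponent # 0.5
#' @export
fit_powerlaw <- function(curve, s_range = c(1, 1000),
                         spacing = c("geometric", "all"), n_points = 50) {
  spacing <- match.arg(spacing)
  stopifnot(length(s_range) == 2L, s_range[1] >= 1)
  s <- curve$s
  C <- curve$C
  keep <- s >= s_range[1] & s <= s_range[2] & C > 0
  if (spacing == "geometric") {
    sg <- unique(round(exp(seq(log(s_range[1]), log(s_range[2]),
                               length.out = n_points))))
    keep <- keep & s %in% sg
  }
  if (sum(keep) < 3L) stop("insufficient positive autocorrelation for fit")
  powerlaw_ols(s[keep], C[keep], s_range)
}

# Shared log10-log10 OLS core for gamma, xi and zeta.
powerlaw_ols <- function(x, y, range = range(x)) {
  lx <- log10(x)
  ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(coef(fit)[2])
  erb <- if (length(lx) > 2) {
    # a zero-residual fit makes the standard error NaN with a warning
    unname(suppressWarnings(summary(fit))$coefficients[2, 2])
  } else 0
  if (!is.finite(erb)) erb <- 0
  err <- mean(fit$residuals^2)
  structure(list(exponent = -slope, erb = erb, err = err,
                 s_range = as.numeric(range), n_points = length(lx)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> exponent = %.4f (erb = %.4g, err = %.4g per point)\n",
    x$exponent, x$erb, x$err))
  cat(sprintf("  %d points in s range [%g, %g]\n",
              x$n_points, x$s_range[1], x$s_range[2]))
  invisible(x)
}

#' Decide long-range correlation from an autocorrelation curve
#'
#' The working criterion: the sequence is judged long-range correlated if
#' and only if `C(s) > 0` for every offset `s = 1..9`. Any negative value
#' at a short offset marks the curve as fluctuating around zero rather
#' than decaying as a power law. This is deliberately loose — scattered but
#' positive points still pass — so `strict = TRUE` additionally requires
#' positivity over the whole supplied `s > 0` range.
#'
#' @param curve an `autocorr_curve` containing at least s = 1..9.
#' @param strict require `C(s) > 0` at every computed positive offset.
#' @return `TRUE` or `FALSE`.
#' @export
is_long_range_correlated <- function(curve, strict = FALSE) {
  s <- curve$s
  C <- curve$C
  need <- 1:9
  if (!all(need %in% s)) stop("curve must contain offsets 1..9")
  if (strict) return(all(C[s > 0] > 0))
  all(C[match(need, s)] > 0)
}

#' Full interval-autocorrelation analysis of a token sequence
#'
#' Runs the complete pipeline: select the rarest 1/N of word occurrences,
#' form their interval sequence, compute the autocorrelation function of
#' the gaps, fit its power-law decay, and decide long-range correlation.
#'
#' @inheritParams select_rare_set
#' @param s_max largest autocorrelation offset (default 1000).
#' @param s_range power-law fit window (default `c(1, 1000)`).
#' @param strict passed to [is_long_range_correlated()].
#' @return An object of class `lrc_analysis`: list with `intervals`
#'   (`interval_sequence`), `curve` (`autocorr_curve`), `fit`
#'   (`powerlaw_fit`, or NULL with a warning when too few positive points
#'   exist), and `lrc` (logical).
#' @examples
#' s <- simon_generate(alpha = 0.1, M = 20000, seed = 1)
#' a <- analyze_sequence(s, N = 16, s_max = 100, s_range = c(1, 100))
#' a$fit$exponent
#' @export
analyze_sequence <- function(seq, N = 16, s_max = 1000,
                             s_range = c(1, min(s_max, 1000)),
                             strict = FALSE) {
  seq <- as_token_sequence(seq)
  iv <- rare_intervals(seq, N = N)
  curve <- autocorrelation(iv, s_max = s_max)
  fit <- tryCatch(fit_powerlaw(curve, s_range = s_range),
                  error = function(e) {
                    warning(conditionMessage(e))
                    NULL
                  })
  structure(list(intervals = iv, curve = curve, fit = fit,
                 lrc = is_long_range_correlated(curve, strict = strict),
                 N = as.integer(N)),
            class = "lrc_analysis")
}

#' @export
print.lrc_analysis <- function(x, ...) {
  cat(sprintf("<lrc_analysis> N = %d, M_N = %d intervals\n",
              x$N, x$intervals$M_N))
  if (!is.null(x$fit)) {
    cat(sprintf("  gamma = %.4f (erb = %.4g, err = %.4g)\n",
                x$fit$exponent, x$fit$erb, x$fit$err))
  } else {
    cat("  power-law fit unavailable (too few positive C(s))\n")
  }
  cat(sprintf("  long-range correlated: %s\n", x$lrc))
  invisible(x)
}
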