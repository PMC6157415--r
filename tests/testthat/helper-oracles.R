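# Independent oracles, kept deliberately naive and separate from the
# package's implementations.

# Textbook double-loop autocorrelation: literal transcription of
# C(s) = 1/((M-s) sigma^2) * sum_i (r_i - mu)(r_{i+s} - mu)
naive_autocorrelation <- function(r, s_max) {
  M <- length(r)
  mu <- sum(r) / M
  sig2 <- sum((r - mu)^2) / M
  C <- numeric(s_max + 1)
  for (s in 0:s_max) {
    acc <- 0
    for (i in 1:(M - s)) acc <- acc + (r[i] - mu) * (r[i + s] - mu)
    C[s + 1] <- acc / ((M - s) * sig2)
  }
  C
}

# Textbook simple-regression formulas (no lm): slope, its standard error,
# and the mean squared residual.
naive_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  list(slope = slope, se = se, msr = mean(res^2))
}

# Hand counter for rank-frequency checks.
naive_freq_table <- function(tokens) {
  tab <- table(tokens)
  sort(as.integer(tab), decreasing = TRUE)
}

# Write a small CHAT transcript to a temp file and return its path.
write_toy_chat <- function(lines) {
  path <- tempfile(fileext = ".cha")
  writeLines(lines, path, useBytes = TRUE)
  path
}
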