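test_that("all generators are seed-reproducible", {
  gens <- list(
    function(seed) simon_generate(0.2, 2000, seed),
    function(seed) pitman_yor_generate(0.6, 2, 2000, seed),
    function(seed) conjunct_generate(0.6, 2, 2000, seed),
    function(seed) iid_zipf_generate(50, 2000, seed = seed),
    function(seed) shuffle_tokens(rep(letters[1:5], 40), seed),
    function(seed) bigram_markov_generate(
      rep(c("a", "b", "c", "a", "c", "b", "b", "a"), 25), 500, seed))
  for (g in gens) {
    expect_identical(g(123)$tokens, g(123)$tokens)
    expect_false(identical(g(123)$tokens, g(124)$tokens))
  }
})

test_that("degenerate parameter limits give constant sequences", {
  expect_true(all(simon_generate(0, 100, seed = 1)$tokens == 1L))
  expect_true(all(pitman_yor_generate(0, 0, 100, seed = 1)$tokens == 1L))
  expect_true(all(conjunct_generate(0, 0, 100, seed = 1)$tokens == 1L))
  expect_equal(iid_zipf_generate(1, 50, seed = 1)$tokens, rep(1L, 50))
  expect_identical(shuffle_tokens("a")$tokens, "a")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(simon_generate(1, 10))
  expect_error(simon_generate(-0.1, 10))
  expect_error(pitman_yor_generate(1.2, 1, 10))
  expect_error(pitman_yor_generate(0.5, -1, 10))
  expect_error(conjunct_generate(-0.5, 1, 10))
})

test_that("Simon vocabulary size is binomial in alpha", {
  M <- 1e5
  alpha <- 0.1
  K <- length(unique(simon_generate(alpha, M, seed = 77)$tokens))
  bounds <- 1 + qbinom(c(5e-4, 1 - 5e-4), M - 1, alpha)
  expect_gte(K, bounds[1])
  expect_lte(K, bounds[2])
})

test_that("Simon near alpha = 1 emits almost all distinct types", {
  s <- simon_generate(0.99, 5000, seed = 8)
  expect_gt(length(unique(s$tokens)), 4800)
})

test_that("Pitman-Yor single-step law matches the closed form", {
  # hand-computed: counts (3, 1, 2), a = 0.5, b = 1 -> t = 6, K = 3
  d <- pitman_yor_step_distribution(c(3, 1, 2), a = 0.5, b = 1)
  expect_equal(d$p_new, 2.5 / 7)
  expect_equal(d$p_reuse, c(2.5, 0.5, 1.5) / 7)

  # every state with t <= 5: probabilities are a simplex
  states <- list(1, c(1, 1), 2, c(2, 1), c(1, 1, 1), 3,
                 c(2, 2), c(3, 1), c(2, 1, 1), c(1, 1, 1, 1), 4)
  for (S in states) {
    for (pars in list(c(0, 0.5), c(0.3, 0), c(0.68, 0.8), c(0.9, 100))) {
      d <- pitman_yor_step_distribution(S, pars[1], pars[2])
      expect_equal(d$p_new + sum(d$p_reuse), 1)
      expect_true(all(d$p_reuse >= 0) && d$p_new >= 0)
    }
  }
})

test_that("the Pitman-Yor sampler realizes the closed-form step law", {
  counts <- c(5, 2, 1, 1)
  a <- 0.6
  b <- 1.5
  d <- pitman_yor_step_distribution(counts, a, b)
  set.seed(31)
  n <- 40000
  draws <- replicate(n, pitman_yor_step(counts, a, b))
  p_hat <- tabulate(draws + 1L, nbins = length(counts) + 1L) / n
  p_exact <- c(d$p_new, d$p_reuse)
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_true(all(abs(p_hat - p_exact) < 4 * se + 1e-4))
})

test_that("Chinese restaurant vocabulary growth matches its expectation", {
  # a = 0: E[K_M] = sum_{n=0}^{M-1} b / (b + n)
  b <- 5
  M <- 1e5
  n_seeds <- 50
  K <- vapply(seq_len(n_seeds), function(sd) {
    length(unique(pitman_yor_generate(0, b, M, seed = 500 + sd)$tokens))
  }, numeric(1))
  expected <- sum(b / (b + 0:(M - 1)))
  se <- sd(K) / sqrt(n_seeds)
  expect_lt(abs(mean(K) - expected), 3 * se)
})

test_that("conjunct model inherits the Pitman-Yor vocabulary growth rate", {
  # the innovation rate eta = (aK + b)/(t + b) is exactly Pitman-Yor's, so
  # K_t grows ~ t^a even though reuse is uniform history sampling
  s <- conjunct_generate(0.5, 1, 5e4, seed = 12)
  zeta <- type_token_curve(s)$fit$exponent
  expect_lt(abs(zeta - 0.5), 0.15)
})

test_that("iid Zipf output realizes its target frequency profile exactly", {
  V <- 40
  M <- 1000
  xi0 <- 1
  s <- iid_zipf_generate(V, M, xi0, seed = 2)
  w <- (1:V)^-xi0
  target <- M * w / sum(w)
  f <- floor(target)
  rem <- M - sum(f)
  extra <- order(target - f, decreasing = TRUE)[seq_len(rem)]
  f[extra] <- f[extra] + 1
  realized <- tabulate(s$tokens, nbins = V)
  expect_equal(realized, as.integer(f))
  expect_equal(s$M, M)
})

test_that("shuffling preserves the token multiset bit-exactly", {
  s <- simon_generate(0.3, 5000, seed = 3)
  sh <- shuffle_tokens(s, seed = 4)
  expect_identical(sort(s$tokens), sort(sh$tokens))
  expect_false(identical(s$tokens, sh$tokens))
})

test_that("bigram model reproduces deterministic chains and handles dead ends", {
  out <- bigram_markov_generate(c("a", "b", "a", "b", "a", "b"), 20,
                                seed = 5)
  expect_true(all(out$tokens[-1] != out$tokens[-20]))
  expect_setequal(unique(out$tokens), c("a", "b"))

  # "c" only occurs finally: generation must restart rather than stall
  out2 <- bigram_markov_generate(c("a", "b", "c"), 50, seed = 6)
  expect_equal(out2$M, 50L)
})

test_that("bigram transitions follow the training statistics", {
  # from "a": successors b (2x) and c (1x)
  train <- c("a", "b", "a", "c", "a", "b", "a")
  set.seed(14)
  out <- bigram_markov_generate(train, 30000)$tokens
  from_a <- out[which(out[-30000] == "a") + 1L]
  p_b <- mean(from_a == "b")
  expect_equal(p_b, 2 / 3, tolerance = 0.05)
})
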