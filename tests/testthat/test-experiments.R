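test_that("replicate runs are reproducible and aggregate correctly", {
  r1 <- replicate_run("simon", list(alpha = 0.3), M = 2e4, n_reps = 3,
                      base_seed = 9, s_max = 100, s_range = c(1, 100))
  r2 <- replicate_run("simon", list(alpha = 0.3), M = 2e4, n_reps = 3,
                      base_seed = 9, s_max = 100, s_range = c(1, 100))
  expect_identical(r1$gammas, r2$gammas)
  expect_equal(r1$mean_gamma, mean(r1$gammas))
  expect_equal(r1$frac_lrc, mean(r1$lrc))
  expect_equal(r1$mean_err, mean(r1$errs))

  single <- replicate_run("simon", list(alpha = 0.3), M = 2e4, n_reps = 1,
                          base_seed = 9, s_max = 100, s_range = c(1, 100))
  expect_equal(single$sd_gamma, 0)
  expect_false(single$sd_defined)
})

test_that("Simon mean gamma decreases from small to large alpha", {
  g <- vapply(c(0.1, 0.4), function(al) {
    replicate_run("simon", list(alpha = al), M = 1e5, n_reps = 3,
                  base_seed = 50)$mean_gamma
  }, numeric(1))
  expect_gt(g[1], g[2])
})

test_that("a 1x1 grid sweep equals a single replicate run", {
  sw <- grid_sweep("conjunct", a_values = 0.68, b_values = 0.8,
                   M = 5e4, n_reps = 2, base_seed = 21,
                   s_max = 100, s_range = c(1, 100))
  rr <- replicate_run("conjunct", list(a = 0.68, b = 0.8), M = 5e4,
                      n_reps = 2, base_seed = 21, s_max = 100,
                      s_range = c(1, 100))
  expect_equal(nrow(sw$cells), 1L)
  expect_equal(sw$cells$mean_gamma, rr$mean_gamma)
  expect_equal(sw$cells$frac_lrc, rr$frac_lrc)
})

test_that("grid sweeps cover the full grid and survive unfittable cells", {
  sw <- grid_sweep("pitman_yor", a_values = c(0, 0.5),
                   b_values = c(0.5, 10, 100), M = 2e4, n_reps = 2,
                   base_seed = 3, s_max = 50, s_range = c(1, 50))
  expect_equal(nrow(sw$cells), 6L)
  expect_true(all(sw$cells$frac_lrc >= 0 & sw$cells$frac_lrc <= 1))
})

test_that("the conjunct LRC region appears at large a, small-to-moderate b", {
  sw <- grid_sweep("conjunct", a_values = c(0, 0.7),
                   b_values = c(1), M = 2e5, n_reps = 3, base_seed = 11)
  low_a <- sw$cells[sw$cells$a == 0, ]
  high_a <- sw$cells[sw$cells$a == 0.7, ]
  expect_equal(high_a$frac_lrc, 1)
  expect_lt(low_a$frac_lrc, high_a$frac_lrc)
})

test_that("cli subcommands chain tokenize -> analyze -> scaling", {
  txt <- tempfile(fileext = ".txt")
  tok <- tempfile(fileext = ".tok")
  json <- tempfile(fileext = ".json")
  set.seed(2)
  writeLines(paste(sample(c(letters, letters[1:6]), 4000, replace = TRUE),
                   collapse = " "), txt)
  expect_equal(suppressMessages(
    lrcseq_main(c("tokenize", "--input", txt, "--output", tok))), 0L)
  expect_equal(read_tokens(tok)$M, 4000L)

  expect_equal(suppressMessages(
    lrcseq_main(c("analyze", "--input", tok, "--n", "4", "--smax", "50",
                  "--json", json))), 0L)
  report <- jsonlite::fromJSON(json)
  expect_named(report, c("M", "N", "M_N", "mu_N", "sigma_N", "gamma",
                         "erb", "err", "lrc"), ignore.order = TRUE)
  expect_equal(report$M, 4000L)

  expect_equal(suppressMessages(
    lrcseq_main(c("scaling", "--input", tok, "--json", json))), 0L)
  expect_true(is.finite(jsonlite::fromJSON(json)$xi))
})

test_that("cli generate and replicate emit seeded, parseable output", {
  tok <- tempfile(fileext = ".tok")
  json <- tempfile(fileext = ".json")
  expect_equal(suppressMessages(
    lrcseq_main(c("generate", "simon", "--alpha", "0.2", "--length",
                  "5000", "--seed", "7", "--output", tok))), 0L)
  expect_identical(read_tokens(tok)$tokens,
                   as.character(simon_generate(0.2, 5000, seed = 7)$tokens))

  expect_equal(suppressMessages(
    lrcseq_main(c("replicate", "simon", "--alpha", "0.3", "--reps", "2",
                  "--length", "20000", "--seed", "5", "--json", json))), 0L)
  rep_json <- jsonlite::fromJSON(json)
  expect_equal(rep_json$n_reps, 2L)
  expect_length(rep_json$gammas, 2L)
})

test_that("cli usage errors exit with status 2", {
  expect_equal(suppressMessages(lrcseq_main(character(0))), 2L)
  expect_equal(suppressMessages(lrcseq_main("frobnicate")), 2L)
  expect_equal(suppressMessages(lrcseq_main(c("generate", "simon"))), 2L)
  expect_equal(suppressMessages(
    lrcseq_main(c("generate", "nosuchmodel", "--length", "10",
                  "--output", tempfile()))), 2L)
})
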