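test_that("bits per symbol is payload bits over input symbols", {
  expect_equal(round(bits_per_symbol(62, 42), 3), 1.476)
  expect_equal(bits_per_symbol(7, 8), 0.875)
  expect_equal(bits_per_symbol(0, 10), 0)
  expect_error(bits_per_symbol(10, 0), "'n' must be >= 1")

  enc <- encode_greedy("aaaaaaab", codebook_weighted())
  expect_equal(bits_per_symbol(enc, 8), 0.875)
})

test_that("two-symbol alphabet forces exactly 1 bit/symbol at m = 1", {
  fib <- as.character(gen_fibonacci(15))
  rep1 <- run_experiment(fib, m = 1, coder = "greedy")
  expect_equal(rep1$bits_per_symbol, 1)
  rep2 <- run_experiment(fib, m = 1, coder = "optimal")
  expect_equal(rep2$bits_per_symbol, 1)
})

test_that("trajectory symbol-by-symbol rate matches the closed form", {
  # Huffman depths for probabilities {.88,.05,.01,.05,.01} are {1,2,3,4,4}
  # (up to relabelling within equal probabilities), giving an expected
  # rate of 0.88*1 + 0.05*2 + 0.05*3 + 0.01*4 + 0.01*4 = 1.21 b/sym
  closed_form <- 1.21
  x <- gen_trajectory(5e4, seed = 12)
  rep <- run_experiment(x, m = 1, alpha = 0, coder = "greedy", split = 0.5)
  expect_lt(abs(rep$bits_per_symbol - closed_form), 0.02)
  expect_lt(rep$entropy, closed_form)  # Huffman sits above the entropy
})

test_that("optimal never loses to greedy and both decode the test data", {
  set.seed(51)
  corpora <- list(
    as.character(gen_fibonacci(12)),
    gen_trajectory(800, seed = 2),
    paste(sample(c("A", "C", "G", "T"), 600, TRUE,
                 prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
  )
  for (corpus in corpora) {
    for (m in c(1, 3)) {
      ropt <- run_experiment(corpus, m = m, coder = "optimal", split = 0.5)
      rgreedy <- run_experiment(corpus, m = m, coder = "greedy", split = 0.5)
      expect_lte(ropt$bits_per_symbol, rgreedy$bits_per_symbol)

      parts <- split_pattern_test(corpus, 0.5)
      book <- train_codebook(parts$pattern, m = m)
      tree <- build_decode_tree(book)
      expect_equal(decode_bits(encode_optimal(parts$test, book), tree),
                   parts$test)
      expect_equal(decode_bits(encode_greedy(parts$test, book), tree),
                   parts$test)
    }
  }
})

test_that("reports are deterministic and flag alphabet mismatches", {
  x <- gen_trajectory(2000, seed = 3)
  r1 <- run_experiment(x, m = 2, coder = "greedy")
  r2 <- run_experiment(x, m = 2, coder = "greedy")
  expect_equal(unclass(r1), unclass(r2))

  mismatched <- paste0(strrep("a", 50), "zzz")
  expect_error(run_experiment(mismatched, m = 1, split = 0.5),
               "alphabet mismatch")
})

test_that("DEFLATE baseline is reported when requested", {
  fib <- as.character(gen_fibonacci(18))
  rep <- run_experiment(fib, m = 8, coder = "greedy", deflate = TRUE)
  expect_true(is.numeric(rep$deflate_bps) && rep$deflate_bps > 0)
})
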