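test_that("sliding-window counts reproduce the worked m = 3 example", {
  f0 <- estimate_frequencies("aaaaaaab", m = 3, alpha = 0)
  expect_equal(f0$gram, c("a", "b", "aa", "ab", "aaa", "aab"))
  expect_equal(f0$count, c(7, 1, 6, 1, 5, 1))

  f1 <- estimate_frequencies("aaaaaaab", m = 3, alpha = 1)
  expect_equal(f1$gram, f0$gram)  # weighting never reorders the table
  expect_equal(f1$count, c(7, 1, 12, 2, 15, 3))
})

test_that("single-symbol counts of the three-letter example sequence", {
  x <- "aaaabbaaaabbbbbbaabcabbccabbaaaaabbccaaaaa"
  f <- estimate_frequencies(x, m = 1, alpha = 0)
  expect_equal(nchar(x), 42L)
  counts <- structure(f$count, names = f$gram)
  expect_equal(counts[["a"]], 22)
  expect_equal(counts[["b"]], 15)
  expect_equal(counts[["c"]], 5)
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  expect_equal(estimate_frequencies("x", 1, 0)$count, 1)
  expect_error(estimate_frequencies("", 1, 0), "empty input")
  expect_error(estimate_frequencies("ab", 3, 0), "m exceeds data size")
  expect_error(estimate_frequencies("ab", 1, -1), "alpha")
})

test_that("length-i counts sum to (n - i + 1) * i^alpha on random patterns", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    pattern <- random_string(n, c("a", "c", "g", "t"))
    m <- sample(1:min(4, n), 1)
    alpha <- sample(c(0, 1, 2, 0.5), 1)
    freqs <- estimate_frequencies(pattern, m, alpha)
    for (i in seq_len(m)) {
      expect_equal(sum(freqs$count[freqs$length == i]), (n - i + 1) * i^alpha)
    }
    # weighted table is the unweighted one scaled by length^alpha
    base <- estimate_frequencies(pattern, m, 0)
    expect_equal(freqs$gram, base$gram)
    expect_equal(freqs$count, base$count * base$length^alpha)
  }
})

test_that("pruning keeps all singles and the top multi-symbol grams", {
  f1 <- estimate_frequencies("aaaaaaab", m = 3, alpha = 1)

  kept <- prune_frequencies(f1, 0.5)  # top 2 of the 4 multi-symbol grams
  expect_equal(kept$gram, c("a", "b", "aa", "aaa"))
  expect_equal(kept$count, c(7, 1, 12, 15))

  expect_equal(prune_frequencies(f1, 1.0), f1)
  floor_case <- prune_frequencies(f1, 0.0)
  expect_equal(floor_case$gram, c("a", "b"))

  expect_error(prune_frequencies(f1, 1.5), "keep_fraction")
  expect_error(prune_frequencies(f1, -0.1), "keep_fraction")
})

test_that("pruning ties go to the earlier-inserted gram and counts survive", {
  set.seed(7)
  for (rep in 1:10) {
    freqs <- estimate_frequencies(random_string(sample(8:30, 1)), sample(2:3, 1), 0)
    kf <- runif(1)
    pruned <- prune_frequencies(freqs, kf)
    # all singles retained, survivor counts unchanged, order preserved
    singles <- freqs$gram[freqs$length == 1]
    expect_true(all(singles %in% pruned$gram))
    expect_equal(pruned$count,
                 freqs$count[match(pruned$gram, freqs$gram)])
    expect_true(!is.unsorted(match(pruned$gram, freqs$gram)))
    # survivor set is the sort-and-cut of the multi-symbol entries
    multi <- which(freqs$length >= 2)
    k <- ceiling(kf * length(multi))
    expect_equal(sum(pruned$length >= 2), k)
    if (k > 0) {
      worst_kept <- min(pruned$count[pruned$length >= 2])
      dropped <- setdiff(freqs$gram[multi], pruned$gram)
      if (length(dropped)) {
        expect_true(max(freqs$count[freqs$gram %in% dropped]) <= worst_kept)
      }
    }
  }
})

test_that("frequency tables round-trip through the tab-separated format", {
  freqs <- estimate_frequencies("aaaaaaab", 3, alpha = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequencies(freqs, path)
  back <- read_frequencies(path)
  expect_equal(back, freqs)

  # grams containing tab/newline/control characters survive escaping
  odd <- gramhuff:::new_gram_freqs(c("\t", "\n", "x", "\u0001"),
                                   c(3, 2, 1, 1), 1L, 0)
  write_frequencies(odd, path)
  expect_equal(read_frequencies(path)$gram, odd$gram)
})
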