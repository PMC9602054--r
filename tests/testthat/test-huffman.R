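test_that("canonical tie policy reproduces both worked codeword columns", {
  f0 <- estimate_frequencies("aaaaaaab", 3, alpha = 0)
  b0 <- extract_codewords(build_huffman_tree(f0))
  expect_equal(unclass(b0)[names(codebook_unweighted())],
               unclass(codebook_unweighted())[names(codebook_unweighted())])

  f1 <- estimate_frequencies("aaaaaaab", 3, alpha = 1)
  b1 <- extract_codewords(build_huffman_tree(f1))
  expect_equal(unclass(b1)[names(codebook_weighted())],
               unclass(codebook_weighted())[names(codebook_weighted())])
})

test_that("three-symbol example yields code lengths {1, 2, 2}", {
  x <- "aaaabbaaaabbbbbbaabcabbccabbaaaaabbccaaaaa"
  book <- train_codebook(x, m = 1, alpha = 0)
  lens <- nchar(unclass(book))
  names(lens) <- names(book)
  # bit polarity below the root is arbitrary; lengths are not
  expect_equal(lens[["a"]], 1L)
  expect_equal(lens[["b"]], 2L)
  expect_equal(lens[["c"]], 2L)
})

test_that("degenerate trees stay encodable", {
  one <- gramhuff:::new_gram_freqs("x", 5, 1L, 0)
  tree <- build_huffman_tree(one)
  expect_equal(as.character(extract_codewords(tree)), "0")

  two <- gramhuff:::new_gram_freqs(c("x", "y"), c(2, 1), 1L, 0)
  book <- extract_codewords(build_huffman_tree(two))
  # smaller weight becomes the "0" child
  expect_equal(book[["y"]], "0")
  expect_equal(book[["x"]], "1")

  expect_error(build_huffman_tree(gramhuff:::new_gram_freqs(
    character(0), numeric(0), 1L, 0)), "empty")
})

test_that("first-order entropy matches hand-computed values", {
  expect_equal(round(first_order_entropy(c(22, 15, 5) / 42), 3), 1.385)
  expect_equal(first_order_entropy(c(0.5, 0.5)), 1)
  expect_equal(first_order_entropy(1), 0)
  expect_error(first_order_entropy(c(0.5, 0)), "positive")
  expect_error(first_order_entropy(c(0.7, -0.2)), "positive")
})

test_that("average code length reports the worked 62-bit total", {
  x <- "aaaabbaaaabbbbbbaabcabbccabbaaaaabbccaaaaa"
  freqs <- estimate_frequencies(x, 1, alpha = 0)
  book <- extract_codewords(build_huffman_tree(freqs))
  avg <- average_code_length(book, freqs)
  expect_equal(attr(avg, "total_bits"), 62)
  expect_equal(round(as.numeric(avg), 3), 1.476)

  uniform <- gramhuff:::new_gram_freqs(c("x", "y"), c(3, 3), 1L, 0)
  expect_equal(as.numeric(average_code_length(
    extract_codewords(build_huffman_tree(uniform)), uniform)), 1)

  expect_error(average_code_length(book, estimate_frequencies(x, 1, 1)[1:2, ]),
               NA)
  bad <- estimate_frequencies("abcd", 1, 0)
  expect_error(average_code_length(book, bad), "missing codeword")
})

test_that("codebooks are prefix-free, Kraft-tight and near-entropy", {
  set.seed(11)
  for (rep in 1:60) {
    freqs <- random_freq_table()
    book <- extract_codewords(build_huffman_tree(freqs))
    codes <- unclass(book)

    if (length(codes) >= 2) {
      # prefix-freeness
      for (i in seq_along(codes)) {
        others <- codes[-i]
        expect_false(any(startsWith(others, codes[[i]])))
      }
      # Kraft equality for a full binary tree
      expect_equal(sum(2^(-nchar(codes))), 1)
    }

    # Shannon bound and the pmax + 0.086 redundancy bound over the gram
    # distribution implied by the table
    p <- freqs$count / sum(freqs$count)
    H <- first_order_entropy(p)
    avg <- as.numeric(average_code_length(book, freqs))
    if (length(codes) >= 2) {
      expect_gte(avg, H)
      expect_lte(avg - H, max(p) + 0.086 + 1e-12)
    }
  }
})

test_that("explicit codebook construction validates its input", {
  book <- as_codebook(c(a = "0", b = "10", c = "11"))
  expect_s3_class(book, "gram_codebook")
  expect_equal(attr(book, "m"), 1L)
  expect_error(as_codebook(c(a = "0", b = "01")), "invalid codebook")
  expect_error(as_codebook(c("0", "1")), "named")
  expect_error(as_codebook(c(a = "0", b = "2")), "0/1")
})
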