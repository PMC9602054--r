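# Independent oracles and fixture builders used across the suite.

# The two m = 3 codebooks for the pattern "aaaaaaab" (unweighted and
# length-weighted frequencies). Built here from explicit gram/codeword
# pairs so they are independent of the package's tree construction.
codebook_unweighted <- function() {
  as_codebook(c(a = "11", b = "0010", aa = "10", ab = "0011",
                aaa = "01", aab = "000"))
}

codebook_weighted <- function() {
  as_codebook(c(a = "111", b = "11010", aa = "10", ab = "11011",
                aaa = "0", aab = "1100"))
}

# Brute-force minimum encoded length: plain recursion over every
# segmentation of `s` into grams of length <= maxlen that carry a codeword.
# Exponential on purpose — it shares no logic with the dynamic program.
brute_min_bits <- function(s, book, maxlen) {
  lens <- nchar(unclass(book))
  names(lens) <- names(book)
  n <- nchar(s)
  rec <- function(pos) {
    if (pos > n) return(0L)
    best <- Inf
    for (k in seq_len(min(maxlen, n - pos + 1L))) {
      g <- substr(s, pos, pos + k - 1L)
      L <- unname(lens[g])
      if (!is.na(L)) {
        tail_bits <- rec(pos + k)
        if (L + tail_bits < best) best <- L + tail_bits
      }
    }
    best
  }
  rec(1L)
}

# Literal stage-based transcription of the multistage-graph procedure:
# stages e = 0..n-1, states i = e..min(m*e, n), full code strings per node,
# strict-improvement updates. Returns the complete code string for node n.
encode_optimal_stages <- function(input, book, m) {
  n <- nchar(input)
  dc <- as.list(unclass(book))
  Dnodes <- vector("list", n + 1L)
  Dnodes[[1L]] <- ""
  for (e in 0:(n - 1L)) {
    hi <- min(m * e, n)
    if (e > hi) next
    for (i in e:hi) {
      if (is.null(Dnodes[[i + 1L]])) next
      if (i >= n) next
      l <- min(i + m, n)
      for (j in (i + 1L):l) {
        S <- substr(input, i + 1L, j)
        cw <- dc[[S]]
        if (is.null(cw)) next
        cand <- paste0(Dnodes[[i + 1L]], cw)
        if (is.null(Dnodes[[j + 1L]]) ||
            nchar(Dnodes[[j + 1L]]) > nchar(cand)) {
          Dnodes[[j + 1L]] <- cand
        }
      }
    }
  }
  Dnodes[[n + 1L]]
}

# All strings of the given length over an alphabet.
all_strings <- function(len, alphabet = c("a", "b")) {
  if (len == 0L) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), len), stringsAsFactors = FALSE))
  do.call(paste0, grid)
}

random_string <- function(len, alphabet = c("a", "b")) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random frequency table: gram statistics of a random pattern string, with
# random m, alpha and optional pruning.
random_freq_table <- function() {
  alphabet <- letters[seq_len(sample(2:5, 1L))]
  pattern <- random_string(sample(10:60, 1L), alphabet)
  m <- sample(1:3, 1L)
  alpha <- sample(c(0, 1, 2, 0.5), 1L)
  freqs <- estimate_frequencies(pattern, m, alpha)
  if (runif(1) < 0.3) freqs <- prune_frequencies(freqs, runif(1))
  freqs
}
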