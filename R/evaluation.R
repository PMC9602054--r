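#' Compressed bits per input symbol
#'
#' The experiments' headline metric: payload size in bits divided by the
#' number of input symbols. Codebook transmission cost is excluded (the
#' codewords are assumed known to both encoder and decoder).
#'
#' @param bits A `gram_encoding`, a 0/1 string, or a bit count.
#' @param n Number of input symbols (>= 1).
#' @return Bits per symbol (numeric).
#' @examples
#' bits_per_symbol(62, 42)
#' @export
bits_per_symbol <- function(bits, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("'n' must be >= 1")
  }
  n_bits(bits) / n
}

#' Run a pattern/test compression experiment
#'
#' Splits the corpus into contiguous pattern and test parts, trains a gram
#' codebook on the pattern part, encodes the test part, and reports the
#' compression achieved. Mirrors the benchmark protocol: statistics come
#' from pattern data only, and the reported rate excludes codebook cost.
#'
#' @param corpus Symbol sequence providing both parts.
#' @param m Maximum gram length.
#' @param alpha Length weight for frequency estimation (see
#'   [estimate_frequencies()]).
#' @param keep_fraction Codebook pruning fraction (see
#'   [prune_frequencies()]).
#' @param coder `"greedy"` (linear-time heuristic) or `"optimal"` (dynamic
#'   programming).
#' @param split Fraction of the corpus used as pattern data.
#' @param deflate If `TRUE`, also report a DEFLATE baseline: the test part
#'   compressed with a standard gzip codec, in bits per symbol.
#' @return A list of class `gram_experiment`: configuration, `n_pattern`,
#'   `n_test`, `bits`, `bits_per_symbol`, `entropy` (first-order entropy of
#'   the pattern symbol distribution), `codebook_size`, and optionally
#'   `deflate_bps`.
#' @examples
#' run_experiment(gen_fibonacci(12), m = 4, coder = "greedy")
#' @export
run_experiment <- function(corpus, m, alpha = 1, keep_fraction = 1,
                           coder = c("greedy", "optimal"), split = 0.25,
                           deflate = FALSE) {
  coder <- match.arg(coder)
  parts <- split_pattern_test(corpus, split)
  if (!all(seq_alphabet(parts$test) %in% seq_alphabet(parts$pattern))) {
    stop("alphabet mismatch")
  }
  book <- train_codebook(parts$pattern, m = m, alpha = alpha,
                         keep_fraction = keep_fraction)
  enc <- if (coder == "optimal") {
    encode_optimal(parts$test, book, m)
  } else {
    encode_greedy(parts$test, book, m)
  }
  n_test <- nchar(parts$test)
  singles <- attr(book, "freqs")
  singles <- singles[singles$length == 1L, ]
  report <- list(
    m = m, alpha = alpha, keep_fraction = keep_fraction, coder = coder,
    split = split,
    n_pattern = nchar(parts$pattern), n_test = n_test,
    bits = n_bits(enc),
    bits_per_symbol = bits_per_symbol(enc, n_test),
    entropy = first_order_entropy(singles$count),
    codebook_size = length(book)
  )
  if (deflate) {
    gz <- memCompress(charToRaw(parts$test), type = "gzip")
    report$deflate_bps <- 8 * length(gz) / n_test
  }
  structure(report, class = "gram_experiment")
}

#' @export
print.gram_experiment <- function(x, ...) {
  cat(sprintf(
    "m-gram coding experiment (m = %d, alpha = %g, keep = %g, %s coder)\n",
    x$m, x$alpha, x$keep_fraction, x$coder))
  cat(sprintf("  pattern/test symbols: %d / %d\n", x$n_pattern, x$n_test))
  cat(sprintf("  bits per symbol:      %.3f\n", x$bits_per_symbol))
  cat(sprintf("  first-order entropy:  %.3f b/sym (pattern)\n", x$entropy))
  cat(sprintf("  codebook size:        %d grams\n", x$codebook_size))
  if (!is.null(x$deflate_bps)) {
    cat(sprintf("  DEFLATE baseline:     %.3f b/sym\n", x$deflate_bps))
  }
  invisible(x)
}
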