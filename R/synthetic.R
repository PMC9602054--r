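#' Generate i.i.d. trajectory symbols
#'
#' Emulates relative movement-trajectory descriptions: over the alphabet
#' `{a, b, c, d, e}` ("keep direction", "slightly left", "hard left",
#' "slightly right", "hard right") symbols are drawn independently with
#' probabilities `{0.88, 0.05, 0.01, 0.05, 0.01}`. A heavily skewed i.i.d.
#' source like this is the regime in which m-gram coding beats
#' symbol-by-symbol Huffman.
#'
#' @param n Number of symbols to draw.
#' @param seed Optional integer seed for reproducibility.
#' @param probs Named probability vector (must sum to 1); the default is the
#'   trajectory model above.
#' @return A symbol sequence (character string of length-`n`).
#' @examples
#' gen_trajectory(20, seed = 1)
#' @export
gen_trajectory <- function(n, seed = NULL,
                           probs = c(a = 0.88, b = 0.05, c = 0.01,
                                     d = 0.05, e = 0.01)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  if (is.null(names(probs)) || any(nchar(names(probs)) != 1L)) {
    stop("'probs' must be named by single-character symbols")
  }
  if (abs(sum(probs) - 1) > 1e-12) stop("'probs' must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(names(probs), as.integer(n), replace = TRUE, prob = probs),
        collapse = "")
}

#' Generate the binary Fibonacci word by token rewriting
#'
#' Starts from the token list `(a, b)` and repeatedly rewrites each token:
#' `a -> (a, b)`, `ba -> (a, b)`, `b -> (ba)`. The rewriting acts on the
#' token list, not on the flattened string — the token `ba` is distinct from
#' adjacent `b`,`a` tokens. The concatenated sequence has equal counts of
#' both symbols (so symbol-by-symbol Huffman cannot compress it) yet only
#' i+1 distinct factors of each length i, making it extremely compressible
#' with long grams. Token-list lengths follow the Fibonacci recurrence.
#'
#' @param iterations Number of rewriting iterations (>= 1); iteration 1 is
#'   the start list `(a, b)`.
#' @param min_length Alternative stopping rule: iterate until the
#'   concatenated sequence has at least this many symbols. Exactly one of
#'   `iterations` and `min_length` must be given.
#' @return The concatenated symbol sequence, with the token list attached as
#'   attribute `"tokens"`.
#' @examples
#' gen_fibonacci(4)  # "abbaababba"
#' @export
gen_fibonacci <- function(iterations = NULL, min_length = NULL) {
  if (is.null(iterations) == is.null(min_length)) {
    stop("give exactly one of 'iterations' and 'min_length'")
  }
  tokens <- c("a", "b")
  rewrite <- function(tok) {
    unlist(lapply(tok, function(t) if (t == "b") "ba" else c("a", "b")),
           use.names = FALSE)
  }
  if (!is.null(iterations)) {
    if (iterations < 1) stop("'iterations' must be >= 1")
    it <- 1L
    while (it < iterations) {
      tokens <- rewrite(tokens)
      it <- it + 1L
    }
  } else {
    if (min_length < 2) stop("'min_length' must be >= 2")
    while (sum(nchar(tokens)) < min_length) tokens <- rewrite(tokens)
  }
  out <- paste(tokens, collapse = "")
  attr(out, "tokens") <- tokens
  out
}

#' Split a sequence into contiguous pattern and test parts
#'
#' The pattern part (a prefix of `round(pattern_fraction * n)` symbols) is
#' used to estimate gram statistics and build codewords; the remainder is
#' the data actually encoded.
#'
#' @param x Symbol sequence.
#' @param pattern_fraction Fraction in (0, 1) of symbols assigned to the
#'   pattern part.
#' @return List with elements `pattern` and `test`.
#' @export
split_pattern_test <- function(x, pattern_fraction) {
  x <- as_symseq(x)
  n <- nchar(x)
  if (!is.numeric(pattern_fraction) || pattern_fraction <= 0 ||
      pattern_fraction >= 1) {
    stop("'pattern_fraction' must be in (0, 1)")
  }
  k <- round(pattern_fraction * n)
  if (k < 1 || k >= n) stop("degenerate split")
  list(pattern = substr(x, 1L, k), test = substr(x, k + 1L, n))
}
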