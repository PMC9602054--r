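#' @title Weighted m-gram frequency tables
#' @description
#' A `gram_freqs` object is a data frame with columns `gram`, `length` and
#' `count`, carrying attributes `m` (maximum gram length) and `alpha`
#' (exponential length weight). Row order is insertion order: grams appear by
#' increasing length, then by first occurrence position in the pattern
#' sequence. That order is part of the contract — the Huffman tie policy and
#' the frequency-mode codebook files both rely on it.
#' @name gram_freqs
NULL

new_gram_freqs <- function(gram, count, m, alpha) {
  out <- data.frame(
    gram = gram,
    length = nchar(gram),
    count = as.numeric(count),
    stringsAsFactors = FALSE
  )
  attr(out, "m") <- as.integer(m)
  attr(out, "alpha") <- as.numeric(alpha)
  class(out) <- c("gram_freqs", "data.frame")
  out
}

is_gram_freqs <- function(x) inherits(x, "gram_freqs")

#' Estimate alpha-weighted m-gram frequencies from pattern data
#'
#' Slides windows of every length `i = 1..m` over the pattern sequence and
#' adds `i^alpha` to the count of each windowed gram. With `alpha = 0` the
#' counts are plain occurrence counts; `alpha > 0` boosts long grams so that
#' they earn shorter codewords. The scan is outer over window length, inner
#' over start position, which fixes the insertion order of the table.
#'
#' @param pattern Pattern symbol sequence (statistics source), see
#'   [as_symseq()].
#' @param m Maximum gram length, a positive integer not exceeding the pattern
#'   length.
#' @param alpha Non-negative exponential length weight. `alpha = 1` weights a
#'   length-i gram occurrence by i; counts stay exact integers for integer
#'   `alpha`.
#' @return A [gram_freqs] table.
#' @examples
#' estimate_frequencies("aaaaaaab", m = 3, alpha = 1)
#' @export
estimate_frequencies <- function(pattern, m, alpha = 1) {
  pattern <- as_symseq(pattern)
  n <- nchar(pattern)
  if (n == 0L) stop("empty input")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("'m' must be a positive integer")
  }
  m <- as.integer(m)
  if (m > n) stop("m exceeds data size")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("'alpha' must be a non-negative number")
  }

  grams <- vector("list", m)
  counts <- vector("list", m)
  for (i in seq_len(m)) {
    starts <- seq_len(n - i + 1L)
    windows <- substring(pattern, starts, starts + i - 1L)
    f <- factor(windows, levels = unique(windows))
    grams[[i]] <- levels(f)
    counts[[i]] <- tabulate(f) * i^alpha
  }
  new_gram_freqs(unlist(grams), unlist(counts), m, alpha)
}

#' Prune a frequency table to its most frequent multi-symbol grams
#'
#' Keeps every length-1 gram unconditionally (all single symbols must stay
#' encodable) and, among grams of length >= 2, the `ceiling(keep_fraction * k)`
#' highest-count ones, where `k` is the number of multi-symbol grams. Count
#' ties are broken in favour of the earlier-inserted gram; survivors keep
#' their counts and relative order.
#'
#' @param freqs A [gram_freqs] table.
#' @param keep_fraction Fraction in `[0, 1]` of multi-symbol grams to retain.
#' @return A pruned [gram_freqs] table.
#' @export
prune_frequencies <- function(freqs, keep_fraction) {
  if (!is_gram_freqs(freqs)) stop("'freqs' must be a gram_freqs table")
  if (nrow(freqs) == 0L) stop("empty frequency table")
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      is.na(keep_fraction) || keep_fraction < 0 || keep_fraction > 1) {
    stop("'keep_fraction' must be a number in [0, 1]")
  }
  singles <- which(freqs$length == 1L)
  multi <- which(freqs$length >= 2L)
  k <- as.integer(ceiling(keep_fraction * length(multi)))
  keep_multi <- if (k > 0L) {
    ranked <- multi[order(-freqs$count[multi], multi)]
    ranked[seq_len(k)]
  } else {
    integer(0)
  }
  idx <- sort(c(singles, keep_multi))
  out <- freqs[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- attr(freqs, "m")
  attr(out, "alpha") <- attr(freqs, "alpha")
  class(out) <- class(freqs)
  out
}

#' Write / read a frequency table as tab-separated text
#'
#' One line per gram with fields gram (escaped), length and count, preceded
#' by header comments recording `m` and `alpha`. Integer counts round-trip
#' exactly; general counts round-trip to full double precision.
#'
#' @param freqs A [gram_freqs] table.
#' @param path File path.
#' @return `write_frequencies()` returns `path` invisibly; `read_frequencies()`
#'   returns a [gram_freqs] table.
#' @export
write_frequencies <- function(freqs, path) {
  if (!is_gram_freqs(freqs)) stop("'freqs' must be a gram_freqs table")
  lines <- c(
    "#gramhuff-frequencies\tv1",
    sprintf("#m\t%d", attr(freqs, "m")),
    sprintf("#alpha\t%s", format_num(attr(freqs, "alpha"))),
    sprintf("%s\t%d\t%s",
            escape_gram(freqs$gram), freqs$length,
            vapply(freqs$count, format_num, character(1)))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L || !startsWith(lines[[1L]], "#gramhuff-frequencies")) {
    stop("not a gramhuff frequency file")
  }
  m <- as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]][2L])
  alpha <- as.numeric(strsplit(lines[[3L]], "\t", fixed = TRUE)[[1L]][2L])
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  gram <- unescape_gram(vapply(parts, `[[`, character(1), 1L))
  count <- as.numeric(vapply(parts, `[[`, character(1), 3L))
  new_gram_freqs(gram, count, m, alpha)
}

# Full-precision plain-text number: integers without exponent, doubles with
# 17 significant digits.
format_num <- function(x) {
  if (!is.na(x) && x == round(x) && abs(x) < 2^53) {
    sprintf("%.0f", x)
  } else {
    sprintf("%.17g", x)
  }
}

# Escape a gram for line-oriented files: backslash, tab, newline, carriage
# return and other control characters become backslash sequences.
escape_gram <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  vapply(x, function(s) {
    cp <- utf8ToInt(s)
    if (!anyNA(cp) && any(cp < 32L)) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      ctrl <- utf8ToInt(s) < 32L
      chars[ctrl] <- sprintf("\\u%04X", utf8ToInt(s)[ctrl])
      s <- paste(chars, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

unescape_gram <- function(x) {
  vapply(x, function(s) {
    out <- character(0)
    i <- 1L
    n <- nchar(s)
    while (i <= n) {
      ch <- substr(s, i, i)
      if (ch == "\\" && i < n) {
        nxt <- substr(s, i + 1L, i + 1L)
        if (nxt == "u") {
          code <- strtoi(substr(s, i + 2L, i + 5L), base = 16L)
          out <- c(out, intToUtf8(code))
          i <- i + 6L
        } else {
          out <- c(out, switch(nxt,
            "\\" = "\\", "t" = "\t", "n" = "\n", "r" = "\r",
            stop("bad escape in gram")))
          i <- i + 2L
        }
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
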