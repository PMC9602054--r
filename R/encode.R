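new_encoding <- function(codes, parse) {
  structure(list(bits = paste(codes, collapse = ""), parse = parse),
            class = "gram_encoding")
}

#' Number of payload bits in an encoding
#' @param x A `gram_encoding`, a 0/1 string, or a bit count.
#' @return Integer bit count.
#' @export
n_bits <- function(x) {
  if (inherits(x, "gram_encoding")) return(nchar(x$bits))
  if (is.character(x)) return(nchar(x))
  as.integer(x)
}

#' @export
print.gram_encoding <- function(x, ...) {
  cat(sprintf("gram encoding: %d bits, %d grams\n", nchar(x$bits),
              length(x$parse)))
  if (nchar(x$bits) <= 64L) cat("bits:", x$bits, "\n")
  invisible(x)
}

check_encodable <- function(input, book) {
  singles <- names(book)[nchar(names(book)) == 1L]
  if (!all(unique(strsplit(input, "", fixed = TRUE)[[1L]]) %in% singles)) {
    stop("unencodable symbol")
  }
}

#' Optimal minimum-bit parse of a sequence into codebook grams
#'
#' Finds the segmentation of the input into codebook grams (lengths 1..m)
#' whose concatenated codewords are globally shortest. The search space is a
#' multistage graph over input positions 0..n, with an edge i -> j for every
#' codebook gram equal to `input[i+1..j]`; the shortest 0 -> n path, weighted
#' by codeword length, is computed by dynamic programming. Since edges only
#' move forward, a single pass in ascending position order suffices; the trie
#' from [build_trie()] enumerates the outgoing edges of a position in one
#' walk. Ties are resolved first-found: predecessors are scanned in ascending
#' position order and only strict improvements replace the incumbent.
#'
#' Grams absent from a pruned codebook simply contribute no edge; the parse
#' always exists because every single symbol carries a codeword.
#'
#' @param input Symbol sequence to encode.
#' @param book A `gram_codebook` containing every single symbol of the input.
#' @param m Maximum gram length to consider; defaults to the codebook's.
#' @return A `gram_encoding`: list with `bits` (0/1 string) and `parse`
#'   (character vector of grams whose codewords were concatenated).
#' @examples
#' book <- train_codebook("aaaaaaab", m = 3, alpha = 1)
#' encode_optimal("aaaaaaab", book)
#' @export
encode_optimal <- function(input, book, m = attr(book, "m")) {
  if (!inherits(book, "gram_codebook")) stop("'book' must be a gram_codebook")
  input <- as_symseq(input)
  n <- nchar(input)
  if (n == 0L) return(new_encoding(character(0), character(0)))
  check_encodable(input, book)
  m <- as.integer(m)
  syms <- strsplit(input, "", fixed = TRUE)[[1L]]
  trie <- build_trie(book)

  f <- rep(Inf, n + 1L)       # f[j + 1]: best bit length to reach position j
  f[1L] <- 0
  back <- integer(n + 1L)     # predecessor position
  code <- character(n + 1L)   # codeword of the gram ending at j

  for (i in 0:(n - 1L)) {
    fi <- f[i + 1L]
    if (!is.finite(fi)) next
    cur <- trie
    for (d in seq_len(min(m, n - i))) {
      cur <- get0(syms[i + d], envir = cur$kids, inherits = FALSE)
      if (is.null(cur)) break
      cw <- cur$code
      if (!is.null(cw)) {
        j <- i + d
        cand <- fi + nchar(cw)
        if (cand < f[j + 1L]) {
          f[j + 1L] <- cand
          back[j + 1L] <- i
          code[j + 1L] <- cw
        }
      }
    }
  }
  if (!is.finite(f[n + 1L])) stop("unencodable symbol")

  codes <- character(0)
  parse <- character(0)
  j <- n
  while (j > 0L) {
    i <- back[j + 1L]
    codes <- c(code[j + 1L], codes)
    parse <- c(substr(input, i + 1L, j), parse)
    j <- i
  }
  new_encoding(codes, parse)
}

#' Greedy approximate parse by the symbols-per-bit ratio
#'
#' Linear-time alternative to [encode_optimal()]: at each position it scans
#' candidate grams of length 1..m (clamped at the end of the input), skips
#' grams without a codeword, and keeps the candidate with the strictly
#' highest ratio of gram length to codeword length — on ties the earlier
#' (shorter) candidate wins. The chosen codeword is emitted and the position
#' advances by the gram length. Greedy output is never shorter than the
#' optimal parse but is computed in O(mn).
#'
#' @inheritParams encode_optimal
#' @return A `gram_encoding`.
#' @examples
#' book <- train_codebook("aaaaaaab", m = 3, alpha = 1)
#' encode_greedy("aaaaaaab", book)
#' @export
encode_greedy <- function(input, book, m = attr(book, "m")) {
  if (!inherits(book, "gram_codebook")) stop("'book' must be a gram_codebook")
  input <- as_symseq(input)
  n <- nchar(input)
  if (n == 0L) return(new_encoding(character(0), character(0)))
  check_encodable(input, book)
  m <- as.integer(m)
  dc <- list2env(as.list(unclass(book)), hash = TRUE, parent = emptyenv())

  codes <- character(64L)
  parse <- character(64L)
  np <- 0L
  i <- 0L
  while (i < n) {
    r <- 0
    l <- 0L
    best_cw <- NULL
    for (k in seq_len(m)) {
      j <- i + k
      if (j > n) j <- n
      s <- substr(input, i + 1L, j)
      cw <- get0(s, envir = dc, inherits = FALSE)
      if (is.null(cw)) next
      t <- (j - i) / nchar(cw)
      if (t > r) {
        r <- t
        l <- j
        best_cw <- cw
      }
    }
    if (l == 0L) stop("unencodable symbol")
    np <- np + 1L
    if (np > length(codes)) {  # grow by doubling
      length(codes) <- 2L * length(codes)
      length(parse) <- 2L * length(parse)
    }
    codes[np] <- best_cw
    parse[np] <- substr(input, i + 1L, l)
    i <- l
  }
  new_encoding(codes[seq_len(np)], parse[seq_len(np)])
}
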