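#' Build a symbol-indexed trie over a codebook's grams
#'
#' The trie lets the optimal parser enumerate, in a single walk of at most
#' `m` symbols, every codebook gram that starts at a given input position:
#' each node corresponds to a gram prefix, and nodes whose path spells a
#' codebook gram carry its codeword.
#'
#' @param book A `gram_codebook`.
#' @return A `gram_trie` of environment nodes; each node has a `kids`
#'   environment keyed by symbol and a `code` field (codeword string or
#'   `NULL`).
#' @export
build_trie <- function(book) {
  if (!inherits(book, "gram_codebook")) stop("'book' must be a gram_codebook")
  if (length(book) == 0L) stop("empty codebook")
  root <- new_trie_node()
  grams <- names(book)
  for (idx in seq_along(grams)) {
    cur <- root
    for (ch in strsplit(grams[[idx]], "", fixed = TRUE)[[1L]]) {
      nxt <- get0(ch, envir = cur$kids, inherits = FALSE)
      if (is.null(nxt)) {
        nxt <- new_trie_node()
        assign(ch, nxt, envir = cur$kids)
      }
      cur <- nxt
    }
    cur$code <- book[[idx]]
  }
  class(root) <- "gram_trie"
  root
}

new_trie_node <- function() {
  node <- new.env(parent = emptyenv())
  node$kids <- new.env(parent = emptyenv())
  node$code <- NULL
  node
}

#' Count the marked (codeword-carrying) nodes of a trie
#'
#' Equals the codebook size by construction.
#'
#' @param trie A `gram_trie`.
#' @return Integer count.
#' @export
trie_size <- function(trie) {
  count <- function(node) {
    n <- if (!is.null(node$code)) 1L else 0L
    for (ch in ls(node$kids, all.names = TRUE)) {
      n <- n + count(get(ch, envir = node$kids, inherits = FALSE))
    }
    n
  }
  count(trie)
}
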