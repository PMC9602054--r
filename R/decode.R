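#' Build the bit-indexed decode tree of a prefix-free codebook
#'
#' Inverse index of a codebook: a binary tree in which 0 selects the left
#' and 1 the right child, and every codeword path ends at a leaf carrying
#' its gram. Construction fails if any codeword is a prefix of another.
#'
#' @param book A `gram_codebook`.
#' @return A `gram_decode_tree` of environment nodes with fields `zero`,
#'   `one` and `gram`; attribute `n_leaves` equals the codebook size.
#' @export
build_decode_tree <- function(book) {
  if (length(book) == 0L) stop("empty codebook")
  root <- new_decode_node()
  grams <- names(book)
  for (idx in seq_along(grams)) {
    cur <- root
    bits <- strsplit(book[[idx]], "", fixed = TRUE)[[1L]]
    for (b in bits) {
      if (!is.null(cur$gram)) stop("invalid codebook")  # codeword under a leaf
      nxt <- if (b == "0") cur$zero else cur$one
      if (is.null(nxt)) {
        nxt <- new_decode_node()
        if (b == "0") cur$zero <- nxt else cur$one <- nxt
      }
      cur <- nxt
    }
    if (!is.null(cur$gram) || !is.null(cur$zero) || !is.null(cur$one)) {
      stop("invalid codebook")  # duplicate or prefix of an existing codeword
    }
    cur$gram <- grams[[idx]]
  }
  attr(root, "n_leaves") <- length(book)
  class(root) <- "gram_decode_tree"
  root
}

new_decode_node <- function() {
  node <- new.env(parent = emptyenv())
  node$zero <- NULL
  node$one <- NULL
  node$gram <- NULL
  node
}

#' Decode a bitstring by walking the decode tree
#'
#' Reads bits left to right, descending from the root (0 = left, 1 = right);
#' each leaf reached emits its gram and restarts the walk. The bitstring
#' must be an exact concatenation of codewords.
#'
#' @param bits A `gram_encoding`, or a character string of 0/1 bits.
#' @param tree A `gram_decode_tree` from [build_decode_tree()].
#' @return The decoded symbol sequence (character string).
#' @examples
#' book <- train_codebook("aaaaaaab", m = 3, alpha = 1)
#' tree <- build_decode_tree(book)
#' decode_bits(encode_optimal("aaaaaaab", book), tree)
#' @export
decode_bits <- function(bits, tree) {
  if (!inherits(tree, "gram_decode_tree")) {
    stop("'tree' must be a gram_decode_tree")
  }
  if (inherits(bits, "gram_encoding")) bits <- bits$bits
  if (!is.character(bits) || length(bits) != 1L) {
    stop("'bits' must be a single 0/1 string")
  }
  if (nchar(bits) == 0L) return("")
  vals <- as.integer(charToRaw(bits)) - 48L
  if (any(vals < 0L | vals > 1L)) stop("'bits' must contain only 0 and 1")

  out <- character(64L)
  k <- 0L
  cur <- tree
  for (b in vals) {
    cur <- if (b == 0L) cur$zero else cur$one
    if (is.null(cur)) stop("corrupt stream")
    if (!is.null(cur$gram)) {
      k <- k + 1L
      if (k > length(out)) length(out) <- 2L * length(out)
      out[k] <- cur$gram
      cur <- tree
    }
  }
  if (!identical(cur, tree)) stop("truncated stream")
  paste(out[seq_len(k)], collapse = "")
}
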