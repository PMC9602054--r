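#' Build a Huffman code tree over a gram frequency table
#'
#' Standard bottom-up Huffman merging: repeatedly take the two live nodes
#' with the smallest weights and join them under a fresh internal node whose
#' weight is their sum. Because the bit assignment of a Huffman code is
#' arbitrary, the tree is made deterministic by a canonical tie policy:
#'
#' * every node carries a creation index — leaves are numbered first, in the
#'   insertion order of the frequency table, then internal nodes in merge
#'   order;
#' * among equal weights the node with the smaller creation index is merged
#'   first;
#' * of the two merged nodes, the smaller weight becomes the left ("0")
#'   child; on a weight tie the smaller creation index does.
#'
#' The policy only fixes which of the many optimal codes is produced; the
#' weighted code length is the same for all of them.
#'
#' @param freqs A [gram_freqs] table with at least one row.
#' @return A `huffman_tree`: nested lists with fields `weight`, `creation`,
#'   and either `gram` (leaf) or `left`/`right` (internal node).
#' @examples
#' tr <- build_huffman_tree(estimate_frequencies("aaaaaaab", 3, alpha = 1))
#' extract_codewords(tr)
#' @export
build_huffman_tree <- function(freqs) {
  if (!is_gram_freqs(freqs)) stop("'freqs' must be a gram_freqs table")
  k <- nrow(freqs)
  if (k == 0L) stop("empty frequency table")

  pool <- vector("list", k)
  for (i in seq_len(k)) {
    pool[[i]] <- list(weight = freqs$count[i], creation = i,
                      gram = freqs$gram[i])
  }
  weight <- freqs$count
  creation <- seq_len(k)
  next_creation <- k + 1L

  while (length(pool) > 1L) {
    ord <- order(weight, creation)
    a <- ord[1L]  # smaller (weight, creation): becomes the "0" child
    b <- ord[2L]
    merged <- list(weight = weight[a] + weight[b], creation = next_creation,
                   left = pool[[a]], right = pool[[b]])
    drop <- c(a, b)
    pool <- c(pool[-drop], list(merged))
    weight <- c(weight[-drop], merged$weight)
    creation <- c(creation[-drop], next_creation)
    next_creation <- next_creation + 1L
  }
  structure(pool[[1L]], class = "huffman_tree")
}

is_leaf <- function(node) !is.null(node$gram)

#' Extract prefix-free codewords from a Huffman tree
#'
#' Walks root-to-leaf paths, emitting "0" for the left and "1" for the right
#' child. A single-leaf tree (one-gram table) gets the one-bit codeword "0"
#' so degenerate inputs remain encodable.
#'
#' @param tree A `huffman_tree` from [build_huffman_tree()].
#' @return A `gram_codebook`: named character vector mapping grams to 0/1
#'   codeword strings, ordered by the leaves' creation index (i.e. the
#'   frequency table's insertion order), with attribute `m` set to the
#'   longest gram.
#' @export
extract_codewords <- function(tree) {
  if (!inherits(tree, "huffman_tree")) stop("'tree' must be a huffman_tree")
  grams <- character(0)
  codes <- character(0)
  creations <- integer(0)
  if (is_leaf(tree)) {
    grams <- tree$gram
    codes <- "0"
    creations <- tree$creation
  } else {
    walk <- function(node, prefix) {
      if (is_leaf(node)) {
        grams <<- c(grams, node$gram)
        codes <<- c(codes, prefix)
        creations <<- c(creations, node$creation)
      } else {
        walk(node$left, paste0(prefix, "0"))
        walk(node$right, paste0(prefix, "1"))
      }
    }
    walk(tree, "")
  }
  ord <- order(creations)
  book <- codes[ord]
  names(book) <- grams[ord]
  new_codebook(book)
}

new_codebook <- function(book, alpha = NA_real_) {
  attr(book, "m") <- max(nchar(names(book)))
  attr(book, "alpha") <- alpha
  class(book) <- "gram_codebook"
  book
}

#' Construct a codebook directly from explicit gram/codeword pairs
#'
#' @param codewords Named character vector: names are grams, values are 0/1
#'   codeword strings. Must be prefix-free.
#' @return A `gram_codebook`.
#' @export
as_codebook <- function(codewords) {
  if (is.null(names(codewords)) || any(!nzchar(names(codewords)))) {
    stop("codewords must be named by their grams")
  }
  if (any(grepl("[^01]", codewords)) || any(!nzchar(codewords))) {
    stop("codewords must be non-empty 0/1 strings")
  }
  book <- new_codebook(unclass(codewords))
  build_decode_tree(book)  # validates prefix-freeness
  book
}

#' Train a gram codebook from pattern data
#'
#' Convenience pipeline: [estimate_frequencies()], [prune_frequencies()],
#' [build_huffman_tree()], [extract_codewords()].
#'
#' @inheritParams estimate_frequencies
#' @inheritParams prune_frequencies
#' @return A `gram_codebook` with the pruned frequency table attached as
#'   attribute `"freqs"` (used for frequency-mode codebook files).
#' @examples
#' train_codebook("aaaaaaab", m = 3, alpha = 1)
#' @export
train_codebook <- function(pattern, m, alpha = 1, keep_fraction = 1) {
  freqs <- estimate_frequencies(pattern, m, alpha)
  freqs <- prune_frequencies(freqs, keep_fraction)
  book <- extract_codewords(build_huffman_tree(freqs))
  attr(book, "alpha") <- attr(freqs, "alpha")
  attr(book, "freqs") <- freqs
  book
}

#' First-order entropy of a symbol distribution
#'
#' `H = -sum(p * log2(p))` in bits per symbol, the information-theoretic
#' floor for symbol-by-symbol coding. Counts are accepted and normalised.
#'
#' @param p Numeric vector of probabilities (or positive counts).
#' @return Entropy in bits per symbol.
#' @examples
#' first_order_entropy(c(22, 15, 5) / 42)
#' @export
first_order_entropy <- function(p) {
  if (!is.numeric(p) || length(p) == 0L) stop("'p' must be a numeric vector")
  if (any(is.na(p)) || any(p <= 0)) {
    stop("probabilities must be positive")
  }
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Average codeword length under a frequency table
#'
#' Weighted mean codeword length `sum(count * nchar(code)) / sum(count)` in
#' bits per table entry; for a single-symbol table this is bits per input
#' symbol. The raw weighted bit total is attached as attribute
#' `"total_bits"`.
#'
#' @param book A `gram_codebook` covering every gram of `freqs`.
#' @param freqs A [gram_freqs] table.
#' @return Average length (numeric) with attribute `total_bits`.
#' @export
average_code_length <- function(book, freqs) {
  if (!inherits(book, "gram_codebook")) stop("'book' must be a gram_codebook")
  if (!is_gram_freqs(freqs)) stop("'freqs' must be a gram_freqs table")
  cw <- unclass(book)[freqs$gram]
  if (anyNA(cw)) stop("missing codeword for gram in frequency table")
  total <- sum(freqs$count * nchar(cw))
  avg <- total / sum(freqs$count)
  attr(avg, "total_bits") <- total
  avg
}

#' @export
print.gram_codebook <- function(x, ...) {
  cat(sprintf("gram codebook: %d grams, max gram length m = %d\n",
              length(x), attr(x, "m")))
  df <- data.frame(gram = names(x), codeword = unclass(unname(x)),
                   stringsAsFactors = FALSE)
  print(df, ...)
  invisible(x)
}
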