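#' Normalise a symbol sequence
#'
#' Throughout gramhuff a symbol sequence is an ordinary character string in
#' which every character is one symbol. This keeps gram keys (substrings)
#' unambiguous and lets the coders use fast substring arithmetic. Vectors of
#' single-symbol strings are collapsed; anything else is rejected.
#'
#' @param x A character scalar (one symbol per character) or a character
#'   vector of single-character symbols.
#' @return A character scalar.
#' @examples
#' as_symseq(c("a", "c", "g", "t"))
#' @export
as_symseq <- function(x) {
  if (!is.character(x)) stop("symbol sequence must be character")
  if (length(x) == 1L) return(x)
  if (any(nchar(x) != 1L)) {
    stop("symbol vectors must contain single-character symbols")
  }
  paste(x, collapse = "")
}

#' Alphabet of a symbol sequence
#'
#' @param x A symbol sequence (see [as_symseq()]).
#' @return Sorted character vector of the distinct symbols.
#' @export
seq_alphabet <- function(x) {
  x <- as_symseq(x)
  sort(unique(strsplit(x, "", fixed = TRUE)[[1L]]))
}

#' Split a sequence into its symbols
#' @param x A symbol sequence.
#' @return Character vector, one element per symbol.
#' @export
seq_symbols <- function(x) {
  x <- as_symseq(x)
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}
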