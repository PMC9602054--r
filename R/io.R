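#' Read a FASTA file as one symbol sequence
#'
#' Concatenates the sequence lines of all records (headers excluded) and
#' uppercases them, yielding one symbol per residue — the natural input for
#' coding DNA over `{A, C, G, T}`.
#'
#' @param path Path to a FASTA file.
#' @return A symbol sequence (character string).
#' @export
read_fasta <- function(path) {
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("not a FASTA file"))
  if (length(recs) == 0L) stop("not a FASTA file")
  toupper(paste(as.character(recs), collapse = ""))
}

# Byte <-> symbol mapping for byte granularity: byte value v becomes the
# single character U+0001+v, so every byte (including 0) is one character
# and gram keys stay unambiguous.
bytes_to_symbols <- function(raw) {
  if (length(raw) == 0L) return("")
  intToUtf8(as.integer(raw) + 1L)
}

symbols_to_bytes <- function(x) {
  if (nchar(x) == 0L) return(raw(0))
  as.raw(utf8ToInt(x) - 1L)
}

#' Read a file as a symbol sequence at a chosen granularity
#'
#' * `"byte"`: one symbol per byte (byte value v maps to the character
#'   `U+0001 + v`);
#' * `"char"`: one symbol per text character (UTF-8);
#' * `"bit"`: one symbol per bit, most-significant bit first within each
#'   byte, as the characters "0"/"1".
#'
#' @param path File path.
#' @param granularity One of `"byte"`, `"char"`, `"bit"`.
#' @return A symbol sequence (character string).
#' @export
read_symbols <- function(path, granularity = c("byte", "char", "bit")) {
  granularity <- match.arg(granularity)
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  switch(granularity,
    byte = bytes_to_symbols(raw),
    char = {
      s <- rawToChar(raw)
      Encoding(s) <- "UTF-8"
      s
    },
    bit = unpack_bitstring(raw, 8L * length(raw))
  )
}

#' Write a symbol sequence back to a file at a chosen granularity
#'
#' Inverse of [read_symbols()]; with `"bit"` granularity the number of
#' symbols must be a multiple of 8.
#'
#' @param x Symbol sequence.
#' @inheritParams read_symbols
#' @return `path`, invisibly.
#' @export
write_symbols <- function(x, path, granularity = c("byte", "char", "bit")) {
  granularity <- match.arg(granularity)
  raw <- switch(granularity,
    byte = symbols_to_bytes(x),
    char = charToRaw(enc2utf8(x)),
    bit = {
      if (nchar(x) %% 8L != 0L) stop("bit count not a multiple of 8")
      pack_bitstring(x)
    }
  )
  writeBin(raw, path)
  invisible(path)
}

# Pack a 0/1 string into raw bytes, MSB first, zero-padded to a byte
# boundary. (base packBits is LSB-first per byte, hence the explicit
# weights.)
pack_bitstring <- function(bits) {
  nb <- nchar(bits)
  if (nb == 0L) return(raw(0))
  vals <- as.integer(charToRaw(bits)) - 48L
  pad <- (-nb) %% 8L
  if (pad > 0L) vals <- c(vals, integer(pad))
  mat <- matrix(vals, nrow = 8L)
  as.raw(colSums(mat * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L)))
}

unpack_bitstring <- function(raw, nbits) {
  if (nbits == 0L) return("")
  vals <- as.integer(raw)
  bits <- integer(8L * length(vals))
  for (k in 0:7) {  # bit 7-k of each byte, MSB first
    bits[seq_along(vals) * 8L - 7L + k] <- (vals %/% 2L^(7L - k)) %% 2L
  }
  rawToChar(as.raw(bits[seq_len(nbits)] + 48L))
}

granularity_codes <- c(byte = 1L, char = 2L, bit = 3L)

#' Write / read a codebook file
#'
#' Line-oriented text with header comments (`mode`, `m`, `alpha`,
#' `granularity`) followed by one record per gram. Two modes:
#'
#' * `"codewords"`: explicit `gram <TAB> codeword` records;
#' * `"frequencies"`: `gram <TAB> count` records in the frequency table's
#'   insertion order — enough for the reader to rebuild bit-identical
#'   codewords via the deterministic tie policy of [build_huffman_tree()],
#'   mirroring the classical practice of transmitting frequencies instead of
#'   codes.
#'
#' @param book A `gram_codebook`; frequency mode requires the table trained
#'   by [train_codebook()] (attribute `"freqs"`).
#' @param path File path.
#' @param mode `"codewords"` or `"frequencies"`.
#' @param granularity Recorded for downstream decoding (`"byte"`, `"char"`,
#'   `"bit"`).
#' @return `write_codebook()` returns `path` invisibly; `read_codebook()`
#'   returns a `gram_codebook` with attribute `"granularity"` (and
#'   `"freqs"` in frequency mode).
#' @export
write_codebook <- function(book, path, mode = c("codewords", "frequencies"),
                           granularity = "char") {
  mode <- match.arg(mode)
  if (!inherits(book, "gram_codebook")) stop("'book' must be a gram_codebook")
  header <- c(
    "#gramhuff-codebook\tv1",
    sprintf("#mode\t%s", mode),
    sprintf("#m\t%d", attr(book, "m")),
    sprintf("#alpha\t%s", format_num(attr(book, "alpha"))),
    sprintf("#granularity\t%s", granularity)
  )
  body <- if (mode == "codewords") {
    sprintf("%s\t%s", escape_gram(names(book)), unclass(unname(book)))
  } else {
    freqs <- attr(book, "freqs")
    if (is.null(freqs)) stop("frequency mode needs a codebook with 'freqs'")
    sprintf("%s\t%s", escape_gram(freqs$gram),
            vapply(freqs$count, format_num, character(1)))
  }
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 5L || !startsWith(lines[[1L]], "#gramhuff-codebook")) {
    stop("not a gramhuff codebook file")
  }
  field <- function(i) strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]][2L]
  mode <- field(2L)
  m <- as.integer(field(3L))
  alpha <- as.numeric(field(4L))
  granularity <- field(5L)
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  gram <- unescape_gram(vapply(parts, `[[`, character(1), 1L))
  val <- vapply(parts, `[[`, character(1), 2L)
  book <- if (mode == "codewords") {
    b <- val
    names(b) <- gram
    new_codebook(b, alpha = alpha)
  } else if (mode == "frequencies") {
    freqs <- new_gram_freqs(gram, as.numeric(val), m, alpha)
    b <- extract_codewords(build_huffman_tree(freqs))
    attr(b, "alpha") <- alpha
    attr(b, "freqs") <- freqs
    b
  } else {
    stop("unknown codebook mode: ", mode)
  }
  attr(book, "granularity") <- granularity
  book
}

#' Encoded container blocks
#'
#' A self-describing binary container for one encoded payload: magic tag,
#' format version, granularity, `m`, `alpha`, an embedded codebook (explicit
#' codewords, an insertion-ordered frequency table for canonical rebuild, or
#' an "external" marker when the codewords are known out of band), the exact
#' payload bit count, and the payload packed MSB-first and zero-padded to a
#' byte boundary.
#'
#' @param bits A `gram_encoding` or 0/1 string.
#' @param granularity `"byte"`, `"char"` or `"bit"` — how the original file
#'   was symbolised.
#' @param m,alpha Coding parameters, recorded for provenance.
#' @param codebook The `gram_codebook` to embed (ignored for
#'   `codebook_mode = "none"`).
#' @param codebook_mode `"explicit"`, `"frequencies"` or `"none"`.
#' @return An `encoded_block` list.
#' @export
encoded_block <- function(bits, granularity = "char", m = NA_integer_,
                          alpha = NA_real_, codebook = NULL,
                          codebook_mode = c("explicit", "frequencies",
                                            "none")) {
  codebook_mode <- match.arg(codebook_mode)
  if (inherits(bits, "gram_encoding")) bits <- bits$bits
  if (!granularity %in% names(granularity_codes)) {
    stop("unknown granularity: ", granularity)
  }
  if (codebook_mode != "none" && is.null(codebook)) {
    stop("embedding a codebook requires 'codebook'")
  }
  if (codebook_mode == "frequencies" && is.null(attr(codebook, "freqs"))) {
    stop("frequency mode needs a codebook with 'freqs'")
  }
  structure(list(
    version = 1L,
    granularity = granularity,
    m = as.integer(m),
    alpha = as.numeric(alpha),
    codebook_mode = codebook_mode,
    codebook = if (codebook_mode == "none") NULL else codebook,
    payload_bit_count = nchar(bits),
    bits = bits
  ), class = "encoded_block")
}

block_magic <- charToRaw("GHUF")

#' Write / read an encoded container block
#'
#' Bit-exact round-trip; the reader rejects a bad magic tag, an unsupported
#' version, and truncated or length-inconsistent payloads with distinct
#' errors.
#'
#' @param block An [encoded_block()].
#' @param path File path.
#' @return `write_block()` returns `path` invisibly; `read_block()` returns
#'   an `encoded_block`.
#' @export
write_block <- function(block, path) {
  if (!inherits(block, "encoded_block")) stop("'block' must be an encoded_block")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(block_magic, con)
  writeBin(as.raw(block$version), con)
  writeBin(as.raw(granularity_codes[[block$granularity]]), con)
  writeBin(as.integer(block$m), con, size = 4L, endian = "little")
  writeBin(as.numeric(block$alpha), con, size = 8L, endian = "little")
  mode_code <- switch(block$codebook_mode,
                      none = 0L, explicit = 1L, frequencies = 2L)
  writeBin(as.raw(mode_code), con)
  if (mode_code == 1L) {
    book <- block$codebook
    writeBin(length(book), con, size = 4L, endian = "little")
    for (i in seq_along(book)) {
      g <- charToRaw(enc2utf8(names(book)[i]))
      writeBin(length(g), con, size = 4L, endian = "little")
      writeBin(g, con)
      cw <- charToRaw(book[[i]])
      writeBin(length(cw), con, size = 4L, endian = "little")
      writeBin(cw, con)
    }
  } else if (mode_code == 2L) {
    freqs <- attr(block$codebook, "freqs")
    writeBin(nrow(freqs), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(freqs))) {
      g <- charToRaw(enc2utf8(freqs$gram[i]))
      writeBin(length(g), con, size = 4L, endian = "little")
      writeBin(g, con)
      writeBin(freqs$count[i], con, size = 8L, endian = "little")
    }
  }
  writeBin(as.numeric(block$payload_bit_count), con, size = 8L,
           endian = "little")
  writeBin(pack_bitstring(block$bits), con)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  con <- rawConnection(raw_all)
  on.exit(close(con))
  need <- function(what, ...) {
    out <- tryCatch(readBin(con, what, ...), error = function(e) NULL)
    out
  }
  magic <- need("raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, block_magic)) {
    stop("bad magic")
  }
  version <- as.integer(need("raw", n = 1L))
  if (!identical(version, 1L)) stop("unsupported container version")
  gcode <- as.integer(need("raw", n = 1L))
  granularity <- names(granularity_codes)[match(gcode, granularity_codes)]
  if (is.na(granularity)) stop("truncated container")
  m <- need("integer", n = 1L, size = 4L, endian = "little")
  alpha <- need("numeric", n = 1L, size = 8L, endian = "little")
  mode_code <- as.integer(need("raw", n = 1L))
  if (length(mode_code) == 0L) stop("truncated container")
  read_str <- function() {
    len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(len) == 0L) stop("truncated container")
    b <- readBin(con, "raw", n = len)
    if (length(b) < len) stop("truncated container")
    s <- rawToChar(b)
    Encoding(s) <- "UTF-8"
    s
  }
  codebook <- NULL
  codebook_mode <- c("none", "explicit", "frequencies")[mode_code + 1L]
  if (is.na(codebook_mode)) stop("truncated container")
  if (codebook_mode == "explicit") {
    cnt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    grams <- character(cnt)
    codes <- character(cnt)
    for (i in seq_len(cnt)) {
      grams[i] <- read_str()
      codes[i] <- read_str()
    }
    names(codes) <- grams
    codebook <- new_codebook(codes, alpha = alpha)
  } else if (codebook_mode == "frequencies") {
    cnt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    grams <- character(cnt)
    counts <- numeric(cnt)
    for (i in seq_len(cnt)) {
      grams[i] <- read_str()
      counts[i] <- readBin(con, "numeric", n = 1L, size = 8L,
                           endian = "little")
    }
    freqs <- new_gram_freqs(grams, counts, m, alpha)
    codebook <- extract_codewords(build_huffman_tree(freqs))
    attr(codebook, "alpha") <- alpha
    attr(codebook, "freqs") <- freqs
  }
  nbits <- need("numeric", n = 1L, size = 8L, endian = "little")
  if (length(nbits) == 0L) stop("truncated container")
  payload <- readBin(con, "raw", n = ceiling(nbits / 8))
  if (length(payload) < ceiling(nbits / 8)) stop("truncated container")
  trailing <- readBin(con, "raw", n = 1L)
  if (length(trailing) > 0L) stop("payload length mismatch")
  structure(list(
    version = version,
    granularity = granularity,
    m = m,
    alpha = alpha,
    codebook_mode = codebook_mode,
    codebook = codebook,
    payload_bit_count = as.integer(nbits),
    bits = unpack_bitstring(payload, as.integer(nbits))
  ), class = "encoded_block")
}

#' Decode an encoded container block
#'
#' @param block An `encoded_block`.
#' @param codebook Required when the block's codebook mode is `"none"`.
#' @return The decoded symbol sequence.
#' @export
decode_block <- function(block, codebook = NULL) {
  if (!inherits(block, "encoded_block")) stop("'block' must be an encoded_block")
  book <- if (block$codebook_mode == "none") {
    if (is.null(codebook)) stop("external codebook required")
    codebook
  } else {
    block$codebook
  }
  decode_bits(block$bits, build_decode_tree(book))
}
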