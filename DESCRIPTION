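Package: gramhuff
Title: Variable-to-Variable m-Gram Huffman Coding for Biological and Generic Sequences
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless variable-to-variable entropy coding that extends classical
    Huffman coding from single symbols to m-grams, i.e. runs of 1 to m consecutive
    symbols. Provides alpha-weighted sliding-window estimation of m-gram
    frequencies from pattern data, Huffman codebook construction over grams with
    a deterministic tie policy and frequency-based pruning, an optimal
    minimum-bit parser by dynamic programming over the multistage position graph
    (accelerated with a trie over the codebook grams), a linear-time greedy
    parser driven by the symbols-per-bit ratio, and a prefix-tree decoder.
    Includes readers and writers for FASTA, plain text and raw byte/bit streams,
    a self-describing container format, generators for synthetic benchmark
    corpora (i.i.d. trajectory symbols and the binary Fibonacci word), bits-per-
    symbol evaluation with an optional DEFLATE baseline, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
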