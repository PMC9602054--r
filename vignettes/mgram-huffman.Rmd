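---
title: "Variable-to-variable m-gram Huffman coding with gramhuff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-to-variable m-gram Huffman coding with gramhuff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gramhuff)
```

## The coding model

A symbol sequence `I` of length `n` over a finite alphabet `A` is encoded by
segmenting it into **grams** — contiguous runs of 1 to `m` symbols — and
concatenating one prefix-free binary codeword per gram. Classical Huffman
coding is the `m = 1` special case; its rate cannot beat the first-order
entropy `H = -Σ p_i log2 p_i`, no matter how repetitive the data. Allowing
grams up to length `m` lets the code exploit run structure: the rate is then
governed by the m-gram statistics of the source, which for DNA reads,
trajectory logs or the Fibonacci word lies far below the first-order
entropy.

Unlike Tunstall-style dual-tree schemes, no parsing tree dictates *which*
gram starts at a given position — any segmentation into codebook grams is
admissible, and the encoder's job is to pick the cheapest one. That
ambiguity is the price of approaching the m-gram entropy, and it is what
the two parsers below resolve.

The pipeline has four stages, each an exported function (and a `train /
encode / decode / eval` CLI):

1. `estimate_frequencies()` — gram statistics from *pattern* data;
2. `build_huffman_tree()` / `extract_codewords()` — the codebook;
3. `encode_optimal()` or `encode_greedy()` — the parse;
4. `decode_bits()` — reconstruction.

## Frequency estimation and the α weight

Every window of length `i = 1..m` over the pattern sequence adds `i^α` to
its gram's count (outer loop over `i`, inner over start position, which
fixes the table's insertion order). With `α = 0` the table holds plain
occurrence counts; counts stay exact integers for any integer `α`.

```{r}
estimate_frequencies("aaaaaaab", m = 3, alpha = 1)
```

The weight matters because a length-`i` gram covers `i` symbols per
codeword: leaving `α = 0` makes short grams look as valuable as long ones
and can trap the greedy parser (see below). `α = 1` — count symbols covered
rather than occurrences — is the package default; on the worked example it
is exactly the difference between the greedy parser emitting 10 bits and
matching the 7-bit optimum. Higher values over-reward rare long grams and
are exposed for experimentation only.

For large `m` the table grows too big to build a Huffman tree over, so
`prune_frequencies(keep_fraction)` keeps the `ceiling(keep_fraction * k)`
highest-count multi-symbol grams (count ties break toward the
earlier-inserted gram) — a count-based cut, chosen over a
probability-mass cut because the mandatory part of the codebook is a *count*
of symbols: every length-1 gram is always retained, which is what guarantees
that any sequence over the pattern's alphabet remains encodable, pruned or
not.

## The codebook and the canonical tie policy

The Huffman construction itself is the textbook one: repeatedly merge the
two lightest trees. Which optimal code it emits, however, depends on how
ties are broken, and a codec that ships frequency tables instead of
codeword tables needs both sides to rebuild *bit-identical* codes. gramhuff
therefore fixes a canonical policy:

* every node carries a creation index — leaves first, in table insertion
  order, then internal nodes in merge order;
* among equal weights, the smaller creation index is merged first;
* of the two merged nodes, the smaller weight (tie: smaller creation index)
  becomes the left, "0" child.

All choices consistent with Huffman's invariant give the same weighted code
length; the policy only pins the bits. It is regression-tested against the
two reference codeword tables for the `"aaaaaaab"` example, and the
frequency-mode codebook file format (gram + count, insertion order) relies
on it for its round-trip guarantee. A one-gram table gets the codeword
`"0"` so degenerate inputs stay encodable.

## Optimal parsing as a shortest path

The admissible segmentations form a multistage graph on positions
`0, 1, …, n`: an edge `i → j` exists when `I[i+1..j]` (length ≤ `m`) has a
codeword, weighted by that codeword's length. The cheapest encoding is the
shortest `0 → n` path. Because every edge moves forward, ascending position
order is a topological order, and one pass of the Bellman relaxation

```
f(j) = min over { i : 1 ≤ j - i ≤ m, I[i+1..j] in codebook } of f(i) + |c(I[i+1..j])|
```

computes all `f(j)` exactly; the package's encoder does this with
per-position back-pointers and reconstructs the bits at the end, rather
than carrying full code strings per node. A stage-indexed formulation of
the same recursion — states revisited stage by stage — computes identical
values; the test suite keeps a literal stage-based transcription as an
oracle and checks both the values and the emitted bits agree everywhere.

Two details are contractual:

* **Tie rule.** Predecessors are scanned in ascending `i` and only strict
  improvements replace the incumbent ("first possibility" on ties). This
  makes the emitted bit string, not just its length, deterministic.
* **Missing grams.** After pruning (or on test data with unseen runs) a
  gram may have no codeword; it simply contributes no edge. Reachability is
  still guaranteed because all single symbols carry codewords.

A trie over the codebook grams (`build_trie()`) enumerates all edges out of
a position in one walk of at most `m` symbols, aborting as soon as the
walked prefix leaves the codebook — on corpora whose distinct-factor count
grows slowly (DNA, the Fibonacci word) most walks stop long before depth
`m`, so the `O(mn)` bound is loose in practice.

## The greedy heuristic

`encode_greedy()` is the knapsack-style shortcut: at each position scan
candidate grams of length `1..m` (clamped at the end of the input; clamped
duplicates are harmless re-evaluations and are kept for fidelity to the
scan order), skip grams without codewords, and take the candidate with the
*strictly* highest symbols-per-bit ratio — ties keep the earlier, shorter
candidate. The position always advances, so the cost is `O(mn)` scans and
the output length is never below the optimum (`length(greedy) ≥
length(optimal)` is property-tested). The strict comparison is load-bearing:
a `≥` would switch the unweighted worked example away from its reference
10-bit parse.

## Decoding

Prefix-freeness makes concatenated codewords uniquely decodable regardless
of which parser produced them. `build_decode_tree()` inverts the codebook
into a bit-indexed binary tree (rejecting non-prefix-free input), and
`decode_bits()` walks it bit by bit, emitting a gram at each leaf. Bits
ending mid-codeword raise `"truncated stream"`; walking off an absent
branch raises `"corrupt stream"`. For the degenerate one-gram codebook each
`"0"` bit decodes to the lone gram, inverting the encoder's convention.

## Parameters at a glance

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `m` | maximum gram length (symbols) | required | tables hold all grams up to `m`; prune for large `m` |
| `alpha` | length weight, window adds `i^α` | 1 | 0 = raw counts; integer α keeps counts exact |
| `keep_fraction` | fraction of multi-symbol grams kept | 1 | singles always kept |
| `split` | pattern fraction of a corpus | 0.25 | contiguous prefix |
| `granularity` | `byte` / `char` / `bit` symbolisation | `char` | bit order is MSB-first within a byte |

## Synthetic corpora: what they emulate and what they do not

`gen_trajectory(n, seed)` draws i.i.d. symbols over `{a,b,c,d,e}` with
probabilities `{0.88, 0.05, 0.01, 0.05, 0.01}` — the relative
movement-trajectory model (keep direction / turn slightly / turn hard). It
reproduces the skewed marginal distribution of such logs but, being i.i.d.,
none of the temporal correlation a real vehicle or animal track has; m-gram
gains on it come from run statistics of an i.i.d. source only.

`gen_fibonacci()` iterates the token rewriting `a → (a,b)`, `ba → (a,b)`,
`b → (ba)` from the start list `(a,b)`; the rewrite acts on the token list,
not the flattened string, which is required to reproduce the reference
iterates (`abbaab`, `abbaababba`, …). Token-list lengths follow the
Fibonacci recurrence, both symbols occur equally often (so `m = 1` coding
is pinned at exactly 1 bit/symbol), and the word has only `i + 1` distinct
factors of each length `i` — an extreme best case for long grams that no
natural sequence matches.

`split_pattern_test()` takes a contiguous prefix as pattern data — the
simplest split consistent with the train/test protocol; for i.i.d. corpora
the two parts are statistically exchangeable (checked by a χ² test in the
suite), but for drifting sources a contiguous split *will* expose
statistics mismatch, which is a property of the method being modelled, not
a bug.

Passing tests on these generators show the codec is correct and that its
rates behave as theory predicts on stationary sources; they say nothing
about rates on natural-language text, where frequency estimates from a
pattern set transfer poorly and the method is known to be weak.

## Problem sizes and numerical choices

The test suite works at desk scale, chosen so the whole suite runs in
minutes: exhaustive optimality is verified against a brute-force
segmentation enumeration for *every* binary string of length ≤ 12 under
both reference codebooks; code properties (prefix-freeness, Kraft equality,
the `p_max + 0.086` redundancy bound) on 500 randomly generated frequency
tables; decode∘encode identity on 1000 random inputs; the Fibonacci trend
on a 92,736-symbol word (rewriting iteration 23, split 25/75) for
`m ∈ {1, 16, 64}` with `keep_fraction = 1`, asserting the strict rate
decrease rather than exact mid-range values, which depend on corpus size
and pruning percentage; and the trajectory rate on 10⁵ symbols against the
closed-form expected Huffman length `0.88·1 + 0.05·2 + 0.05·3 + 2·0.01·4 =
1.21` bits/symbol.

Other numerical conventions: positions are 0-based with half-open gram
ranges internally; counts are doubles (exact for integer α up to 2⁵³);
rates are rounded only for display; byte granularity maps byte `v` to the
character `U+0001 + v` so all 256 byte values are single characters and
gram keys stay unambiguous; container payloads are packed MSB-first and
zero-padded to a byte boundary, with the exact bit count stored alongside.

## Known limitations

* Statistics are static: one codebook per stream, no adaptive or per-block
  updates.
* The codebook must cover the test alphabet; unseen symbols are a hard
  error (`"alphabet mismatch"` / `"unencodable symbol"`), not an escape
  code.
* Reported rates exclude codebook transmission; for short inputs with
  large `m` the codebook dominates and the container's embedded-codebook
  modes should be costed in.
* The optimal parser holds the whole input in memory; it is intended for
  benchmarking and short sequences, with the greedy parser as the
  production path.
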