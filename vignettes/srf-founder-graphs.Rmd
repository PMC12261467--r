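---
title: "Indexable elastic founder graphs: construction, seeding and chaining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexable elastic founder graphs: construction, seeding and chaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srfkit)
```

## The model

A pangenome can be represented as a *blocked, node-labeled DAG*: a multiple
sequence alignment (MSA) of `m` haplotypes is cut into consecutive column
intervals; each interval (block) contributes one node per distinct spelled
row segment, and two nodes of consecutive blocks are joined when some
haplotype spells them back to back. This *elastic founder graph* compacts
the haplotypes while letting paths recombine between them.

Arbitrary graphs of this kind are still hard to index. The property that
restores fast exact matching is *semi-repeat-freeness*: every occurrence of
a node label in the graph must start at the beginning of a node of its own
block. A graph with this property (an *iEFG*) has three useful
consequences, each checked directly by `validate_efg()`: node labels are
globally distinct, no label is a proper suffix of another, and every
occurrence of an edge label `l(u)l(v)` starts at the beginning of `u`.
Intuitively, recombination is only allowed after a unique piece of
sequence, which also suppresses spurious recombinant paths.

## Segmentation

`compute_f_exact()` computes, for every column `j`, the leftmost column
`f(j)` such that the block `[j..f(j)]` is valid, where validity means: no
row spells the empty string on the interval, and every occurrence of a
spelled row segment inside any full spelled row starts exactly at the
gaps-removed position of the interval's first column. This is the
MSA-level surrogate of graph indexability; the graph-level validator
remains the final authority and every build pipeline runs it.

Validity is closed under extending a block to the right: an occurrence of
the extended segment string at a misplaced position would contain an
occurrence of the original (prefix) segment string at the same misplaced
position, contradicting the validity of the original block. The
segmentation dynamic program therefore admits any segment `[x..y]` with
`y >= f(x)`.

Among admissible segmentations, `optimal_segmentation()` minimizes the
maximum block height (the number of distinct row segments), breaking ties
by maximizing the number of blocks and finally by the lexicographically
smallest boundary list, which makes the output unique and reproducible.
Height was chosen as the default objective because height is the quantity
that drives both matching complexity and graph statistics; maximizing
block count and minimizing maximum label length are available by flag.

The *row-partition approximation* (`compute_f_approx()`) shuffles rows
under a seed, splits them into `k` contiguous chunks, computes `f` per
chunk and takes the elementwise maximum. The result can violate
indexability, so `repair_segmentation()` rebuilds the graph, finds
offending blocks, and merges each with its right neighbor (the last block
merges left) until the graph validates; the block count strictly decreases,
so the loop terminates. The merge direction is arbitrary but fixed.

## Indexing and exact matching

`build_edge_text_index()` concatenates all edge labels separated by `#`
into a single text, builds its suffix array (prefix doubling, sentinel
order `$ < # < A < C < G < N < T`) and FM-style rank structures so that
`left_extend()` — one backward-search step — is a constant-time operation,
plus a position map sending each text position to its unique `(u, v, i)`.
A single-block graph has no edges; its index falls back to the
concatenated node labels, since a one-block graph is simply a set of
strings.

`exact_match()` works in two phases. Occurrences of the query contained in
one edge label (spanning one or two nodes) are read off the suffix-array
interval of the query directly. Occurrences spanning three or more nodes
must end with a suffix `Q[f'..]` that is a prefix of some edge label
`l(w w')` and covers `w` entirely; for each such split (found in one
backward pass over `Q`) the remaining prefix `Q[1..f'-1]` must end exactly
at a node boundary before `w`, and is recovered by walking right-to-left
matching whole node labels — a step that is essentially deterministic on an
iEFG because labels cannot be suffixes of one another. The brute-force
searcher `brute_force_match()` (every start position, DFS across edges) is
kept as the independent oracle; the randomized suite asserts agreement on
the found/not-found bit and that every witness re-spells the query.

Queries containing `N` or any symbol outside `A,C,G,T` never match: exact
seeds must be real sequence.

## Greedy semi-repeat-free seeding

A seed is an anchor whose subpath spans at least one full node (`k > 2`;
or `k = 1` covering the whole label; or `k = 2` touching one of its ends).
`greedy_srf_seeds()` repeatedly finds the longest suffix of the remaining
read prefix that occurs in the graph (binary search over suffix lengths,
each probe one `exact_match()` call), reports it if it passes the seed
predicate, and always truncates the read at the match start. When no
nonempty suffix occurs, one trailing character is dropped — the dead-end
rule that guarantees termination within `|Q|` iterations. Seeds of one
pass are pairwise disjoint in the read, the property chaining relies on.

`top_x_expand()` re-runs the greedy pass recording all matches, keeps the
`X` longest matched substrings, and reports every occurrence of each in
the graph. Occurrences are identified by their start position (first node,
offset); one witness path per start is reported with the lexicographically
smallest continuation. `full_node_seeds()` computes the complete set of
single-node seeds by multi-pattern scanning and doubles as a test oracle.

## Chaining on the EDS relaxation

Chaining operates on the *EDS relaxation*: the edge set is dropped and all
consecutive-block pairs are considered connected, so precedence and the
connect cost become O(1) queries after precomputing each node's block and
the prefix sums of per-block minimum label lengths. Multi-node seeds are
first split into node anchors (`split_to_node_anchors()`). The chain found
on the relaxation need not be a path of the iEFG, but its anchors still
guide downstream extension.

The connect cost between consecutive anchors is `gap + overlap`: on the
same node both follow the two-sequence formulas
(`gap = max(0, xq-yp-1, iq-jp-1)`,
`overlap = |max(0, yp-xq+1) - max(0, jp-iq+1)|`); across nodes the
graph-side gap is the EDS distance — remainder of the source label, the
minimum label length of every intervening block, and the offset into the
target label — while the graph-side overlap is zero, leaving the query-side
overlap. Virtual terminal anchors close the chain: global mode charges
both query and graph end-gaps (so with no anchors the cost is
`max(|Q|, S[b])`); semi-global mode frees the graph ends only, the natural
objective for long reads. With these terminals the minimum chain cost on a
degenerate one-node-per-block EDS equals the anchored edit distance
between query and spelled target, which the suite verifies against an
independent dynamic-programming oracle (`anchored_edit_distance()`, which
permits zero-cost matches only on anchor-covered cells and unit-cost
edits anywhere).

`chain_dp()` is the exact quadratic dynamic program. `chain_chainx()`
restricts transitions to those whose *gap* term is at most a window `B`
(checking the gap rather than the distance between anchor starts), then
verifies the result: if the best cost is at most `B`, every excluded
transition alone would already cost more than the solution, so the chain
is optimal and the iteration stops; otherwise `B` is multiplied by the
ramp-up factor `alpha` and the program re-run. Defaults `B1 = 128`,
`alpha = 4` are deliberate user-tunable guesses (any `B1 >= 1`,
`alpha > 1` give the same final costs, only the iteration count changes);
optionally the initial guess is `beta * (|Q| - c)` with `c` the read
coverage by the input seeds. Anchors overlapping in the query are accepted
by both algorithms; the optimality comparison in the suite uses greedy
seeds, which never overlap.

`chain_implied_subpath()` turns a chain into the single reported subpath
used by the evaluation criteria: the chain pins the node of every block it
touches, and a small semiglobal alignment (all of the read against a
contiguous infix of the EDS, restricted to the pinned nodes) resolves the
remaining blocks of the covered range and the end offsets. This stays an
anchor-guided skeleton: base-level extension of alignments is outside the
package's scope.

## Synthetic data and what passing tests show

`random_msa()` mutates an ancestor string per row (substitutions at
`mutation_rate`, default 0.05) and punches gap runs (run start probability
`gap_rate`, default 0.1, geometric continuation with mean length 2).
Draws in which one row's spelled sequence occurs inside another row away
from its aligned start are rejected and redrawn: such alignments admit no
semi-repeat-free segmentation at all (single-block validity is exactly
this condition) and do not arise from genuine haplotype alignments.
`simulate_read()` samples a maximal path uniformly via the path-count DP,
takes a window of the requested length, and applies iid
substitution/insertion/deletion errors at `error_rate/3` each (default 5%
total), flipping strand with probability 1/2.

The generator emulates: block-structured variation, indels as alignment
gaps, uniform sequencing noise on both strands. It does not emulate:
structured error profiles of real long-read chemistry, repeat-rich genomic
sequence, coverage biases, or chromosome-scale graphs. Passing the suite
therefore demonstrates correctness of the algorithms under the stated
model, not performance claims on real pangenomes.

Problem sizes used by the suite and the acceptance script were chosen to
exercise every code path at desk scale while keeping runs reproducible on
one CPU: 200 random alignments with `m <= 6`, `n <= 40` for construction;
1000 matching trials; 200 chaining instances; 300 string pairs (length
at most 12) for the anchored-edit-distance equivalence; one `m = 6`,
`n = 200` graph with 500 reads of length 100 at 5% error end to end.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout the API; GAF output uses
  0-based half-open query and path intervals.
* Node order, edge order, witness choice and segmentation tie-breaks are
  all fixed deterministically, so equal inputs give byte-identical
  outputs.
* `f(j) = Inf` encodes "no valid block starts at j"; the DP treats such
  columns as non-startable and reports "no valid segmentation" when
  column 1 cannot reach column `n`.
* Block membership in GFA is written as the `bl:i` tag (our convention);
  on input without tags, blocks are inferred as longest-path levels and
  re-validated.
* The maximal-path count is the number of block-1 to block-b paths;
  dead-end nodes contribute none.
* Empty queries are rejected rather than trivially matched.

## Known limitations

* `exact_match()` requires every node of a multi-block graph to be
  incident to an edge (always true for MSA-induced graphs); isolated
  nodes are invisible to the edge-label text.
* The windowed chaining algorithm's average-case running-time guarantee
  assumes non-overlapping, roughly uniform anchors; with overlapping
  anchors it still returns optimal costs (the gap-check stopping rule) but
  may iterate more.
* The seeding stage reports seeds per strand and leaves strand
  reconciliation to chaining; no minimizer or MEM seeding is provided.
* Extension (base-level alignment) is delegated to an external aligner;
  the pipeline emits GAF seeds/chains for that hand-off.
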