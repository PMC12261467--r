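# srfkit

Seed-chain alignment machinery for **indexable elastic founder graphs
(iEFGs)** — pangenome graphs built by segmenting a multiple sequence
alignment into blocks so that every node label occurs in the graph only
from the beginning of nodes of its own block (the *semi-repeat-free*
property). That uniqueness is what makes exact pattern matching on the
graph about as fast as on a plain string index, and it is the basis of
every stage implemented here:

* **Construction** — minimal valid right extensions `f(j)` per column
  (exactly, or by a seeded row-partition approximation with a repair
  loop), an optimal segmentation DP (default objective: minimize the
  maximum block height `H(G)`), and graph materialization with full
  structural and semi-repeat-free validation. GFA1 input/output with
  `bl:i` block tags.
* **Indexing & exact matching** — the edge-label text
  `T_edges = # l(u1v1) # l(u2v2) # ...` with a suffix array, FM-style
  constant-time `leftExtend`, and position-to-edge locate; exact matching
  of a query `Q` in `O(|Q| + min(|Q|, L(G))^2 + H(G)^2)`-style time, with
  a brute-force DFS oracle for verification.
* **Seeding** — greedy semi-repeat-free seeds: repeatedly match the
  longest suffix of the remaining read, keep it if its subpath spans a
  full node, truncate, repeat. Seeds are pairwise disjoint in the read.
  A `-o X` mode expands the X longest matches to all their graph
  occurrences; an Aho-Corasick-style full-node seeder serves as oracle.
  Seeds are emitted as GAF.
* **Chaining** — co-linear chaining of node anchors on the EDS relaxation
  of the graph with the `connect = gap + overlap` cost model
  (`gap(Ap,Aq) = max(0, xq-yp-1, graph distance)`), where the graph-side
  gap uses precomputed prefix sums of per-block minimum label lengths.
  Exact `O(n^2)` DP, and the windowed iterative algorithm with gap check
  and ramp-up `alpha` whose minimum chain cost equals the **anchored edit
  distance** between read and graph (verified against an independent DP
  oracle). Global and semi-global objectives.
* **Simulation & evaluation** — random MSAs, noisy reads sampled from
  graph paths, and the three correctness criteria (base-level path
  overlap `delta`, truth edit distance `sigma_truth`, read edit distance
  `sigma_read`).

## Worked example

```r
library(srfkit)

m <- msa(c("AC-GT-A", "ACTGTTA", "AC-GATA"))   # 3 haplotypes, 7 columns
f <- compute_f_exact(m)
#> [1]   2   2   7   4 Inf Inf Inf
g <- build_efg(m, optimal_segmentation(f, m))
g
#> Elastic founder graph: 2 blocks, 4 nodes, 3 edges
#>   H(G) = 3, L(G) = 5, total label length = 14
validate_efg(g)
#> iEFG validation: PASS
#>   semi-repeat-free violations: 0
#>   distinct labels: TRUE; no proper-suffix labels: TRUE; edge labels anchored: TRUE
```

`f` says a valid block starting at column 1 must reach column 2, one
starting at column 3 must run to the end, and no block may start past
column 4; the optimal segmentation is `[1..2] | [3..7]`, giving one shared
node `AC` and three variant nodes `GATA`, `GTA`, `TGTTA`.

Seeding and chaining a read with two errors ("ACTGTAA", truth `ACGTA`):

```r
idx <- build_edge_text_index(g)      # text "#ACGATA#ACGTA#ACTGTTA#"
seeds <- greedy_srf_seeds(g, idx, "ACTGTAA")
#> ([1..3], (1, v1.1v2.3, 1), +)
#> ([4..6], (1, v2.2, 3), +)
ch <- chain_dp(unlist(lapply(seeds, split_to_node_anchors, g = g),
                      recursive = FALSE),
               block_tables(g), 7, "global")
ch
#> Co-linear chain (global): 2 anchors, cost 2
spell_subpath(g, chain_implied_subpath(g, ch, "ACTGTAA"))
#> [1] "ACGTA"
```

The chain cost 2 is the anchored edit distance of the read to the graph:
one inserted `T` and one trailing `A`. The GAF output of the chain:

```
read1	7	0	2	+	>v1.1	2	0	2	2	2	255
read1	7	3	6	+	>v2.2	3	0	3	3	3	255
```

## Command line

A thin `Rscript` front-end is installed as `exec/srfkit`:

```sh
srfkit segment  --msa msa.fa --out graph.gfa [--approx-k K --seed S]
srfkit stats    --gfa graph.gfa [--json]
srfkit locate   --gfa graph.gfa --reads reads.fq --out hits.gaf --reverse-complement
srfkit seed     --gfa graph.gfa --reads reads.fq --out seeds.gaf [-o X] [--no-rc]
srfkit chain    --gfa graph.gfa --gaf seeds.gaf --out chains.gaf [--mode semiglobal]
srfkit align    --gfa graph.gfa --reads reads.fq --out chains.gaf   # seed + chain
srfkit simulate --gfa graph.gfa --n 500 --length 100 --error-rate 0.05 \
                --seed 1 --out reads.fq --truth truth.tsv
srfkit evaluate --gfa graph.gfa --gaf chains.gaf --truth truth.tsv --reads reads.fq
```

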