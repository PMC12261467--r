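Package: srfkit
Title: Seed-Chain Alignment on Indexable Elastic Founder Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of indexable (semi-repeat-free) elastic founder
    graphs from multiple sequence alignments, exact pattern matching on them
    through an edge-label text index with suffix-array backward search,
    greedy semi-repeat-free seeding of long reads, and co-linear chaining of
    node anchors on the elastic-degenerate-string relaxation with a
    gap-plus-overlap cost model equivalent to anchored edit distance.
    Includes GFA1 and GAF input/output, a read simulator, alignment
    evaluation criteria, and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
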