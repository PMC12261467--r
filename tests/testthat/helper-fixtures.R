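# Shared fixtures built in code.

# Small worked-example graph: three blocks, four source-to-sink spellings
# ACGGTT, ACGGTA, CAGGTT, CAGGTA; semi-repeat-free.
make_g0 <- function() {
  efg(nodes = data.frame(id = c("v1", "v2", "v3", "v4", "v5"),
                         block = c(1, 1, 2, 3, 3),
                         label = c("AC", "CA", "GG", "TT", "TA")),
      edges = data.frame(from = c("v1", "v2", "v3", "v3"),
                         to = c("v3", "v3", "v4", "v5")))
}

make_m0 <- function() msa(c("ACGT", "ATGT"))

# Random iEFG built through the exact-f pipeline.
make_random_iefg <- function(seed, m_max = 5L, n_max = 25L) {
  set.seed(seed)
  x <- random_msa(sample(2:m_max, 1L), sample(10:n_max, 1L),
                  mutation_rate = 0.08, gap_rate = 0.1, seed = seed)
  efg_from_msa(x, "exact")$graph
}

# Random queries for oracle trials: half true path substrings, half random.
random_query <- function(g, path_spell) {
  if (stats::runif(1L) < 0.5) {
    st <- sample(nchar(path_spell), 1L)
    substr(path_spell, st, min(nchar(path_spell), st + sample(1:12, 1L) - 1L))
  } else {
    paste(sample(c("A", "C", "G", "T"), sample(1:10, 1L), replace = TRUE),
          collapse = "")
  }
}

spell_of_path <- function(g, nodes) paste(g$label[nodes], collapse = "")
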