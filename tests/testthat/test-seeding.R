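test_that("seed predicate implements the full-node-span rule", {
  g0 <- make_g0()
  expect_true(is_srf_seed(g0, anchor(6, 7, subpath(1, "v4", 2))))     # k=1 full node
  expect_false(is_srf_seed(g0, anchor(2, 2, subpath(2, "v4", 2))))    # k=1 partial
  expect_false(is_srf_seed(g0, anchor(2, 3, subpath(2, c("v1", "v3"), 1))))  # k=2 neither end full
  expect_true(is_srf_seed(g0, anchor(1, 3, subpath(1, c("v1", "v3"), 1))))   # k=2, i=1
  expect_true(is_srf_seed(g0, anchor(1, 5, subpath(1, c("v2", "v3", "v4"), 1))))  # k=3
})

test_that("greedy seeding reproduces the worked-example seeds", {
  g0 <- make_g0()
  idx <- build_edge_text_index(g0)
  seeds <- greedy_srf_seeds(g0, idx, "CAGGTTT")
  expect_length(seeds, 2L)
  expect_equal(c(seeds[[1]]$x, seeds[[1]]$y), c(1L, 5L))
  expect_equal(seeds[[1]]$subpath$nodes, c("v2", "v3", "v4"))
  expect_equal(c(seeds[[2]]$x, seeds[[2]]$y), c(6L, 7L))
  expect_equal(seeds[[2]]$subpath$nodes, "v4")

  s2 <- greedy_srf_seeds(g0, idx, "ACGGTA")
  expect_length(s2, 1L)
  expect_equal(c(s2[[1]]$x, s2[[1]]$y), c(1L, 6L))

  expect_length(greedy_srf_seeds(g0, idx, "NN"), 0L)
})

test_that("greedy seeds are disjoint, semi-repeat-free, and re-spell their substrings", {
  set.seed(12)
  for (trial in 1:10) {
    g <- make_random_iefg(trial + 300)
    idx <- build_edge_text_index(g)
    sp <- spell_of_path(g, enumerate_paths(g)[[1]])
    for (q in 1:5) {
      st <- sample(max(1L, nchar(sp) - 30L), 1L)
      Q <- substr(sp, st, min(nchar(sp), st + 29L))
      seeds <- greedy_srf_seeds(g, idx, Q)
      covered <- integer(0)
      for (a in seeds) {
        expect_true(is_srf_seed(g, a))
        expect_equal(spell_subpath(g, a$subpath), substr(Q, a$x, a$y))
        expect_length(intersect(covered, a$x:a$y), 0L)
        covered <- c(covered, a$x:a$y)
      }
      ## error-free reads from a path: seeds cover most of the read
      expect_gte(length(covered), 0.8 * nchar(Q))
    }
  }
})

test_that("top-X expansion reports every occurrence of the longest matches", {
  g0 <- make_g0()
  idx <- build_edge_text_index(g0)
  ex <- top_x_expand(g0, idx, "CAGGTTT", X = 1)
  expect_length(ex, 1L)  # "CAGGT" occurs from one start position
  expect_equal(c(ex[[1]]$x, ex[[1]]$y), c(1L, 5L))
  expect_equal(spell_subpath(g0, ex[[1]]$subpath), "CAGGT")

  ## X saturating: expanded set covers every greedy seed's occurrence
  greedy <- greedy_srf_seeds(g0, idx, "CAGGTTT")
  exall <- top_x_expand(g0, idx, "CAGGTTT", X = 100)
  keys <- vapply(exall, function(a) paste(a$x, a$y, paste(a$subpath$nodes, collapse = ",")),
                 character(1L))
  for (a in greedy) {
    expect_true(paste(a$x, a$y, paste(a$subpath$nodes, collapse = ",")) %in% keys)
  }
  expect_error(top_x_expand(g0, idx, "CAGGTTT", X = 0), "X must be")
})

test_that("full-node seeding equals a naive all-substring scan", {
  g0 <- make_g0()
  an <- full_node_seeds(g0, "CAGGTT")
  expect_length(an, 3L)
  expect_equal(sort(vapply(an, function(a) a$subpath$nodes, character(1L))),
               c("v2", "v3", "v4"))
  an2 <- full_node_seeds(g0, "GGGG")
  expect_length(an2, 3L)  # overlapping GG occurrences at 1, 2, 3
  expect_equal(vapply(an2, function(a) a$x, integer(1L)), 1:3)
  expect_length(full_node_seeds(g0, ""), 0L)

  set.seed(5)
  for (trial in 1:5) {
    g <- make_random_iefg(trial + 350)
    Q <- spell_of_path(g, enumerate_paths(g)[[1]])
    got <- full_node_seeds(g, Q)
    naive <- 0L
    for (t in seq_len(nrow(g$nodes))) {
      lab <- g$nodes$label[t]
      for (s in seq_len(max(0L, nchar(Q) - nchar(lab) + 1L))) {
        if (substr(Q, s, s + nchar(lab) - 1L) == lab) naive <- naive + 1L
      }
    }
    expect_length(got, naive)
    for (a in got) expect_equal(spell_subpath(g, a$subpath), substr(Q, a$x, a$y))
  }
})

test_that("GAF serialization follows the stated field convention and round-trips", {
  g0 <- make_g0()
  line <- seeds_to_gaf(list(anchor(1, 5, subpath(1, c("v2", "v3", "v4"), 1))),
                       g0, "r1", 7L)
  expect_equal(line, "r1\t7\t0\t5\t+\t>v2>v3>v4\t6\t0\t5\t5\t5\t255")
  expect_length(seeds_to_gaf(list(), g0, "r1", 7L), 0L)
  rec <- parse_gaf(line, g0)
  expect_equal(rec$qname, "r1")
  a <- rec$anchor[[1]]
  expect_equal(c(a$x, a$y, a$subpath$i, a$subpath$j), c(1L, 5L, 1L, 1L))
  expect_equal(a$subpath$nodes, c("v2", "v3", "v4"))
})
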