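test_that("multi-node anchors split into re-spelling node anchors", {
  g0 <- make_g0()
  parts <- split_to_node_anchors(g0, anchor(1, 5, subpath(1, c("v2", "v3", "v4"), 1)))
  expect_length(parts, 3L)
  expect_equal(lapply(parts, function(a) c(a$x, a$y)),
               list(c(1L, 2L), c(3L, 4L), c(5L, 5L)))
  expect_equal(vapply(parts, function(a) spell_subpath(g0, a$subpath), character(1L)),
               c("CA", "GG", "T"))

  single <- anchor(3, 4, subpath(1, "v3", 2))
  expect_equal(split_to_node_anchors(g0, single), list(single))

  two <- split_to_node_anchors(g0, anchor(2, 3, subpath(2, c("v1", "v3"), 1)))
  expect_equal(lapply(two, function(a) c(a$x, a$y, a$subpath$i, a$subpath$j)),
               list(c(2L, 2L, 2L, 2L), c(3L, 3L, 1L, 1L)))
})

test_that("precedence combines query-interval and EDS block order", {
  g0 <- make_g0()
  tab <- block_tables(g0)
  expect_true(precedes(anchor(3, 4, subpath(1, "v3", 2)),
                       anchor(5, 5, subpath(1, "v4", 1)), tab))
  expect_true(precedes(anchor(5, 5, subpath(1, "v4", 1)),
                       anchor(6, 7, subpath(1, "v4", 2)), tab))
  expect_false(precedes(anchor(5, 5, subpath(1, "v4", 1)),
                        anchor(3, 4, subpath(1, "v3", 2)), tab))
  ## same block, different nodes: never precedes
  expect_false(precedes(anchor(1, 2, subpath(1, "v4", 2)),
                        anchor(3, 4, subpath(1, "v5", 2)), tab))
})

test_that("connect cost reproduces the gap and overlap formulas", {
  g0 <- make_g0()
  tab <- block_tables(g0)
  ## adjacent in query and graph: zero cost
  expect_equal(connect_cost(anchor(3, 4, subpath(1, "v3", 2)),
                            anchor(5, 5, subpath(1, "v4", 1)), tab), 0)
  ## block 1 -> block 3 skips V2: gap = min label length of V2 = 2
  expect_equal(connect_cost(anchor(1, 2, subpath(1, "v1", 2)),
                            anchor(3, 3, subpath(1, "v4", 1)), tab), 2)
  ## same node, query adjacent but graph overlap 1
  expect_equal(connect_cost(anchor(5, 5, subpath(1, "v4", 1)),
                            anchor(6, 7, subpath(1, "v4", 2)), tab), 1)
  expect_error(connect_cost(anchor(5, 5, subpath(1, "v4", 1)),
                            anchor(3, 4, subpath(1, "v3", 2)), tab),
               "non-preceding")
})

test_that("global chain cost on the worked example equals the read's edit distance", {
  g0 <- make_g0()
  idx <- build_edge_text_index(g0)
  tab <- block_tables(g0)
  seeds <- greedy_srf_seeds(g0, idx, "CAGGTTT")
  na <- unlist(lapply(seeds, function(a) split_to_node_anchors(g0, a)),
               recursive = FALSE)
  expect_length(na, 4L)
  res <- chain_dp(na, tab, 7L, "global")
  expect_equal(res$cost, 1)  # read CAGGTTT vs best path CAGGTT
  expect_equal(chain_chainx(na, tab, 7L, "global")$cost, 1)
})

test_that("terminal connects charge query and graph end-gaps", {
  ## a 2-block path graph with total shortest spelling 4
  g <- efg(data.frame(id = c("a", "b"), block = c(1, 2), label = c("AC", "GT")),
           data.frame(from = "a", to = "b"))
  tab <- block_tables(g)
  expect_equal(chain_dp(list(), tab, 5L, "global")$cost, 5)   # max(|Q|, S[b]) = max(5,4)
  expect_equal(chain_dp(list(), tab, 3L, "global")$cost, 4)
  expect_equal(chain_dp(list(), tab, 5L, "semiglobal")$cost, 5)
  ## a single anchor tiling the full read along a full path: zero cost
  full <- split_to_node_anchors(g, anchor(1, 4, subpath(1, c("a", "b"), 2)))
  expect_equal(chain_dp(full, tab, 4L, "global")$cost, 0)
  expect_equal(chain_chainx(full, tab, 4L, "global")$iterations, 1L)
})

test_that("windowed chaining with gap check matches the quadratic oracle", {
  set.seed(88)
  for (trial in 1:60) {
    g <- make_random_iefg(trial + 700)
    idx <- build_edge_text_index(g)
    tab <- block_tables(g)
    r <- simulate_read(g, sample(15:40, 1), error_rate = 0.08, seed = trial)
    Q <- if (r$strand == "+") r$seq else revcomp(r$seq)
    seeds <- greedy_srf_seeds(g, idx, Q)
    na <- unlist(lapply(seeds, function(a) split_to_node_anchors(g, a)),
                 recursive = FALSE)
    for (mode in c("global", "semiglobal")) {
      opt <- chain_dp(na, tab, nchar(Q), mode)
      fast <- chain_chainx(na, tab, nchar(Q), mode, b1 = 2, alpha = 2)
      expect_equal(fast$cost, opt$cost,
                   label = sprintf("trial %d mode %s", trial, mode))
      ## chain cost identity: sum of connects plus terminal connects
      if (length(opt$chain) > 1L) {
        inner <- sum(vapply(seq_len(length(opt$chain) - 1L), function(t) {
          connect_cost(opt$chain[[t]], opt$chain[[t + 1L]], tab)
        }, numeric(1L)))
        expect_lte(inner, opt$cost)
      }
    }
  }
})

test_that("degenerate single-node-block chaining equals anchored edit distance", {
  set.seed(21)
  for (trial in 1:40) {
    T1 <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), replace = TRUE),
                collapse = "")
    T2 <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1), replace = TRUE),
                collapse = "")
    eds <- string_to_eds(T2)
    tab <- block_tables(eds)
    an <- common_substring_anchors(T1, T2)
    na <- sequence_anchors_to_node_anchors(an, eds)
    expect_equal(chain_dp(na, tab, nchar(T1), "global")$cost,
                 anchored_edit_distance(T1, T2, an),
                 label = sprintf("%s vs %s", T1, T2))
  }
})

test_that("implied subpath of an error-free read chain spells the read", {
  g0 <- make_g0()
  idx <- build_edge_text_index(g0)
  tab <- block_tables(g0)
  Q <- "CAGGTT"
  seeds <- greedy_srf_seeds(g0, idx, Q)
  na <- unlist(lapply(seeds, function(a) split_to_node_anchors(g0, a)),
               recursive = FALSE)
  ch <- chain_chainx(na, tab, nchar(Q), "semiglobal")
  sp <- chain_implied_subpath(g0, ch, Q)
  expect_equal(spell_subpath(g0, sp), Q)
  expect_null(chain_implied_subpath(g0, chain_dp(list(), tab, 6L, "global"), Q))
})
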