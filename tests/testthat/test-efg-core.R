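test_that("efg constructor enforces the block/label/edge structure", {
  expect_s3_class(make_g0(), "efg")
  expect_error(efg(data.frame(id = c("a", "a"), block = c(1, 1), label = c("A", "C"))),
               "duplicate node id")
  expect_error(efg(data.frame(id = "a", block = 1, label = "")), "empty label")
  expect_error(efg(data.frame(id = c("a", "b"), block = c(1, 1), label = c("A", "A"))),
               "duplicate label within block")
  expect_error(efg(data.frame(id = c("a", "b"), block = c(1, 3), label = c("A", "C"))),
               "blocks must cover")
  g0n <- make_g0()$nodes
  expect_error(efg(g0n, data.frame(from = "v1", to = "v4")), "non-consecutive")
})

test_that("height, max label and block accessors are derived from the node table", {
  g0 <- make_g0()
  expect_equal(efg_height(g0), 2L)
  expect_equal(efg_max_label(g0), 2L)
  expect_equal(efg_block_nodes(g0, 3L), c("v5", "v4"))  # ordered by label: TA < TT
})

test_that("subpath spelling and validity checks work on the worked example", {
  g0 <- make_g0()
  expect_equal(spell_subpath(g0, subpath(2, c("v1", "v3", "v4"), 1)), "CGGT")
  expect_equal(spell_subpath(g0, subpath(1, "v3", 2)), "GG")
  expect_true(check_subpath(g0, subpath(2, c("v1", "v3"), 1)))
  expect_error(check_subpath(g0, subpath(1, c("v1", "v4"), 1)), "missing edge")
  expect_error(check_subpath(g0, subpath(3, "v1", 2)), "out of range|i <= j")
})

test_that("GFA serialization round-trips and carries block tags", {
  g0 <- make_g0()
  path <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g0, path)
  txt <- readLines(path)
  expect_true("S\tv3\tGG\tbl:i:2" %in% txt)
  expect_true(efg_equal(parse_gfa(path), g0))
})

test_that("GFA parsing reports structured errors and infers missing blocks", {
  bad <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c("H\tVN:Z:1.0", "S\tv1\t\tbl:i:1"), bad)
  expect_error(parse_gfa(bad), "line 2.*empty label")

  noncons <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(make_g0(), noncons)
  cat("L\tv1\t+\tv4\t+\t0M\n", file = noncons, append = TRUE)
  expect_error(parse_gfa(noncons), "non-consecutive")

  ## strip the bl tags: blocks are inferred as longest-path levels
  untag <- withr::local_tempfile(fileext = ".gfa")
  writeLines(sub("\tbl:i:[0-9]+", "", readLines(noncons)[seq_len(10)][
    !grepl("v1\t\\+\tv4", readLines(noncons)[seq_len(10)])]), untag)
  expect_true(efg_equal(parse_gfa(untag), make_g0()))
})

test_that("GFA round-trip holds for random pipeline-built graphs", {
  for (s in 1:25) {
    g <- make_random_iefg(s)
    path <- tempfile(fileext = ".gfa")
    write_gfa(g, path)
    expect_true(efg_equal(parse_gfa(path), g))
    unlink(path)
  }
})

test_that("semi-repeat-free check accepts the worked example and flags planted repeats", {
  g0 <- make_g0()
  expect_length(check_semi_repeat_free(g0), 0L)

  ## relabel v5 as CG: "CG" occurs starting inside v1 on path v1 v3
  g_bad <- efg(data.frame(id = c("v1", "v2", "v3", "v4", "v5"),
                          block = c(1, 1, 2, 3, 3),
                          label = c("AC", "CA", "GG", "TT", "CG")),
               make_g0()$edges)
  viol <- check_semi_repeat_free(g_bad)
  expect_gt(length(viol), 0L)
  expect_true("v5" %in% vapply(viol, `[[`, character(1L), "node"))

  ## single block: labels occur only at their own node starts
  g1 <- efg(data.frame(id = c("a", "b"), block = c(1, 1), label = c("A", "C")))
  expect_length(check_semi_repeat_free(g1), 0L)
})

test_that("validate_efg checks the three uniqueness consequences directly", {
  rep0 <- validate_efg(make_g0())
  expect_true(rep0$is_iefg)
  expect_true(rep0$distinct_labels && rep0$no_proper_suffix && rep0$edge_label_starts)

  ## same label in two blocks: duplicate-label failure and srf failure
  g_dup <- efg(data.frame(id = c("a", "b", "c"), block = c(1, 2, 3),
                          label = c("GG", "AA", "GG")),
               data.frame(from = c("a", "b"), to = c("b", "c")))
  rep1 <- validate_efg(g_dup)
  expect_false(rep1$distinct_labels)
  expect_gt(length(rep1$srf_violations), 0L)

  ## "TA" proper suffix of "GGTA" across blocks
  g_suf <- efg(data.frame(id = c("a", "b"), block = c(1, 2),
                          label = c("TA", "GGTA")),
               data.frame(from = "a", to = "b"))
  expect_false(validate_efg(g_suf)$no_proper_suffix)
})

test_that("graphs passing the semi-repeat-free check satisfy the uniqueness properties", {
  for (s in 1:40) {
    g <- make_random_iefg(s)
    if (length(check_semi_repeat_free(g)) == 0L) {
      rep <- validate_efg(g)
      expect_true(rep$distinct_labels, label = sprintf("distinct labels, seed %d", s))
      expect_true(rep$no_proper_suffix, label = sprintf("no proper suffix, seed %d", s))
      expect_true(rep$edge_label_starts, label = sprintf("edge labels anchored, seed %d", s))
    }
  }
})

test_that("EDS relaxation drops edges; expansion connects all consecutive pairs", {
  g0 <- make_g0()
  eds <- eds_relaxation(g0)
  expect_s3_class(eds, "efg_eds")
  expect_equal(eds$b, 3L)
  expect_null(eds$edges)
  expect_equal(nrow(eds_expand(eds)$edges), 4L)  # 2*1 + 1*2: already complete
  g1 <- efg(data.frame(id = "a", block = 1, label = "A"))
  expect_equal(eds_relaxation(g1)$b, 1L)
})

test_that("graph statistics match the worked example and handle degenerate graphs", {
  st <- graph_stats(make_g0())
  expect_equal(st[c("b", "height", "max_label", "n_paths")],
               list(b = 3L, height = 2L, max_label = 2L, n_paths = 4))
  st1 <- graph_stats(efg(data.frame(id = "a", block = 1, label = "A")))
  expect_equal(st1$n_paths, 1)
  expect_equal(st1$height, 1L)
  ## removing (v2, v3) leaves only the v1-rooted maximal paths
  g_cut <- efg(make_g0()$nodes,
               data.frame(from = c("v1", "v3", "v3"), to = c("v3", "v4", "v5")))
  expect_equal(graph_stats(g_cut)$n_paths, 2)
})

test_that("path-count DP agrees with exhaustive enumeration", {
  for (s in 1:20) {
    g <- make_random_iefg(s)
    expect_equal(graph_stats(g)$n_paths, length(enumerate_paths(g)),
                 label = sprintf("seed %d", s))
  }
})
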