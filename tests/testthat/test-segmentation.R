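test_that("spell removes gaps", {
  expect_equal(spell("A-C-"), "AC")
  expect_equal(spell("----"), "")
  expect_equal(spell("ACGT"), "ACGT")
  expect_error(msa(c("A-", "--")), "empty string")
})

test_that("segment validity matches the brute-force definition on the 2x4 example", {
  m0 <- make_m0()
  ## {"C","T"}: "T" occurs in row 2 at positions 2 and 4; 4 is misplaced
  expect_false(is_valid_segment(m0, 2, 2))
  expect_true(is_valid_segment(m0, 2, 3))
  expect_true(is_valid_segment(m0, 1, 4))
})

test_that("exact f values come from exhaustive segment validity", {
  expect_equal(compute_f_exact(make_m0()), c(1, 3, 3, Inf))
  expect_equal(compute_f_exact(msa("ACGT")), c(1, 2, 3, 4))
  expect_equal(compute_f_exact(msa(c("AC", "AC"))), c(1, 2))
})

test_that("row-partition approximation is exact for k = 1 and deterministic", {
  m0 <- make_m0()
  expect_equal(compute_f_approx(m0, 1, seed = 5), compute_f_exact(m0))
  x <- random_msa(5, 20, seed = 3)
  expect_identical(compute_f_approx(x, 3, seed = 11), compute_f_approx(x, 3, seed = 11))
  expect_error(compute_f_approx(m0, 5), "k must be")
  ## k = m: elementwise max of the per-row f values
  per_row <- do.call(pmax, lapply(seq_len(m0$m), function(i) {
    compute_f_exact(msa(m0$rows[i]))
  }))
  expect_equal(compute_f_approx(m0, m0$m, seed = 1), per_row)
})

test_that("optimal segmentation minimizes max height then maximizes blocks", {
  m0 <- make_m0()
  f <- compute_f_exact(m0)
  seg <- optimal_segmentation(f, m0)
  expect_equal(seg$start, c(1L, 2L))
  expect_equal(seg$end, c(1L, 4L))
  expect_equal(optimal_segmentation(1, msa("A"))$end, 1L)
  expect_error(optimal_segmentation(c(Inf, Inf), msa("AC")), "no valid segmentation")
})

test_that("graph construction dedups labels per block and wires row adjacencies", {
  m0 <- make_m0()
  g <- build_efg(m0, segmentation(c(1, 4), 4))
  expect_equal(sort(g$nodes$label[g$nodes$block == 1]), "A")
  expect_equal(sort(g$nodes$label[g$nodes$block == 2]), c("CGT", "TGT"))
  expect_equal(nrow(g$edges), 2L)
  expect_length(check_semi_repeat_free(g), 0L)

  g1 <- build_efg(m0, segmentation(4, 4))
  expect_equal(g1$b, 1L)
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 0L)

  expect_error(build_efg(msa(c("A-", "AC")), segmentation(c(1, 2), 2)),
               "empty label in block 2")
})

test_that("repair leaves valid segmentations untouched and fixes approximate ones", {
  m0 <- make_m0()
  seg <- segmentation(c(2, 4), 4)  # both blocks valid for this alignment
  expect_equal(repair_segmentation(m0, seg), seg)
  for (s in 1:25) {
    set.seed(s)
    x <- random_msa(sample(3:6, 1), sample(15:40, 1), seed = s + 500)
    k <- sample(2:x$m, 1)
    f <- compute_f_approx(x, k, seed = s)
    seg0 <- optimal_segmentation(f, x)
    seg1 <- repair_segmentation(x, seg0)
    expect_true(validate_efg(build_efg(x, seg1))$is_iefg,
                label = sprintf("repaired approx graph validates, seed %d", s))
  }
})

test_that("exact-f pipeline graphs validate and spell every row on some path", {
  for (s in 1:25) {
    set.seed(s)
    x <- random_msa(sample(2:6, 1), sample(10:40, 1), seed = s)
    res <- efg_from_msa(x, "exact")
    expect_true(validate_efg(res$graph)$is_iefg, label = sprintf("seed %d", s))
    spelled_paths <- vapply(enumerate_paths(res$graph),
                            function(p) spell_of_path(res$graph, p), character(1L))
    for (row_spell in spell(x$rows)) {
      expect_true(row_spell %in% spelled_paths,
                  label = sprintf("row spelled by a path, seed %d", s))
    }
  }
})

test_that("segment validity is preserved under right extension on random alignments", {
  ## closure property relied upon by the f-based segmentation rule
  for (s in 1:10) {
    set.seed(s)
    x <- random_msa(3, 15, seed = s + 900)
    f <- compute_f_exact(x)
    for (j in which(is.finite(f))) {
      for (y in seq(f[j], x$n)) {
        expect_true(is_valid_segment(x, j, y),
                    label = sprintf("seed %d segment [%d..%d]", s, j, y))
      }
    }
  }
})
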