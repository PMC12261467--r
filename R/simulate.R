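#' Random multiple sequence alignments
#'
#' Generates an ancestor string of length `n` over `A,C,G,T` and derives
#' each of the `m` rows by substituting symbols at `mutation_rate` and
#' punching gap runs: a run starts at each column with probability
#' `gap_rate` and continues with probability 1/2 per column (geometric run
#' length, mean 2). Rows that would spell the empty string are redrawn,
#' and the whole alignment is redrawn while any row's spelled sequence
#' occurs inside another row away from its aligned start — such alignments
#' (one haplotype a misplaced substring of another) are degenerate for
#' founder-graph segmentation and do not arise from genuine haplotype
#' alignments. Deterministic under `seed`; the caller's RNG state is
#' untouched.
#'
#' @param m,n rows and columns, both `>= 1`.
#' @param mutation_rate,gap_rate per-column rates in `[0, 1)`.
#' @param seed integer seed.
#' @return An `efg_msa`.
#' @export
random_msa <- function(m, n, mutation_rate = 0.05, gap_rate = 0.1, seed = 1L) {
  stopifnot(m >= 1L, n >= 1L,
            mutation_rate >= 0, mutation_rate < 1, gap_rate >= 0, gap_rate < 1)
  with_seed(seed, {
    for (attempt in 1:1000) {
      anc <- sample(MATCH_ALPHABET, n, replace = TRUE)
      rows <- character(m)
      for (i in seq_len(m)) {
        repeat {
          row <- anc
          mut <- stats::runif(n) < mutation_rate
          if (any(mut)) {
            row[mut] <- vapply(row[mut], function(ch) {
              sample(setdiff(MATCH_ALPHABET, ch), 1L)
            }, character(1L))
          }
          gap <- logical(n)
          c0 <- 1L
          while (c0 <= n) {
            if (stats::runif(1L) < gap_rate) {
              len <- 1L + stats::rgeom(1L, 0.5)
              gap[c0:min(n, c0 + len - 1L)] <- TRUE
              c0 <- c0 + len
            }
            c0 <- c0 + 1L
          }
          row[gap] <- "-"
          if (any(!gap)) {
            rows[i] <- paste(row, collapse = "")
            break
          }
        }
      }
      ## reject alignments where a whole spelled row sits inside another
      ## row away from its aligned start (unsegmentable, unrealistic)
      spelled <- spell(rows)
      ok <- TRUE
      for (i in seq_len(m)) {
        for (i2 in seq_len(m)) {
          if (any(str_occ_all(spelled[i], spelled[i2]) != 1L)) ok <- FALSE
        }
        if (!ok) break
      }
      if (ok) return(msa(rows))
    }
    stop("could not draw a non-degenerate MSA in 1000 attempts")
  })
}

#' Simulate a read from a graph path
#'
#' Samples a maximal (block-1 to block-b) path uniformly at random by the
#' path-count dynamic program, takes a window of the requested length from
#' its spelling at a uniform start, applies iid errors (substitution,
#' insertion, deletion each with probability `error_rate/3` per position),
#' and flips to the reverse strand with probability 1/2. The record keeps
#' the true source subpath on the forward graph.
#'
#' @param g an `efg` object.
#' @param length requested read length (clipped to the path spelling).
#' @param error_rate total per-base error probability in `[0, 1)`.
#' @param seed integer seed.
#' @param name read name.
#' @return An `efg_read` with fields `name`, `seq` (as sequenced, i.e.
#'   reverse-complemented for `-` strand reads), `strand`, `truth` (an
#'   `efg_subpath`), `true_seq` (forward-strand spelling of the truth),
#'   and `error_rate`.
#' @export
simulate_read <- function(g, length, error_rate = 0.05, seed = 1L, name = "read1") {
  stopifnot(length >= 1L, error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    ## uniform maximal path via path counts
    cnt <- stats::setNames(numeric(nrow(g$nodes)), g$nodes$id)
    for (k in seq(g$b, 1L)) {
      for (v in efg_block_nodes(g, k)) {
        cnt[v] <- if (k == g$b) 1 else sum(cnt[g$out[[v]]])
      }
    }
    src <- efg_block_nodes(g, 1L)
    if (sum(cnt[src]) == 0) stop("graph has no block-1 to block-b path")
    path <- sample(src, 1L, prob = cnt[src])
    while (g$block[[path[length(path)]]] < g$b) {
      nxt <- g$out[[path[length(path)]]]
      nxt <- nxt[cnt[nxt] > 0]
      path <- c(path, if (length(nxt) == 1L) nxt else sample(nxt, 1L, prob = cnt[nxt]))
    }
    spelled <- paste(g$label[path], collapse = "")
    len <- min(length, nchar(spelled))
    start <- sample.int(nchar(spelled) - len + 1L, 1L)
    true_seq <- substr(spelled, start, start + len - 1L)

    ## true subpath: trim the path to the covered nodes and offsets
    lens <- nchar(g$label[path])
    ends <- cumsum(lens)
    first <- which(ends >= start)[1L]
    last <- which(ends >= start + len - 1L)[1L]
    i <- start - c(0L, ends)[first]
    j <- (start + len - 1L) - c(0L, ends)[last]
    truth <- subpath(i, path[first:last], j)

    ## iid sequencing errors
    chs <- strsplit(true_seq, "")[[1L]]
    out <- character(0)
    for (ch in chs) {
      r <- stats::runif(1L)
      if (r < error_rate / 3) {                     # substitution
        out <- c(out, sample(setdiff(MATCH_ALPHABET, ch), 1L))
      } else if (r < 2 * error_rate / 3) {          # insertion (before base)
        out <- c(out, sample(MATCH_ALPHABET, 1L), ch)
      } else if (r < error_rate) {                  # deletion
      } else {
        out <- c(out, ch)
      }
    }
    if (!length(out)) out <- sample(MATCH_ALPHABET, 1L)
    seq <- paste(out, collapse = "")
    strand <- if (stats::runif(1L) < 0.5) "+" else "-"
    if (strand == "-") seq <- revcomp(seq)
    structure(list(name = name, seq = seq, strand = strand,
                   truth = truth, true_seq = true_seq, error_rate = error_rate),
              class = "efg_read")
  })
}

#' @export
print.efg_read <- function(x, ...) {
  cat(sprintf("%s (%s strand, %d bp, error rate %g)\n",
              x$name, x$strand, nchar(x$seq), x$error_rate))
  invisible(x)
}

## Per-base graph positions "node:offset" covered by a subpath.
subpath_positions <- function(g, sp) {
  k <- length(sp$nodes)
  lens <- nchar(g$label[sp$nodes])
  unlist(lapply(seq_len(k), function(t) {
    from <- if (t == 1L) sp$i else 1L
    to <- if (t == k) sp$j else lens[t]
    if (to < from) character(0) else paste0(sp$nodes[t], ":", from:to)
  }))
}

#' Alignment correctness criteria
#'
#' Evaluates a reported alignment against the ground truth with three
#' parameterized criteria: (1) path accuracy — the base-level overlap
#' between the reported and true subpaths (shared `(node, offset)`
#' positions) is at least `delta` times the true subpath length; (2) truth
#' edit-distance accuracy — the Levenshtein distance between the reported
#' and true sequences is at most `sigma_truth` times the true sequence
#' length; (3) read edit-distance accuracy — the Levenshtein distance
#' between the read and the reported sequence is at most `sigma_read`
#' times the read length.
#'
#' @param g an `efg` object (both subpaths live on it).
#' @param reported,truth `efg_subpath` objects (`reported` may be `NULL`,
#'   failing all criteria).
#' @param read the read sequence, oriented to the forward graph strand.
#' @param delta,sigma_truth,sigma_read criterion parameters in `(0, 1]`.
#' @return named logical vector `c(path, edit_truth, edit_read)`.
#' @export
evaluate_alignment <- function(g, reported, truth, read,
                               delta = 0.1, sigma_truth = 0.1, sigma_read = 0.1) {
  if (is.null(reported)) {
    return(c(path = FALSE, edit_truth = FALSE, edit_read = FALSE))
  }
  tp <- subpath_positions(g, truth)
  rp <- subpath_positions(g, reported)
  ov <- length(intersect(tp, rp))
  rep_seq <- spell_subpath(g, reported)
  true_seq <- spell_subpath(g, truth)
  c(path = ov >= delta * length(tp),
    edit_truth = utils::adist(rep_seq, true_seq)[1L, 1L] <= sigma_truth * nchar(true_seq),
    edit_read = utils::adist(read, rep_seq)[1L, 1L] <= sigma_read * nchar(read))
}

#' Anchored edit distance
#'
#' Minimum unit-cost edit script between `T1` and `T2` where zero-cost
#' matches are permitted only at position pairs covered consistently by
#' some anchor (an anchor `([x..y],[a..b])` covers `(i, j)` when
#' `x <= i <= y` and `j - a = i - x`); substitutions, insertions and
#' deletions cost 1 anywhere. Computed by exhaustive dynamic programming
#' over the anchor-restricted match set — the oracle for the equivalence
#' between minimum chain cost and edit distance supported by the anchors.
#'
#' @param T1,T2 strings (oracle scale; quadratic DP).
#' @param anchors list of anchors, each a list/vector with elements
#'   `x, y, a, b` (1-based inclusive intervals in `T1` and `T2` of equal
#'   length, spelling the same substring).
#' @return non-negative integer.
#' @export
anchored_edit_distance <- function(T1, T2, anchors) {
  n1 <- nchar(T1); n2 <- nchar(T2)
  allow <- matrix(FALSE, nrow = n1, ncol = n2)
  for (a in anchors) {
    a <- as.list(a)
    len <- a$y - a$x + 1L
    stopifnot(a$b - a$a + 1L == len,
              substr(T1, a$x, a$y) == substr(T2, a$a, a$b))
    idx <- seq_len(len) - 1L
    allow[cbind(a$x + idx, a$a + idx)] <- TRUE
  }
  D <- matrix(0L, nrow = n1 + 1L, ncol = n2 + 1L)
  D[, 1L] <- 0:n1
  D[1L, ] <- 0:n2
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      diag_cost <- if (allow[i, j]) 0L else 1L
      D[i + 1L, j + 1L] <- min(D[i, j] + diag_cost,
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  D[n1 + 1L, n2 + 1L]
}

#' All common-substring anchors between two strings
#'
#' Every maximal run is decomposed into its constituent anchors implicitly:
#' this returns one anchor per common-substring occurrence pair that is
#' *maximal* (cannot be extended left or right), which generates the same
#' anchored match set as the full common-substring family.
#'
#' @param T1,T2 strings.
#' @return list of anchors as used by [anchored_edit_distance()].
#' @export
common_substring_anchors <- function(T1, T2) {
  n1 <- nchar(T1); n2 <- nchar(T2)
  c1 <- strsplit(T1, "")[[1L]]
  c2 <- strsplit(T2, "")[[1L]]
  eq <- outer(c1, c2, "==")
  out <- list()
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      if (!eq[i, j]) next
      if (i > 1L && j > 1L && eq[i - 1L, j - 1L]) next  # not run start
      len <- 0L
      while (i + len <= n1 && j + len <= n2 && eq[i + len, j + len]) len <- len + 1L
      out[[length(out) + 1L]] <- list(x = i, y = i + len - 1L, a = j, b = j + len - 1L)
    }
  }
  out
}

#' Encode a string as a single-node-per-block EDS graph
#'
#' Each symbol becomes one block with one node: the degenerate EDS on which
#' chaining reduces to sequence-to-sequence chaining; companion of the
#' anchored edit distance oracle.
#'
#' @param s nonempty string.
#' @return An `efg` object (a path graph).
#' @export
string_to_eds <- function(s) {
  n <- nchar(s)
  stopifnot(n >= 1L)
  ids <- sprintf("p%d", seq_len(n))
  nodes <- data.frame(id = ids, block = seq_len(n),
                      label = strsplit(s, "")[[1L]])
  edges <- if (n > 1L) data.frame(from = ids[-n], to = ids[-1L])
  efg(nodes, edges)
}

#' Sequence anchors as node anchors on a string EDS
#'
#' Converts `([x..y],[a..b])` anchors between query `T1` and target `T2`
#' into single-node anchors on [string_to_eds()]`(T2)`.
#'
#' @param anchors list of anchors (as in [anchored_edit_distance()]).
#' @param eds the graph from [string_to_eds()].
#' @return list of `efg_anchor` objects (one per covered position pair).
#' @export
sequence_anchors_to_node_anchors <- function(anchors, eds) {
  out <- list()
  for (a in anchors) {
    a <- as.list(a)
    for (t in 0:(a$y - a$x)) {
      out[[length(out) + 1L]] <-
        anchor(a$x + t, a$x + t, subpath(1L, sprintf("p%d", a$a + t), 1L))
    }
  }
  out
}
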