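## Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Semi-repeat-free validity of an MSA segment
#'
#' Columns `[x..y]` induce a valid (semi-repeat-free) block when (a) no row
#' spells the empty string on `[x..y]`, and (b) for every row `i`, every
#' occurrence of `spell(MSA[i, x..y])` inside any spelled row starts exactly
#' at the gaps-removed position of column `x` in that row. This is the
#' MSA-level surrogate of graph indexability used by the segmentation
#' algorithms; the graph-level validator ([validate_efg()]) remains the
#' final authority for built graphs.
#'
#' @param x_msa an `efg_msa`.
#' @param x,y 1-based column interval, `1 <= x <= y <= n`.
#' @return logical scalar.
#' @export
is_valid_segment <- function(x_msa, x, y) {
  ctx <- seg_context(x_msa)
  is_valid_segment_ctx(ctx, x, y)
}

is_valid_segment_ctx <- function(ctx, x, y) {
  stopifnot(x >= 1L, y >= x, y <= ctx$n)
  segs <- seg_strings(ctx, x, y)
  if (any(!nzchar(segs))) return(FALSE)
  expect_pos <- ctx$cum[, x] + 1L
  for (P in unique(segs)) {
    for (i2 in seq_len(ctx$m)) {
      occ <- str_occ_all(P, ctx$spelled[i2])
      if (length(occ) && any(occ != expect_pos[i2])) return(FALSE)
    }
  }
  TRUE
}

#' Minimal right extensions f(j)
#'
#' `compute_f_exact()` returns, for every column `j`, the smallest `y >= j`
#' such that columns `[j..y]` form a valid semi-repeat-free block
#' ([is_valid_segment()]), or `Inf` when no valid block starts at `j`.
#' Validity is closed under right extension, so any segment `[j..y]` with
#' `y >= f(j)` is valid.
#'
#' `compute_f_approx()` implements the row-partition approximation: rows are
#' shuffled (deterministically under `seed`) and split into `k` contiguous
#' chunks; `f` is computed on each row subset and the elementwise maximum is
#' returned. The result is not guaranteed valid for the full MSA; build
#' pipelines repair the resulting segmentation ([repair_segmentation()]).
#'
#' @param x_msa an `efg_msa`.
#' @return numeric vector `f[1..n]` (with `Inf` for non-startable columns).
#' @export
compute_f_exact <- function(x_msa) {
  ctx <- seg_context(x_msa)
  n <- ctx$n
  f <- rep(Inf, n)
  for (j in seq_len(n)) {
    for (y in j:n) {
      if (is_valid_segment_ctx(ctx, j, y)) {
        f[j] <- y
        break
      }
    }
  }
  f
}

#' @rdname compute_f_exact
#' @param k number of row subsets, `1 <= k <= m` (`k = 1` is exact).
#' @param seed integer seed for the row shuffle.
#' @export
compute_f_approx <- function(x_msa, k, seed = 1L) {
  stopifnot(inherits(x_msa, "efg_msa"))
  if (k < 1L || k > x_msa$m) stop("k must be in 1..m")
  perm <- with_seed(seed, sample.int(x_msa$m))
  chunk <- sort(rep_len(seq_len(k), x_msa$m))
  f_parts <- lapply(seq_len(k), function(ck) {
    rows <- perm[chunk == ck]
    compute_f_exact(msa(x_msa$rows[rows], x_msa$names[rows]))
  })
  do.call(pmax, f_parts)
}

#' Column segmentations
#'
#' A segmentation partitions columns `[1..n]` into consecutive intervals
#' `[x1..y1], ..., [xb..yb]` with `x1 = 1`, `yb = n`, `x(k+1) = yk + 1`.
#'
#' @param ends integer vector of segment right endpoints `y1 < ... < yb = n`.
#' @param n total number of columns.
#' @return An `efg_segmentation`: data.frame with columns `start`, `end`.
#' @export
segmentation <- function(ends, n) {
  ends <- as.integer(ends)
  if (!length(ends) || is.unsorted(ends, strictly = TRUE) || ends[length(ends)] != n) {
    stop("segment ends must be strictly increasing and finish at n")
  }
  starts <- c(1L, ends[-length(ends)] + 1L)
  structure(data.frame(start = starts, end = ends),
            class = c("efg_segmentation", "data.frame"))
}

#' Optimal segmentation from f values
#'
#' Dynamic program over the valid blocks encoded by `f`: a segment `[x..y]`
#' is usable iff `y >= f(x)`. The default objective minimizes the maximum
#' block height of the induced graph (requires the MSA), breaking ties by
#' maximizing the number of blocks and finally by the lexicographically
#' smallest boundary list. Alternative objectives: `"blocks"` maximizes the
#' number of blocks; `"length"` minimizes the maximum block label length.
#'
#' @param f numeric vector from [compute_f_exact()] or [compute_f_approx()].
#' @param x_msa the `efg_msa` the f values were computed from; required for
#'   the `"height"` and `"length"` objectives.
#' @param objective one of `"height"`, `"blocks"`, `"length"`.
#' @return An `efg_segmentation`.
#' @export
optimal_segmentation <- function(f, x_msa = NULL, objective = c("height", "blocks", "length")) {
  objective <- match.arg(objective)
  n <- length(f)
  ctx <- if (!is.null(x_msa)) seg_context(x_msa)
  if (objective %in% c("height", "length") && is.null(ctx)) {
    stop("objective '", objective, "' needs the MSA")
  }
  seg_primary <- function(x, y) {
    switch(objective,
           height = length(unique(seg_strings(ctx, x, y))),
           blocks = 0,
           length = max(nchar(seg_strings(ctx, x, y))))
  }
  ## suffix DP: P[x], S[x] = lexicographically minimal (primary, -blocks)
  ## over segmentations of columns [x..n]; P uses max-combine (minimax).
  P <- rep(Inf, n + 1L); S <- rep(Inf, n + 1L); feas <- rep(FALSE, n + 1L)
  P[n + 1L] <- -Inf; S[n + 1L] <- 0; feas[n + 1L] <- TRUE
  for (x in seq(n, 1L)) {
    if (!is.finite(f[x]) || f[x] > n) next
    for (y in seq(f[x], n)) {
      if (!feas[y + 1L]) next
      p <- max(seg_primary(x, y), P[y + 1L])
      s <- S[y + 1L] - 1
      if (!feas[x] || p < P[x] || (p == P[x] && s < S[x])) {
        P[x] <- p; S[x] <- s; feas[x] <- TRUE
      }
    }
  }
  if (!feas[1L]) stop("no valid segmentation: no partition into valid blocks exists")
  ## greedy reconstruction: smallest y first gives the lexicographically
  ## smallest boundary list among optimal segmentations
  ends <- integer(0)
  x <- 1L
  while (x <= n) {
    found <- FALSE
    for (y in seq(f[x], n)) {
      if (feas[y + 1L] &&
          max(seg_primary(x, y), P[y + 1L]) == P[x] &&
          S[y + 1L] - 1 == S[x]) {
        ends <- c(ends, y)
        x <- y + 1L
        found <- TRUE
        break
      }
    }
    if (!found) stop("internal error: segmentation reconstruction failed")
  }
  segmentation(ends, n)
}

#' Build the elastic founder graph induced by a segmentation
#'
#' Block `k` of the graph holds one node per distinct spelled row segment of
#' columns `[xk..yk]`; nodes `v`, `w` of consecutive blocks are joined iff
#' some row spells `l(v)l(w)` across the two segments.
#'
#' @param x_msa an `efg_msa`.
#' @param seg an `efg_segmentation` of its columns.
#' @return An `efg` object.
#' @export
build_efg <- function(x_msa, seg) {
  ctx <- seg_context(x_msa)
  b <- nrow(seg)
  if (seg$start[1L] != 1L || seg$end[b] != ctx$n) stop("segmentation must cover all columns")
  node_of_row <- matrix("", nrow = ctx$m, ncol = b)
  ids <- character(0); blocks <- integer(0); labels <- character(0)
  for (k in seq_len(b)) {
    segs <- seg_strings(ctx, seg$start[k], seg$end[k])
    if (any(!nzchar(segs))) stop("empty label in block ", k)
    labs <- sort(unique(segs))
    id_k <- sprintf("v%d.%d", k, seq_along(labs))
    ids <- c(ids, id_k); blocks <- c(blocks, rep(k, length(labs))); labels <- c(labels, labs)
    node_of_row[, k] <- id_k[match(segs, labs)]
  }
  edges <- NULL
  if (b > 1L) {
    edges <- unique(do.call(rbind, lapply(seq_len(b - 1L), function(k) {
      data.frame(from = node_of_row[, k], to = node_of_row[, k + 1L])
    })))
  }
  efg(data.frame(id = ids, block = blocks, label = labels), edges)
}

#' Repair a segmentation until the built graph is indexable
#'
#' Repeatedly builds the graph, runs [check_semi_repeat_free()], and merges
#' each offending block with its right neighbor (the last block merges
#' left); blocks whose spelled segment is empty for some row are treated as
#' offending too. Terminates because the number of blocks strictly
#' decreases; errors with "irreparable" if even the single whole-MSA block
#' fails.
#'
#' @inheritParams build_efg
#' @return A repaired `efg_segmentation` whose built graph passes
#'   [check_semi_repeat_free()]; valid segmentations are returned unchanged.
#' @export
repair_segmentation <- function(x_msa, seg) {
  ctx <- seg_context(x_msa)
  repeat {
    bad <- integer(0)
    g <- NULL
    ## blocks with an empty spelled segment cannot be materialized
    for (k in seq_len(nrow(seg))) {
      if (any(!nzchar(seg_strings(ctx, seg$start[k], seg$end[k])))) bad <- c(bad, k)
    }
    if (!length(bad)) {
      g <- build_efg(x_msa, seg)
      viol <- check_semi_repeat_free(g)
      if (!length(viol)) return(seg)
      bad <- sort(unique(vapply(viol, function(v) g$block[[v$node]], integer(1L))))
    }
    if (nrow(seg) == 1L) stop("irreparable: even the single-block segmentation is invalid")
    k <- bad[1L]
    drop <- if (k == nrow(seg)) k - 1L else k  # merge right; last block merges left
    seg <- segmentation(seg$end[-drop], ctx$n)
  }
}

#' End-to-end iEFG construction from an MSA
#'
#' Convenience pipeline: compute f values (exactly or by the row-partition
#' approximation), segment optimally, optionally repair, and build the
#' graph. The approximate strategy always repairs; the exact strategy
#' repairs only on request (with exact f the built graph is already
#' semi-repeat-free).
#'
#' @inheritParams compute_f_exact
#' @param method `"exact"` or `"approx"`.
#' @param k,seed row-partition parameters for `method = "approx"`.
#' @param objective segmentation objective, see [optimal_segmentation()].
#' @param repair force the repair loop to run.
#' @return A list with the built `graph`, the `segmentation` used, and `f`.
#' @export
efg_from_msa <- function(x_msa, method = c("exact", "approx"), k = 2L, seed = 1L,
                         objective = "height", repair = NULL) {
  method <- match.arg(method)
  f <- switch(method,
              exact = compute_f_exact(x_msa),
              approx = compute_f_approx(x_msa, k = k, seed = seed))
  seg <- optimal_segmentation(f, x_msa, objective = objective)
  if (is.null(repair)) repair <- method == "approx"
  if (repair) seg <- repair_segmentation(x_msa, seg)
  list(graph = build_efg(x_msa, seg), segmentation = seg, f = f)
}
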