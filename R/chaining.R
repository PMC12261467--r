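#' Block tables for constant-time EDS chaining queries
#'
#' Precomputes `B[u]`, the block index of each node, and the prefix sums
#' `S[k] = sum_{j<=k} min_{v in Vj} ||v||` of minimum label lengths, which
#' make the graph-side gap of the EDS cost model an O(1) evaluation.
#'
#' @param g an `efg` or `efg_eds` object.
#' @return An `efg_block_tables` list with `B`, `minlen`, `S`, `b`.
#' @export
block_tables <- function(g) {
  nodes <- g$nodes
  minlen <- vapply(seq_len(g$b), function(k) min(nchar(nodes$label[nodes$block == k])),
                   numeric(1L))
  structure(list(B = stats::setNames(nodes$block, nodes$id),
                 nodelen = stats::setNames(nchar(nodes$label), nodes$id),
                 minlen = minlen,
                 S = cumsum(minlen),
                 b = g$b),
            class = "efg_block_tables")
}

#' Split a multi-node anchor into node anchors
#'
#' EDS chaining operates on node anchors (subpaths spanning one node): an
#' anchor over `u1...uk` is split into `k` anchors whose query intervals
#' partition `[x..y]` according to the covered label lengths; each split
#' anchor spells its node segment.
#'
#' @param g an `efg` object.
#' @param a an `efg_anchor`.
#' @return list of single-node `efg_anchor` objects.
#' @export
split_to_node_anchors <- function(g, a) {
  sp <- a$subpath
  k <- length(sp$nodes)
  if (k == 1L) return(list(a))
  lens <- nchar(g$label[sp$nodes])
  cov <- c(lens[1L] - sp$i + 1L, if (k > 2L) lens[2:(k - 1L)], sp$j)
  qs <- a$x + c(0L, cumsum(cov))[seq_len(k)]
  lapply(seq_len(k), function(t) {
    i <- if (t == 1L) sp$i else 1L
    anchor(qs[t], qs[t] + cov[t] - 1L, subpath(i, sp$nodes[t], i + cov[t] - 1L),
           strand = a$strand)
  })
}

## Node anchors as a data frame for vectorized chaining.
anchor_frame <- function(anchors, tab) {
  if (!length(anchors)) {
    return(data.frame(x = integer(), y = integer(), node = character(),
                      i = integer(), j = integer(), block = integer(),
                      nlen = integer()))
  }
  df <- data.frame(
    x = vapply(anchors, function(a) a$x, integer(1L)),
    y = vapply(anchors, function(a) a$y, integer(1L)),
    node = vapply(anchors, function(a) a$subpath$nodes[1L], character(1L)),
    i = vapply(anchors, function(a) a$subpath$i, integer(1L)),
    j = vapply(anchors, function(a) a$subpath$j, integer(1L)),
    stringsAsFactors = FALSE)
  df$block <- as.integer(tab$B[df$node])
  df$nlen <- as.integer(tab$nodelen[df$node])
  df <- unique(df)
  df[order(df$x, df$y, df$block, df$i, df$j), , drop = FALSE]
}

#' Precedence of node anchors on the EDS relaxation
#'
#' `Ap` precedes `Aq` iff the query interval of `Ap` precedes that of `Aq`
#' (interval `[x..y]` precedes `[x'..y']` when `x <= x'` and `y <= y'`)
#' and, on the graph side, either the anchors lie on the same node with the
#' offset interval of `Ap` preceding that of `Aq`, or on different nodes
#' with `B[up] < B[uq]` (all consecutive-block pairs are connected on the
#' EDS relaxation). O(1) via the block table.
#'
#' @param ap,aq single-node `efg_anchor` objects on the same strand.
#' @param tab an `efg_block_tables`.
#' @return logical scalar.
#' @export
precedes <- function(ap, aq, tab) {
  if (!(ap$x <= aq$x && ap$y <= aq$y)) return(FALSE)
  up <- ap$subpath$nodes[1L]; uq <- aq$subpath$nodes[1L]
  if (up == uq) {
    ap$subpath$i <= aq$subpath$i && ap$subpath$j <= aq$subpath$j
  } else {
    tab$B[[up]] < tab$B[[uq]]
  }
}

#' Connect cost between node anchors
#'
#' `connect = gap + overlap`. On the same node both follow the
#' sequence-to-sequence formulas with the node offsets playing the role of
#' target coordinates: `gap = max(0, xq-yp-1, iq-jp-1)` and
#' `overlap = |max(0, yp-xq+1) - max(0, jp-iq+1)|`. Across different nodes
#' the graph-side overlap is zero (so the overlap term reduces to the
#' query overlap) and the graph-side gap is the EDS distance
#' `||up|| - jp + sum of intervening minimum block lengths + (iq - 1)`,
#' evaluated in O(1) from the `S` prefix sums; the query-side terms are
#' unchanged.
#'
#' @inheritParams precedes
#' @return non-negative number.
#' @export
connect_cost <- function(ap, aq, tab) {
  if (!precedes(ap, aq, tab)) stop("connect_cost called on a non-preceding pair")
  qgap <- aq$x - ap$y - 1L
  up <- ap$subpath$nodes[1L]; uq <- aq$subpath$nodes[1L]
  if (up == uq) {
    g <- max(0L, qgap, aq$subpath$i - ap$subpath$j - 1L)
    o <- abs(max(0L, ap$y - aq$x + 1L) - max(0L, ap$subpath$j - aq$subpath$i + 1L))
    g + o
  } else {
    bp <- tab$B[[up]]; bq <- tab$B[[uq]]
    ggap <- tab$nodelen[[up]] - ap$subpath$j +
      (tab$S[bq - 1L] - tab$S[bp]) + (aq$subpath$i - 1L)
    max(0L, qgap, ggap) + max(0L, ap$y - aq$x + 1L)
  }
}

## Vectorized connect of rows `ps` (data frame) into single row `q`;
## returns Inf where precedence fails. Also returns the bare gap term for
## the ChainX window check.
connect_vec <- function(ps, q, tab) {
  n <- nrow(ps)
  if (!n) return(list(cost = numeric(0), gap = numeric(0)))
  prec_q <- ps$x <= q$x & ps$y <= q$y
  same <- ps$node == q$node
  cost <- rep(Inf, n)
  gap <- rep(Inf, n)
  qgap <- q$x - ps$y - 1L
  if (any(same)) {
    ok <- same & prec_q & ps$i <= q$i & ps$j <= q$j
    g <- pmax(0L, qgap[ok], q$i - ps$j[ok] - 1L)
    o <- abs(pmax(0L, ps$y[ok] - q$x + 1L) - pmax(0L, ps$j[ok] - q$i + 1L))
    cost[ok] <- g + o
    gap[ok] <- g
  }
  diff <- !same & prec_q & ps$block < q$block
  if (any(diff)) {
    ggap <- ps$nlen[diff] - ps$j[diff] +
      (tab$S[q$block - 1L] - tab$S[ps$block[diff]]) + (q$i - 1L)
    g <- pmax(0L, qgap[diff], ggap)
    o <- pmax(0L, ps$y[diff] - q$x + 1L)
    cost[diff] <- g + o
    gap[diff] <- g
  }
  list(cost = cost, gap = gap)
}

## Terminal connects for the virtual start/end anchors. Global mode charges
## both the query and the graph end-gaps (graph side through the S prefix
## sums); semi-global zeroes the graph-side terms (the read's ends are free
## in the graph but not in the query).
start_connect <- function(df, tab, mode) {
  if (!nrow(df)) return(numeric(0))
  if (mode == "global") {
    pmax(0, df$x - 1L, c(0, tab$S)[df$block] + df$i - 1L)
  } else {
    pmax(0, df$x - 1L)
  }
}

end_connect <- function(df, tab, qlen, mode) {
  if (!nrow(df)) return(numeric(0))
  if (mode == "global") {
    pmax(0, qlen - df$y, (df$nlen - df$j) + (tab$S[tab$b] - tab$S[df$block]))
  } else {
    pmax(0, qlen - df$y)
  }
}

empty_chain_cost <- function(tab, qlen, mode) {
  if (mode == "global") max(qlen, tab$S[tab$b]) else qlen
}

frame_to_anchors <- function(df, strand = "+") {
  lapply(seq_len(nrow(df)), function(t) {
    anchor(df$x[t], df$y[t], subpath(df$i[t], df$node[t], df$j[t]), strand = strand)
  })
}

chain_result <- function(df, sel, cost, mode, iterations = 1L, window = Inf) {
  structure(list(chain = frame_to_anchors(df[sel, , drop = FALSE]),
                 cost = as.numeric(cost), mode = mode,
                 iterations = iterations, window = window),
            class = "efg_chain")
}

#' @export
print.efg_chain <- function(x, ...) {
  cat(sprintf("Co-linear chain (%s): %d anchors, cost %g\n",
              x$mode, length(x$chain), x$cost))
  invisible(x)
}

#' Optimal co-linear chaining by quadratic dynamic programming
#'
#' For each anchor `Aq`, the minimum cost `C[q]` of a chain ending at `Aq`
#' is the minimum of `C[p] + connect(Ap, Aq)` over all preceding anchors,
#' seeded and closed by the virtual start/end anchors of the selected mode.
#' Provably optimal in O(n^2); serves as the oracle for [chain_chainx()].
#' Anchors overlapping in the query are accepted.
#'
#' @param anchors list of single-node `efg_anchor` objects (one strand).
#' @param tab an `efg_block_tables`.
#' @param qlen query (read) length.
#' @param mode `"global"` or `"semiglobal"`.
#' @return An `efg_chain` with the optimal `chain` (ordered anchors) and
#'   its `cost`.
#' @export
chain_dp <- function(anchors, tab, qlen, mode = c("global", "semiglobal")) {
  mode <- match.arg(mode)
  df <- anchor_frame(anchors, tab)
  n <- nrow(df)
  if (!n) return(chain_result(df, integer(0), empty_chain_cost(tab, qlen, mode), mode))
  C <- start_connect(df, tab, mode)
  back <- rep(0L, n)
  for (q in seq_len(n)[-1L]) {
    cv <- connect_vec(df[seq_len(q - 1L), , drop = FALSE], df[q, ], tab)
    tot <- C[seq_len(q - 1L)] + cv$cost
    bst <- which.min(tot)
    if (length(bst) && tot[bst] < C[q]) {
      C[q] <- tot[bst]
      back[q] <- bst
    }
  }
  fin <- C + end_connect(df, tab, qlen, mode)
  ec <- empty_chain_cost(tab, qlen, mode)
  qbest <- which.min(fin)
  if (fin[qbest] <= ec) {
    sel <- integer(0)
    q <- qbest
    while (q > 0L) {
      sel <- c(q, sel)
      q <- back[q]
    }
    chain_result(df, sel, fin[qbest], mode)
  } else {
    chain_result(df, integer(0), ec, mode)
  }
}

#' Iterative windowed chaining with gap check and ramp-up
#'
#' Restricts the dynamic program to transitions whose gap term is at most a
#' window `B` (the gap between anchors is checked rather than the distance
#' between their starting positions), then verifies the solution: when the
#' best cost is at most `B`, every excluded transition alone would cost
#' more than the solution, so the chain is optimal and the algorithm stops;
#' otherwise `B` is multiplied by the ramp-up factor `alpha > 1` and the
#' program re-run. The initial window is the constant `b1`, or
#' `beta * (qlen - coverage)` when `beta` is given (`coverage` = number of
#' query positions covered by the input anchors).
#'
#' @inheritParams chain_dp
#' @param b1 initial window guess (`>= 1`).
#' @param alpha ramp-up factor (`> 1`).
#' @param beta optional coverage-based guess coefficient in `(0, 1]`,
#'   replacing `b1`.
#' @return An `efg_chain`; `iterations` and the final `window` are reported
#'   as diagnostics. The cost equals [chain_dp()]'s whenever the anchors do
#'   not overlap in the query (and on all instances by the gap-check
#'   stopping rule).
#' @export
chain_chainx <- function(anchors, tab, qlen, mode = c("global", "semiglobal"),
                         b1 = 128, alpha = 4, beta = NULL) {
  mode <- match.arg(mode)
  stopifnot(b1 >= 1, alpha > 1)
  df <- anchor_frame(anchors, tab)
  n <- nrow(df)
  if (!n) return(chain_result(df, integer(0), empty_chain_cost(tab, qlen, mode), mode))
  if (!is.null(beta)) {
    stopifnot(beta > 0, beta <= 1)
    cov <- sum(coverage_mask(df, qlen))
    B <- max(1, ceiling(beta * (qlen - cov)))
  } else {
    B <- b1
  }
  cap <- max(qlen, tab$S[tab$b]) + 1
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    C <- start_connect(df, tab, mode)
    back <- rep(0L, n)
    for (q in seq_len(n)[-1L]) {
      cv <- connect_vec(df[seq_len(q - 1L), , drop = FALSE], df[q, ], tab)
      use <- cv$gap <= B
      if (any(use)) {
        tot <- ifelse(use, C[seq_len(q - 1L)] + cv$cost, Inf)
        bst <- which.min(tot)
        if (tot[bst] < C[q]) {
          C[q] <- tot[bst]
          back[q] <- bst
        }
      }
    }
    fin <- C + end_connect(df, tab, qlen, mode)
    qbest <- which.min(fin)
    ec <- empty_chain_cost(tab, qlen, mode)
    cost <- min(fin[qbest], ec)
    if (cost <= B || B >= cap) break
    B <- B * alpha
  }
  if (fin[qbest] <= ec) {
    sel <- integer(0)
    q <- qbest
    while (q > 0L) {
      sel <- c(q, sel)
      q <- back[q]
    }
    chain_result(df, sel, fin[qbest], mode, iterations, B)
  } else {
    chain_result(df, integer(0), cost, mode, iterations, B)
  }
}

## Logical mask of query positions covered by the anchors.
coverage_mask <- function(df, qlen) {
  mask <- logical(qlen)
  for (t in seq_len(nrow(df))) mask[df$x[t]:df$y[t]] <- TRUE
  mask
}

#' Reported subpath implied by a chain
#'
#' Converts a chain of node anchors into the single reported subpath of the
#' alignment skeleton: the chain pins the node choice in every block it
#' touches, and the remaining blocks of the covered range are resolved by a
#' small semiglobal dynamic program (all of the read, a contiguous infix of
#' the graph) restricted to those pinned nodes — each free block
#' contributes its best-matching node, and the end offsets fall out of the
#' traceback. The spelled result is the reported sequence used by the
#' evaluation criteria.
#'
#' @param g an `efg` object.
#' @param chain an `efg_chain` whose `chain` is nonempty.
#' @param Q the read oriented to the forward graph strand (i.e.
#'   reverse-complemented by the caller for `-` strand chains).
#' @return An `efg_subpath`, or `NULL` for an empty chain.
#' @export
chain_implied_subpath <- function(g, chain, Q) {
  as <- chain$chain
  if (!length(as)) return(NULL)
  tab <- block_tables(g)
  n <- nchar(Q)
  qc <- strsplit(Q, "")[[1L]]
  rs <- 0:n

  fixed <- character(0)
  for (a in as) {
    u <- a$subpath$nodes[1L]
    fixed[as.character(tab$B[[u]])] <- u
  }
  bfirst <- tab$B[[as[[1L]]$subpath$nodes[1L]]]
  blast <- tab$B[[as[[length(as)]]$subpath$nodes[1L]]]
  ## extend the block range far enough to cover the uncovered read ends
  ks <- bfirst
  acc <- 0
  while (ks > 1L && acc < as[[1L]]$x + 4L) {
    ks <- ks - 1L
    acc <- acc + tab$minlen[ks]
  }
  ke <- blast
  acc <- 0
  while (ke < tab$b && acc < n - as[[length(as)]]$y + 5L) {
    ke <- ke + 1L
    acc <- acc + tab$minlen[ke]
  }

  INF <- .Machine$integer.max %/% 4L
  boundary <- rep(INF, n + 1L)
  boundary[1L] <- 0L
  store <- list()
  bnd_src <- list()
  best <- list(cost = INF)
  for (k in ks:ke) {
    cand <- if (!is.na(fixed[as.character(k)])) fixed[[as.character(k)]]
            else g$nodes$id[g$nodes$block == k]
    mats <- list()
    newb <- rep(INF, n + 1L)
    srcn <- rep(NA_character_, n + 1L)
    for (v in cand) {
      lab <- strsplit(g$label[[v]], "")[[1L]]
      L <- length(lab)
      D <- matrix(INF, nrow = L + 1L, ncol = n + 1L)
      D[1L, ] <- pmin(boundary, c(0L, rep(INF, n)))
      for (t in seq_len(L)) {
        prev <- D[t, ]
        subc <- as.integer(lab[t] != qc)
        tmp <- pmin(prev[1:n] + subc, prev[2:(n + 1L)] + 1L)
        D[t + 1L, ] <- cummin(c(0L, tmp) - rs) + rs
      }
      mats[[v]] <- D
      fin <- D[-1L, n + 1L]
      tb <- which.min(fin)
      if (fin[tb] < best$cost) best <- list(cost = fin[tb], k = k, v = v, t = tb)
      upd <- D[L + 1L, ] < newb
      newb[upd] <- D[L + 1L, upd]
      srcn[upd] <- v
    }
    store[[as.character(k)]] <- mats
    bnd_src[[as.character(k)]] <- srcn
    boundary <- newb
  }
  if (best$cost >= INF) return(as[[1L]]$subpath)

  ## traceback from the best end cell to a zero-cost start
  k <- best$k; v <- best$v; t <- best$t; r <- n
  j_end <- best$t
  nodes <- character(0)
  i0 <- 1L
  repeat {
    D <- store[[as.character(k)]][[v]]
    lab <- strsplit(g$label[[v]], "")[[1L]]
    while (t > 0L && r > 0L) {
      cur <- D[t + 1L, r + 1L]
      if (cur == D[t, r] + as.integer(lab[t] != qc[r])) {
        t <- t - 1L; r <- r - 1L
      } else if (cur == D[t, r + 1L] + 1L) {
        t <- t - 1L
      } else if (cur == D[t + 1L, r] + 1L) {
        r <- r - 1L
      } else if (cur == 0L && r == 0L) {
        break
      } else {
        break  # reached an exact start cell
      }
    }
    if (r == 0L) {
      ## start of the alignment: offset t+1 in the current node
      if (t < length(lab)) {
        nodes <- c(v, nodes)
        i0 <- t + 1L
      } else {
        i0 <- 1L  # node contributed nothing; start at next node
      }
      break
    }
    ## t == 0 and r > 0: continue in the previous block
    nodes <- c(v, nodes)
    k <- k - 1L
    v <- bnd_src[[as.character(k)]][r + 1L]
    if (is.na(v)) {  # defensive: no source recorded
      i0 <- 1L
      break
    }
    t <- nchar(g$label[[v]])
  }
  if (!length(nodes)) return(as[[1L]]$subpath)
  subpath(i0, nodes, j_end)
}
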