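## One backward pass over Q: for every suffix Q[f..] still occurring in
## T_edges, record its interval and (when nonempty) the interval of
## '#'.Q[f..], i.e. the suffixes that are prefixes of some edge label.
edge_prefix_scan <- function(idx, Q) {
  n <- nchar(Q)
  chs <- strsplit(Q, "")[[1L]]
  iv <- full_interval(idx)
  hash <- vector("list", n)
  qiv <- vector("list", n)
  for (f in seq(n, 1L)) {
    if (!(chs[f] %in% MATCH_ALPHABET)) break  # 'N' and friends never match
    iv <- left_extend(idx, iv, chs[f])
    if (iv[1L] > iv[2L]) break
    qiv[[f]] <- iv
    h <- left_extend(idx, iv, "#")
    if (h[1L] <= h[2L]) hash[[f]] <- h
  }
  list(hash = hash, qiv = qiv)
}

#' Longest query suffix that prefixes an edge label
#'
#' Finds the smallest `f` such that `Q[f..]` is a prefix of some edge label
#' `l(uv)` — equivalently, such that `#`-prepended `Q[f..]` occurs in
#' `T_edges` — by backward extension from the right end of `Q`. Returns
#' `f = nchar(Q) + 1` with an empty interval when no suffix qualifies.
#'
#' @param idx an `efg_index`.
#' @param Q query string.
#' @return list with `f` and `interval`, the suffix-array interval of
#'   `paste0("#", substr(Q, f, nchar(Q)))`.
#' @export
match_suffix_in_edge <- function(idx, Q) {
  n <- nchar(Q)
  stopifnot(n >= 1L)
  scan <- edge_prefix_scan(idx, Q)
  fs <- which(!vapply(scan$hash, is.null, TRUE))
  if (!length(fs)) return(list(f = n + 1L, interval = c(1L, 0L)))
  f <- min(fs)
  list(f = f, interval = scan$hash[[f]])
}

## Prefix Q[1..r] ending exactly at the end of a predecessor chain into
## `cur`: walk right-to-left matching whole node labels (unique by the
## iEFG suffix-uniqueness property), terminating with a partial or full
## first node. Returns all terminal results list(i, nodes).
walk_back <- function(g, Q, cur, r) {
  out <- list()
  for (p in g$inn[[cur]]) {
    lab <- g$label[[p]]
    L <- nchar(lab)
    if (L < r) {
      if (substr(Q, r - L + 1L, r) == lab) {
        for (res in walk_back(g, Q, p, r - L)) {
          out[[length(out) + 1L]] <- list(i = res$i, nodes = c(res$nodes, p))
        }
      }
    } else if (L == r) {
      if (substr(Q, 1L, r) == lab) out[[length(out) + 1L]] <- list(i = 1L, nodes = p)
    } else {
      if (substr(lab, L - r + 1L, L) == substr(Q, 1L, r)) {
        out[[length(out) + 1L]] <- list(i = L - r + 1L, nodes = p)
      }
    }
  }
  out
}

## Deterministic witness order: (block of first node, first node id, start
## offset, then the node id sequence).
order_witnesses <- function(g, ws) {
  if (length(ws) <= 1L) return(ws)
  key <- vapply(ws, function(sp) {
    sprintf("%06d\r%s\r%06d\r%s", g$block[[sp$nodes[1L]]], sp$nodes[1L], sp$i,
            paste(sp$nodes, collapse = "\r"))
  }, character(1L))
  ws[order(key)]
}

#' Exact pattern matching in an indexable elastic founder graph
#'
#' Searches for an occurrence of `Q` as a subpath spelling of the graph
#' using the edge-label text index: occurrences contained in a single edge
#' label are located directly from the suffix-array interval of `Q`;
#' occurrences spanning three or more nodes are reconstructed by trying
#' each split `f'` for which `Q[f'..]` prefixes an edge label `l(w w')`
#' covering `w` entirely, and walking right-to-left from `w` matching whole
#' node labels (each backward step is unique on an iEFG by its
#' suffix-uniqueness property). Never falls back to a whole-graph scan.
#' When several witnesses exist the minimal one under (block of first node,
#' node id, start offset, path) is returned. Queries with symbols outside
#' `A,C,G,T` (including `N`) never match. Every node must be incident to an
#' edge for multi-block graphs (always true for MSA-induced graphs).
#'
#' @param g an `efg` object (semi-repeat-free for the complexity guarantee).
#' @param idx the index from [build_edge_text_index()] for `g`.
#' @param Q nonempty query string.
#' @return list with `found` (logical) and `witness` (`efg_subpath` or
#'   `NULL`); when found, `spell_subpath(g, witness) == Q`.
#' @export
exact_match <- function(g, idx, Q) {
  n <- nchar(Q)
  stopifnot(n >= 1L)
  if (!all(strsplit(Q, "")[[1L]] %in% MATCH_ALPHABET)) {
    return(list(found = FALSE, witness = NULL))
  }
  scan <- edge_prefix_scan(idx, Q)
  ws <- list()

  ## occurrences contained in one edge label (covers 1- and 2-node
  ## matches); vectorized, keeping only the minimal witness of the batch
  ivq <- scan$qiv[[1L]]
  if (!is.null(ivq)) {
    p <- idx$sa[ivq[1L]:ivq[2L]]
    e <- idx$pos_edge[p]
    i <- idx$pos_off[p]
    flen <- idx$edge_tab$from_len[e]
    u <- idx$edge_tab$from[e]
    v <- idx$edge_tab$to[e]
    endo <- i + n - 1L
    in_v <- endo > flen & i > flen
    span <- endo > flen & i <= flen
    first <- ifelse(in_v, v, u)
    ii <- ifelse(in_v, i - flen, i)
    key <- sprintf("%06d\r%s\r%06d\r%s", g$block[first], first, ii,
                   ifelse(span, paste(u, v, sep = "\r"), first))
    t <- which.min(rank(key, ties.method = "first"))
    ws[[1L]] <-
      if (span[t]) subpath(i[t], c(u[t], v[t]), endo[t] - flen[t])
      else if (in_v[t]) subpath(i[t] - flen[t], v[t], endo[t] - flen[t])
      else subpath(i[t], u[t], endo[t])
  }

  ## occurrences spanning >= 3 nodes: split at the start of the second-to-
  ## last node; the suffix must cover that node fully within its edge label
  fs <- which(!vapply(scan$hash, is.null, TRUE))
  for (fp in fs[fs >= 2L]) {
    ivh <- scan$hash[[fp]]
    ls <- n - fp + 1L
    seen <- character(0)
    for (row in ivh[1L]:ivh[2L]) {
      p <- idx$sa[row] + 1L  # first label position after the '#'
      e <- idx$pos_edge[p]
      if (e == 0L) next
      w2 <- idx$edge_tab$to[e]
      if (is.na(w2)) next
      flen <- idx$edge_tab$from_len[e]
      if (ls <= flen) next
      w <- idx$edge_tab$from[e]
      key <- paste0(w, "\r", w2)
      if (key %in% seen) next
      seen <- c(seen, key)
      j <- ls - flen
      for (res in walk_back(g, Q, w, fp - 1L)) {
        ws[[length(ws) + 1L]] <- subpath(res$i, c(res$nodes, w, w2), j)
      }
    }
  }

  if (!length(ws)) return(list(found = FALSE, witness = NULL))
  list(found = TRUE, witness = order_witnesses(g, ws)[[1L]])
}

#' Brute-force exact matching oracle
#'
#' Exhaustive search over every start position (every node, every label
#' offset) with depth-first extension across edges. Works on any graph
#' (semi-repeat-freeness is not required) and serves as the independent
#' oracle for [exact_match()]. In all-occurrences mode, occurrences are
#' identified by their start position (first node, start offset) and one
#' witness per start is reported, with the lexicographically minimal
#' continuation path.
#'
#' @param g an `efg` object.
#' @param Q nonempty query string.
#' @param all logical; enumerate all occurrence starts instead of the first.
#' @return As [exact_match()]; with `all = TRUE`, an extra `occurrences`
#'   list of `efg_subpath` objects (one per start).
#' @export
brute_force_match <- function(g, Q, all = FALSE) {
  stopifnot(nchar(Q) >= 1L)
  occ <- find_starts(g, Q)
  occ <- order_witnesses(g, occ)
  res <- list(found = length(occ) > 0L,
              witness = if (length(occ)) occ[[1L]] else NULL)
  if (all) res$occurrences <- occ
  res
}

#' Longest query suffix occurring in the graph
#'
#' Returns the smallest `y` such that `Q[y..]` occurs in `g`, with one
#' witness subpath, found by binary search on the suffix length (occurrence
#' is monotone: every substring of an occurring string occurs). Returns
#' `y = nchar(Q) + 1` and no witness when no nonempty suffix occurs.
#'
#' @inheritParams exact_match
#' @return list with `y` and `witness` (`efg_subpath` or `NULL`).
#' @export
longest_matching_suffix <- function(g, idx, Q) {
  n <- nchar(Q)
  stopifnot(n >= 1L)
  last <- exact_match(g, idx, substr(Q, n, n))
  if (!last$found) return(list(y = n + 1L, witness = NULL))
  lo <- 1L; hi <- n  # invariant: suffix at hi occurs
  best <- last
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    m <- exact_match(g, idx, substr(Q, mid, n))
    if (m$found) {
      hi <- mid
      best <- m
    } else {
      lo <- mid + 1L
    }
  }
  m <- if (hi == n) best else exact_match(g, idx, substr(Q, hi, n))
  list(y = hi, witness = m$witness)
}
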