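## Brute-force occurrence machinery shared by the semi-repeat-free validator
## and the exact-matching test oracle.

## All (possibly overlapping) occurrence start positions of `pat` in `txt`.
str_occ_all <- function(pat, txt) {
  res <- integer(0)
  s <- 1L
  nt <- nchar(txt)
  repeat {
    if (s > nt) break
    p <- regexpr(pat, substr(txt, s, nt), fixed = TRUE)
    if (p < 0L) break
    res <- c(res, s + as.integer(p) - 1L)
    s <- s + as.integer(p)
  }
  res
}

## Match `rest` starting from the beginning of one of `succs`, continuing
## across edges; returns list(nodes, j) for the lexicographically first
## continuation, or NULL. `rest` must be nonempty.
match_rest <- function(g, succs, rest) {
  nr <- nchar(rest)
  for (v in succs) {
    lab <- g$label[[v]]
    Lv <- nchar(lab)
    if (nr <= Lv) {
      if (substr(lab, 1L, nr) == rest) return(list(nodes = v, j = nr))
    } else if (substr(rest, 1L, Lv) == lab) {
      cont <- match_rest(g, g$out[[v]], substr(rest, Lv + 1L, nr))
      if (!is.null(cont)) return(list(nodes = c(v, cont$nodes), j = cont$j))
    }
  }
  NULL
}

## Every start position (u, i) from which pattern P occurs in g, with one
## witness subpath per start (minimal continuation by node id order).
find_starts <- function(g, P) {
  np <- nchar(P)
  if (np == 0L) stop("empty pattern")
  res <- list()
  ids <- g$nodes$id
  labs <- g$nodes$label
  for (t in seq_along(ids)) {
    u <- ids[t]
    lab <- labs[t]
    L <- nchar(lab)
    ## occurrences fully inside the node label
    if (np <= L && grepl(P, lab, fixed = TRUE)) {
      for (s in str_occ_all(P, lab)) {
        res[[length(res) + 1L]] <- subpath(s, u, s + np - 1L)
      }
    }
    ## occurrences starting inside u and crossing its right boundary
    lo <- max(1L, L - np + 2L)
    if (lo <= L) {
      is <- lo:L
      ok <- substring(lab, is, L) == substring(P, 1L, L - is + 1L)
      for (s in is[ok]) {
        cont <- match_rest(g, g$out[[u]], substr(P, L - s + 2L, np))
        if (!is.null(cont)) {
          res[[length(res) + 1L]] <- subpath(s, c(u, cont$nodes), cont$j)
        }
      }
    }
  }
  res
}

#' Check the semi-repeat-free (indexability) property
#'
#' An elastic founder graph is semi-repeat-free when every occurrence of a
#' node label `l(v)`, `v` in block `k`, as a subpath of the graph starts at
#' the beginning (`i = 1`) of a node of block `k`. The check is an exhaustive
#' subpath search: every start position of every node label is examined
#' (occurrence length is bounded by the label length, which bounds the walk).
#'
#' @param g an `efg` object.
#' @return A list of violations, empty iff the graph is semi-repeat-free.
#'   Each violation is a list with the offending `node` id and the
#'   `subpath` (an `efg_subpath`) where its label occurs illegally.
#' @export
check_semi_repeat_free <- function(g) {
  violations <- list()
  for (t in seq_len(nrow(g$nodes))) {
    v <- g$nodes$id[t]
    blk <- g$nodes$block[t]
    for (sp in find_starts(g, g$nodes$label[t])) {
      if (sp$i != 1L || g$block[[sp$nodes[1L]]] != blk) {
        violations[[length(violations) + 1L]] <- list(node = v, subpath = sp)
      }
    }
  }
  violations
}

#' Validate an elastic founder graph as an iEFG
#'
#' Produces a report asserting (a) the block/label/edge structure, (b) the
#' semi-repeat-free property (via [check_semi_repeat_free()]), and (c) the
#' three uniqueness consequences of indexability, each checked directly by
#' brute force: no two nodes share a label; no node label is a proper suffix
#' of another; every occurrence of an edge label `l(u)l(v)` in the graph
#' starts from the beginning of `u`.
#'
#' @param g an `efg` object.
#' @return An `efg_validation` list with logical fields `structure`,
#'   `distinct_labels`, `no_proper_suffix`, `edge_label_starts`, the
#'   `srf_violations` list, and `is_iefg` true iff all checks pass.
#' @export
validate_efg <- function(g) {
  stopifnot(inherits(g, "efg"))
  srf <- check_semi_repeat_free(g)

  labs <- g$nodes$label
  distinct_labels <- !anyDuplicated(labs)

  no_proper_suffix <- TRUE
  for (t in seq_along(labs)) {
    shorter <- nchar(labs) < nchar(labs[t])
    if (any(endsWith(labs[t], labs[shorter]))) {
      no_proper_suffix <- FALSE
      break
    }
  }

  edge_label_starts <- TRUE
  if (nrow(g$edges)) {
    for (t in seq_len(nrow(g$edges))) {
      u <- g$edges$from[t]
      v <- g$edges$to[t]
      pat <- paste0(g$label[[u]], g$label[[v]])
      for (sp in find_starts(g, pat)) {
        if (sp$i != 1L || sp$nodes[1L] != u) {
          edge_label_starts <- FALSE
          break
        }
      }
      if (!edge_label_starts) break
    }
  }

  rep <- list(structure = TRUE,
              srf_violations = srf,
              distinct_labels = distinct_labels,
              no_proper_suffix = no_proper_suffix,
              edge_label_starts = edge_label_starts,
              is_iefg = length(srf) == 0L && distinct_labels &&
                no_proper_suffix && edge_label_starts)
  class(rep) <- "efg_validation"
  rep
}

#' @export
print.efg_validation <- function(x, ...) {
  cat(sprintf("iEFG validation: %s\n", if (x$is_iefg) "PASS" else "FAIL"))
  cat(sprintf("  semi-repeat-free violations: %d\n", length(x$srf_violations)))
  cat(sprintf("  distinct labels: %s; no proper-suffix labels: %s; edge labels anchored: %s\n",
              x$distinct_labels, x$no_proper_suffix, x$edge_label_starts))
  invisible(x)
}

#' EDS relaxation of an elastic founder graph
#'
#' Drops the edge set: the elastic degenerate string (EDS) over the same
#' blocks conceptually connects every node of block `k` to every node of
#' block `k+1`. `eds_expand()` materializes those edges back into an `efg`.
#'
#' @param g an `efg` object.
#' @return `eds_relaxation()` returns an `efg_eds` (nodes only);
#'   `eds_expand()` an `efg` with all consecutive-block edges.
#' @export
eds_relaxation <- function(g) {
  structure(list(nodes = g$nodes, b = g$b), class = "efg_eds")
}

#' @rdname eds_relaxation
#' @param eds an `efg_eds` object.
#' @export
eds_expand <- function(eds) {
  nodes <- eds$nodes
  edges <- NULL
  if (eds$b > 1L) {
    pieces <- lapply(seq_len(eds$b - 1L), function(k) {
      expand.grid(from = nodes$id[nodes$block == k],
                  to = nodes$id[nodes$block == k + 1L],
                  stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, pieces)
  }
  efg(nodes, edges)
}

#' @export
print.efg_eds <- function(x, ...) {
  cat(sprintf("EDS: %d blocks, %d nodes\n", x$b, nrow(x$nodes)))
  invisible(x)
}

#' Summary statistics of an elastic founder graph
#'
#' Reports the number of blocks `b`, node and edge counts, height `H(G)`
#' (largest block), `L(G)` (longest node label), total label length, and the
#' number of maximal paths, i.e. paths from a block-1 node to a block-b
#' node, counted by dynamic programming over blocks.
#'
#' @param g an `efg` object.
#' @return A named list of statistics.
#' @export
graph_stats <- function(g) {
  cnt <- stats::setNames(numeric(nrow(g$nodes)), g$nodes$id)
  for (k in seq(g$b, 1L)) {
    for (v in efg_block_nodes(g, k)) {
      cnt[v] <- if (k == g$b) 1 else sum(cnt[g$out[[v]]])
    }
  }
  list(b = g$b,
       n_nodes = nrow(g$nodes),
       n_edges = nrow(g$edges),
       height = efg_height(g),
       max_label = efg_max_label(g),
       total_label_length = sum(nchar(g$nodes$label)),
       n_paths = sum(cnt[efg_block_nodes(g, 1L)]))
}

## Exhaustive enumeration of maximal (block-1 to block-b) path spellings;
## test oracle for the path-count DP and for read simulation.
enumerate_paths <- function(g, max_paths = 1e5) {
  res <- list()
  walk <- function(v, acc) {
    acc <- c(acc, v)
    if (g$block[[v]] == g$b) {
      if (length(res) >= max_paths) stop("too many paths to enumerate")
      res[[length(res) + 1L]] <<- acc
      return(invisible())
    }
    for (w in g$out[[v]]) walk(w, acc)
  }
  for (v in efg_block_nodes(g, 1L)) walk(v, character(0))
  res
}
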