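#' Semi-repeat-free seed predicate
#'
#' An anchor is a semi-repeat-free seed when its subpath spans at least a
#' full node: `k > 2`; or `k = 1` with `i = 1` and `j` equal to the label
#' length; or `k = 2` with `i = 1` or `j` equal to the last label length.
#'
#' @param g an `efg` object.
#' @param a an `efg_anchor` (or bare `efg_subpath`).
#' @return logical scalar.
#' @export
is_srf_seed <- function(g, a) {
  sp <- if (inherits(a, "efg_anchor")) a$subpath else a
  k <- length(sp$nodes)
  if (k > 2L) return(TRUE)
  last_len <- nchar(g$label[[sp$nodes[k]]])
  if (k == 1L) return(sp$i == 1L && sp$j == last_len)
  sp$i == 1L || sp$j == last_len
}

#' Greedy semi-repeat-free seeding
#'
#' Right-to-left greedy pass over the read: (1) find the longest suffix of
#' the current prefix that occurs in the graph; (2) report the match as a
#' seed only if it spans at least a full node ([is_srf_seed()]), but always
#' truncate at its start; (3) restart on the remaining prefix. When no
#' nonempty suffix occurs, one trailing character is dropped and the search
#' retried, guaranteeing termination in at most `nchar(Q)` iterations.
#' Seeds from one pass are pairwise disjoint in the query.
#'
#' @param g an `efg` object.
#' @param idx its [build_edge_text_index()] index.
#' @param Q read sequence.
#' @param strand strand tag stored on the emitted anchors.
#' @param keep_matches also return the full list of greedy matches
#'   (including those failing the seed predicate), used by [top_x_expand()].
#' @return list of `efg_anchor` seeds, ordered by query start; with
#'   `keep_matches = TRUE`, a list with fields `seeds` and `matches`.
#' @export
greedy_srf_seeds <- function(g, idx, Q, strand = "+", keep_matches = FALSE) {
  stopifnot(nchar(Q) >= 1L)
  seeds <- list()
  matches <- list()
  e <- nchar(Q)
  while (e >= 1L) {
    res <- longest_matching_suffix(g, idx, substr(Q, 1L, e))
    if (res$y == e + 1L) {
      e <- e - 1L
      next
    }
    a <- anchor(res$y, e, res$witness, strand = strand)
    matches[[length(matches) + 1L]] <- a
    if (is_srf_seed(g, a)) seeds[[length(seeds) + 1L]] <- a
    e <- res$y - 1L
  }
  seeds <- rev(seeds)
  if (keep_matches) list(seeds = seeds, matches = rev(matches)) else seeds
}

#' Expand the X longest greedy matches to all their occurrences
#'
#' Runs the greedy pass recording every match (semi-repeat-free or not),
#' selects the `X` longest matched substrings (ties broken by smaller query
#' start), and reports every occurrence of each selected substring in the
#' graph (occurrences are identified by start position). The seed predicate
#' is not applied to the expanded occurrences.
#'
#' @inheritParams greedy_srf_seeds
#' @param X number of substrings to expand, `X >= 1`.
#' @return list of `efg_anchor` seeds.
#' @export
top_x_expand <- function(g, idx, Q, X, strand = "+") {
  if (X < 1L) stop("X must be >= 1")
  gr <- greedy_srf_seeds(g, idx, Q, strand = strand, keep_matches = TRUE)
  ms <- gr$matches
  if (!length(ms)) return(list())
  len <- vapply(ms, function(a) a$y - a$x + 1L, integer(1L))
  xs <- vapply(ms, function(a) a$x, integer(1L))
  sel <- ms[order(-len, xs)][seq_len(min(X, length(ms)))]
  out <- list()
  for (a in sel) {
    sub <- substr(Q, a$x, a$y)
    for (sp in brute_force_match(g, sub, all = TRUE)$occurrences) {
      out[[length(out) + 1L]] <- anchor(a$x, a$y, sp, strand = strand)
    }
  }
  out
}

#' All full-node seeds via multi-pattern matching
#'
#' Every anchor `([x..y], (1, v, ||v||))` with `l(v) = Q[x..y]`: the
#' complete set of single-node semi-repeat-free seeds, found by scanning
#' the read against all node labels (overlapping occurrences included).
#' Serves as a comparison seeder and as a test oracle.
#'
#' @param g an `efg` object.
#' @param Q read sequence (may be empty, giving no anchors).
#' @param strand strand tag stored on the anchors.
#' @return list of `efg_anchor` objects.
#' @export
full_node_seeds <- function(g, Q, strand = "+") {
  out <- list()
  if (!nzchar(Q)) return(out)
  for (t in seq_len(nrow(g$nodes))) {
    lab <- g$nodes$label[t]
    if (nchar(lab) > nchar(Q)) next
    for (s in str_occ_all(lab, Q)) {
      out[[length(out) + 1L]] <- anchor(s, s + nchar(lab) - 1L,
                                        subpath(1L, g$nodes$id[t], nchar(lab)),
                                        strand = strand)
    }
  }
  out
}

#' Serialize seeds as GAF
#'
#' One GAF line per seed: query name, length, 0-based half-open query
#' interval, strand, path `>u1>u2...`, path length (sum of node label
#' lengths), 0-based path start/end, residue matches, block length, MAPQ
#' 255. Query coordinates of `-` strand seeds refer to the original read;
#' the path is always on the forward graph.
#'
#' @param seeds list of `efg_anchor` objects.
#' @param g an `efg` object.
#' @param qname query (read) name.
#' @param qlen query length.
#' @return character vector of GAF lines (possibly empty).
#' @export
seeds_to_gaf <- function(seeds, g, qname, qlen) {
  vapply(seeds, function(a) {
    sp <- a$subpath
    plen <- sum(nchar(g$label[sp$nodes]))
    alen <- a$y - a$x + 1L
    ps <- sp$i - 1L
    sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
            qname, qlen, a$x - 1L, a$y, a$strand,
            paste0(">", sp$nodes, collapse = ""),
            plen, ps, ps + alen, alen, alen)
  }, character(1L))
}

#' Parse GAF lines back into anchors
#'
#' Inverse of [seeds_to_gaf()] for forward-path GAF records with `>`
#' orientations; used by the chaining front-end.
#'
#' @param lines character vector of GAF lines.
#' @param g an `efg` object.
#' @return data.frame with `qname`, `qlen`, and a list column `anchor`.
#' @export
parse_gaf <- function(lines, g) {
  recs <- lapply(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) stop("short GAF line: ", line)
    nodes <- strsplit(f[6L], ">", fixed = TRUE)[[1L]][-1L]
    if (!length(nodes)) stop("unsupported GAF path: ", f[6L])
    x <- as.integer(f[3L]) + 1L
    y <- as.integer(f[4L])
    i <- as.integer(f[8L]) + 1L
    alen <- y - x + 1L
    pre <- sum(nchar(g$label[nodes[-length(nodes)]])) - (i - 1L)
    j <- if (length(nodes) == 1L) i + alen - 1L else alen - pre
    list(qname = f[1L], qlen = as.integer(f[2L]),
         anchor = anchor(x, y, subpath(i, nodes, j), strand = f[5L]))
  })
  data.frame(qname = vapply(recs, `[[`, character(1L), "qname"),
             qlen = vapply(recs, `[[`, integer(1L), "qlen"),
             anchor = I(lapply(recs, `[[`, "anchor")))
}
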