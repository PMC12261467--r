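#' srfkit: seed-chain alignment on indexable elastic founder graphs
#'
#' Tools to build indexable (semi-repeat-free) elastic founder graphs (iEFGs)
#' from multiple sequence alignments, match patterns against them through an
#' edge-label text index, extract greedy semi-repeat-free seeds from reads,
#' and co-linearly chain the seeds on the elastic-degenerate-string (EDS)
#' relaxation of the graph.
#'
#' An elastic founder graph is a node-labeled DAG whose nodes are partitioned
#' into consecutive blocks \eqn{V_1,\dots,V_b}; edges only join consecutive
#' blocks. The graph is *semi-repeat-free* (indexable) when every node label
#' occurs in the graph only starting at the beginning of nodes of its own
#' block, which is what makes linear-time-style exact matching possible.
#'
#' @keywords internal
"_PACKAGE"

## Alphabet. 'N' is an ordinary symbol for indexing but never matches during
## seeding or exact matching: exact seeds must be real sequence.
EFG_ALPHABET <- c("A", "C", "G", "T", "N")
MATCH_ALPHABET <- c("A", "C", "G", "T")

#' Construct an elastic founder graph
#'
#' Builds an `efg` object from a node table and an edge table and checks the
#' structural invariants of an elastic founder graph: blocks `1..b` partition
#' the node set, every label is a nonempty string over `A,C,G,T,N`, labels
#' are distinct within a block, and every edge joins consecutive blocks.
#'
#' @param nodes data.frame with columns `id` (unique character ids),
#'   `block` (1-based block index) and `label` (nonempty label string).
#' @param edges data.frame with columns `from`, `to` (node ids), or `NULL`
#'   for an edgeless (single-block) graph.
#' @return An object of class `efg` with components `nodes` (ordered by
#'   `(block, label)`), `edges`, `b` (number of blocks), and internal
#'   lookup tables.
#' @examples
#' g <- efg(
#'   nodes = data.frame(id = c("v1", "v2", "v3"),
#'                      block = c(1, 1, 2),
#'                      label = c("AC", "CA", "GG")),
#'   edges = data.frame(from = c("v1", "v2"), to = c("v3", "v3")))
#' g
#' @export
efg <- function(nodes, edges = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "block", "label") %in% names(nodes)))
  nodes <- data.frame(id = as.character(nodes$id),
                      block = as.integer(nodes$block),
                      label = as.character(nodes$label),
                      stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) stop("empty graph: at least one node is required")
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1L])
  }
  if (any(!nzchar(nodes$label))) {
    stop("empty label on node ", nodes$id[!nzchar(nodes$label)][1L])
  }
  bad <- !vapply(strsplit(nodes$label, ""), function(ch) all(ch %in% EFG_ALPHABET), TRUE)
  if (any(bad)) stop("label with symbol outside {A,C,G,T,N} on node ", nodes$id[bad][1L])
  b <- max(nodes$block)
  if (any(nodes$block < 1L) || !all(seq_len(b) %in% nodes$block)) {
    stop("blocks must cover 1..b with every block nonempty")
  }
  dup <- duplicated(paste(nodes$block, nodes$label, sep = "\r"))
  if (any(dup)) {
    stop("duplicate label within block ", nodes$block[dup][1L], ": ", nodes$label[dup][1L])
  }
  ## deterministic node order by (block, label)
  nodes <- nodes[order(nodes$block, nodes$label, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
    edges <- data.frame(from = as.character(edges$from), to = as.character(edges$to),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown)) stop("edge references unknown node: ", unknown[1L])
    edges <- unique(edges)
  }
  block_of <- stats::setNames(nodes$block, nodes$id)
  if (nrow(edges)) {
    bad <- block_of[edges$to] != block_of[edges$from] + 1L
    if (any(bad)) {
      stop("edge between non-consecutive blocks: ",
           edges$from[bad][1L], " -> ", edges$to[bad][1L])
    }
    edges <- edges[order(block_of[edges$from], edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }

  g <- list(nodes = nodes, edges = edges, b = as.integer(b))
  g$label <- stats::setNames(nodes$label, nodes$id)
  g$block <- block_of
  g$out <- split(edges$to, factor(edges$from, levels = nodes$id))
  g$inn <- split(edges$from, factor(edges$to, levels = nodes$id))
  class(g) <- "efg"
  g
}

#' @export
print.efg <- function(x, ...) {
  cat(sprintf("Elastic founder graph: %d blocks, %d nodes, %d edges\n",
              x$b, nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  H(G) = %d, L(G) = %d, total label length = %d\n",
              efg_height(x), efg_max_label(x), sum(nchar(x$nodes$label))))
  invisible(x)
}

#' Graph height, maximum label length, node label length
#'
#' `efg_height` is the maximum number of nodes in a block, `efg_max_label`
#' the maximum node label length; both are derived from the current node
#' table, never stored.
#'
#' @param g an `efg` object.
#' @return integer scalar.
#' @export
efg_height <- function(g) max(tabulate(g$nodes$block, nbins = g$b))

#' @rdname efg_height
#' @export
efg_max_label <- function(g) max(nchar(g$nodes$label))

#' Nodes of one block
#' @param g an `efg` object.
#' @param k block index in `1..b`.
#' @return character vector of node ids, ordered by label.
#' @export
efg_block_nodes <- function(g, k) g$nodes$id[g$nodes$block == k]

#' Test two graphs for equality
#'
#' Graphs are equal when they have the same node ids with the same blocks
#' and labels, and the same edge set; node ordering is immaterial.
#' @param g1,g2 `efg` objects.
#' @return logical scalar.
#' @export
efg_equal <- function(g1, g2) {
  n1 <- g1$nodes[order(g1$nodes$id), ]
  n2 <- g2$nodes[order(g2$nodes$id), ]
  if (!identical(n1$id, n2$id)) return(FALSE)
  if (!identical(n1$block, n2$block) || !identical(n1$label, n2$label)) return(FALSE)
  e1 <- sort(paste(g1$edges$from, g1$edges$to, sep = "\r"))
  e2 <- sort(paste(g2$edges$from, g2$edges$to, sep = "\r"))
  identical(e1, e2)
}

#' Subpaths and anchors
#'
#' A subpath `(i, u1...uk, j)` starts at 1-based position `i` of the first
#' node's label and ends at 1-based position `j` of the last node's label;
#' consecutive nodes must be joined by edges of the graph. An anchor pairs a
#' 1-based inclusive query interval `[x..y]` with a subpath spelling exactly
#' the query substring on the stated strand.
#'
#' @param i,j 1-based start/end offsets in the first/last node label.
#' @param nodes character vector of node ids along the subpath.
#' @return `subpath()` returns an `efg_subpath`; `anchor()` an `efg_anchor`.
#' @export
subpath <- function(i, nodes, j) {
  stopifnot(length(nodes) >= 1L, i >= 1L, j >= 1L)
  structure(list(i = as.integer(i), nodes = as.character(nodes), j = as.integer(j)),
            class = "efg_subpath")
}

#' @rdname subpath
#' @param x,y 1-based inclusive query interval.
#' @param sp an `efg_subpath`.
#' @param strand `"+"` or `"-"`.
#' @export
anchor <- function(x, y, sp, strand = "+") {
  stopifnot(inherits(sp, "efg_subpath"), x >= 1L, y >= x, strand %in% c("+", "-"))
  structure(list(x = as.integer(x), y = as.integer(y), subpath = sp, strand = strand),
            class = "efg_anchor")
}

#' @export
print.efg_subpath <- function(x, ...) {
  cat(sprintf("(%d, %s, %d)\n", x$i, paste(x$nodes, collapse = ""), x$j))
  invisible(x)
}

#' @export
print.efg_anchor <- function(x, ...) {
  cat(sprintf("([%d..%d], (%d, %s, %d), %s)\n", x$x, x$y,
              x$subpath$i, paste(x$subpath$nodes, collapse = ""), x$subpath$j, x$strand))
  invisible(x)
}

#' Spell a subpath
#'
#' Concatenates `l(u1)[i..]`, the full labels of the interior nodes, and
#' `l(uk)[..j]` (for a single node, `l(u1)[i..j]`).
#'
#' @param g an `efg` object.
#' @param sp an `efg_subpath`.
#' @return character scalar.
#' @export
spell_subpath <- function(g, sp) {
  labs <- unname(g$label[sp$nodes])
  if (anyNA(labs)) stop("subpath references unknown node")
  k <- length(labs)
  if (k == 1L) return(substr(labs[1L], sp$i, sp$j))
  paste0(substr(labs[1L], sp$i, nchar(labs[1L])),
         if (k > 2L) paste(labs[2:(k - 1L)], collapse = "") else "",
         substr(labs[k], 1L, sp$j))
}

#' Check subpath structural validity
#'
#' Verifies offsets are within label bounds, consecutive nodes are joined by
#' edges, and `i <= j` when the subpath is a single node.
#' @inheritParams spell_subpath
#' @return TRUE, or an error describing the violation.
#' @export
check_subpath <- function(g, sp) {
  labs <- g$label[sp$nodes]
  if (anyNA(labs)) stop("subpath references unknown node")
  k <- length(labs)
  if (sp$i < 1L || sp$i > nchar(labs[1L])) stop("subpath start offset out of range")
  if (sp$j < 1L || sp$j > nchar(labs[k])) stop("subpath end offset out of range")
  if (k == 1L && sp$i > sp$j) stop("single-node subpath needs i <= j")
  if (k > 1L) {
    for (t in seq_len(k - 1L)) {
      if (!(sp$nodes[t + 1L] %in% g$out[[sp$nodes[t]]])) {
        stop("subpath uses missing edge ", sp$nodes[t], " -> ", sp$nodes[t + 1L])
      }
    }
  }
  TRUE
}

#' Reverse complement
#' @param x character vector of DNA strings over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}
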