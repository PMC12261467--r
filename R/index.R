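## Suffix-array / backward-search machinery for the edge-label text
##   T_edges = "#" . prod_{(u,v) in E} l(u)l(v) "#"
## The suffix array is built over T_edges."$" with $ < # < A < C < G < N < T.

SA_ALPHABET <- c("$", "#", "A", "C", "G", "N", "T")

## Prefix-doubling suffix array; returns 1-based start positions of the
## lexicographically sorted suffixes of chr_vec (which must end in "$").
build_suffix_array <- function(chr_vec) {
  n <- length(chr_vec)
  rk <- match(chr_vec, SA_ALPHABET)
  if (anyNA(rk)) stop("symbol outside the index alphabet")
  if (n == 1L) return(1L)
  k <- 1L
  repeat {
    rk2 <- c(rk[-seq_len(k)], rep(0L, min(k, n)))
    o <- order(rk, rk2)
    nr <- integer(n)
    d <- (rk[o[-1L]] != rk[o[-n]]) | (rk2[o[-1L]] != rk2[o[-n]])
    nr[o] <- cumsum(c(1L, as.integer(d)))
    rk <- nr
    if (max(rk) == n) break
    k <- k * 2L
  }
  order(rk)
}

#' Build the edge-label text index of a graph
#'
#' Concatenates all edge labels `l(u)l(v)` separated by `#` into the text
#' `T_edges`, in a deterministic edge order (sorted by source block, source
#' label, target label), and preprocesses it for backward pattern matching:
#' suffix array, FM-style rank structures for O(1) left extension, and a
#' position map sending every non-`#` text position to its unique
#' `(u, v, i)` with `i` the 1-based offset in `l(uv)`. A graph with a single
#' block has no edges; the text then falls back to the concatenated node
#' labels (a one-block graph is just a set of strings) and the `v` component
#' of the map is `NA`.
#'
#' @param g an `efg` object.
#' @return An `efg_index` with fields `text`, `sa`, the rank structures, the
#'   position maps `pos_edge`/`pos_off`, and the edge table `edge_tab`.
#' @export
build_edge_text_index <- function(g) {
  stopifnot(inherits(g, "efg"))
  if (nrow(g$edges)) {
    et <- g$edges
    o <- order(g$block[et$from], g$label[et$from], g$label[et$to])
    et <- et[o, , drop = FALSE]
    edge_tab <- data.frame(from = et$from, to = et$to,
                           from_len = nchar(g$label[et$from]),
                           label = paste0(g$label[et$from], g$label[et$to]),
                           stringsAsFactors = FALSE)
  } else {
    edge_tab <- data.frame(from = g$nodes$id, to = NA_character_,
                           from_len = nchar(g$nodes$label),
                           label = g$nodes$label,
                           stringsAsFactors = FALSE)
  }
  text <- paste0("#", paste0(edge_tab$label, "#", collapse = ""))
  chars <- strsplit(paste0(text, "$"), "")[[1L]]
  n <- length(chars)
  sa <- build_suffix_array(chars)

  ## position map over text positions (1..nchar(text))
  lens <- nchar(edge_tab$label)
  pos_edge <- integer(n)  # 0 for '#'/terminator
  pos_off <- integer(n)
  p <- 2L
  for (e in seq_along(lens)) {
    idx <- p:(p + lens[e] - 1L)
    pos_edge[idx] <- e
    pos_off[idx] <- seq_len(lens[e])
    p <- p + lens[e] + 1L
  }

  ## FM structures: BWT ranks for constant-time left extension
  bwt <- chars[ifelse(sa == 1L, n, sa - 1L)]
  bwt_rk <- match(bwt, SA_ALPHABET)
  occ <- matrix(0L, nrow = n + 1L, ncol = length(SA_ALPHABET))
  for (a in seq_along(SA_ALPHABET)) {
    occ[, a] <- c(0L, cumsum(bwt_rk == a))
  }
  cnt <- tabulate(match(chars, SA_ALPHABET), nbins = length(SA_ALPHABET))
  C <- c(0L, cumsum(cnt))[seq_along(SA_ALPHABET)]

  structure(list(graph = g, text = text, n = n, sa = sa,
                 occ = occ, C = C,
                 pos_edge = pos_edge, pos_off = pos_off,
                 edge_tab = edge_tab),
            class = "efg_index")
}

#' @export
print.efg_index <- function(x, ...) {
  cat(sprintf("Edge-label text index: |T_edges| = %d over %d %s\n",
              nchar(x$text), nrow(x$edge_tab),
              if (all(is.na(x$edge_tab$to))) "node labels (single-block fallback)" else "edges"))
  invisible(x)
}

#' Suffix-array intervals and backward extension
#'
#' `full_interval()` is the interval of the empty string. `left_extend()`
#' maps the interval of a string `S` to the interval of `c.S` in constant
#' time via FM ranks, returning the empty interval (with `l > r`) when `c.S`
#' does not occur. `sa_count()` gives the interval width.
#'
#' @param idx an `efg_index`.
#' @param interval length-2 integer vector `c(l, r)` of suffix-array rows.
#' @param c a single symbol in `A,C,G,T,N,#`.
#' @return `left_extend()` returns the new interval `c(l, r)`.
#' @export
left_extend <- function(idx, interval, c) {
  a <- match(c, SA_ALPHABET)
  if (is.na(a) || c == "$") stop("symbol outside the index alphabet: ", c)
  l <- interval[1L]; r <- interval[2L]
  if (l > r) return(c(1L, 0L))
  l2 <- idx$C[a] + idx$occ[l, a] + 1L
  r2 <- idx$C[a] + idx$occ[r + 1L, a]
  c(l2, r2)
}

#' @rdname left_extend
#' @export
full_interval <- function(idx) c(1L, idx$n)

#' @rdname left_extend
#' @export
sa_count <- function(interval) max(0L, interval[2L] - interval[1L] + 1L)

## Interval of an arbitrary string by repeated left extension.
bw_search <- function(idx, s) {
  iv <- full_interval(idx)
  for (ch in rev(strsplit(s, "")[[1L]])) {
    iv <- left_extend(idx, iv, ch)
    if (iv[1L] > iv[2L]) break
  }
  iv
}

#' Locate a suffix-array row on the graph
#'
#' For a suffix-array row whose suffix starts at a non-`#` text position,
#' returns the unique edge `(u, v)` and 1-based offset `i` in `l(uv)` of
#' that position (for single-block fallback indexes `v` is `NA` and the
#' offset is within `l(u)`).
#'
#' @param idx an `efg_index`.
#' @param sa_pos suffix-array row (1-based).
#' @return list with `u`, `v`, `i`.
#' @export
edge_locate <- function(idx, sa_pos) {
  stopifnot(sa_pos >= 1L, sa_pos <= idx$n)
  p <- idx$sa[sa_pos]
  e <- if (p <= length(idx$pos_edge)) idx$pos_edge[p] else 0L
  if (e == 0L) stop("suffix starts at a separator (# or terminator)")
  list(u = idx$edge_tab$from[e], v = idx$edge_tab$to[e], i = idx$pos_off[p])
}
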