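#' Read an elastic founder graph from GFA1
#'
#' Parses a GFA1 file with `S` lines (segment id, label) and `L` lines with
#' `0M` overlap. Block membership is taken from the optional `S`-line tag
#' `bl:i:<k>` (1-based). When no segment carries the tag, block indices are
#' inferred as longest-path levels from the in-degree-0 nodes and then
#' validated against the consecutive-block edge requirement; a mix of tagged
#' and untagged segments is rejected.
#'
#' @param path path to a GFA1 file.
#' @return An `efg` object satisfying all structural invariants.
#' @export
parse_gfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seg_id <- character(0); seg_lab <- character(0); seg_bl <- integer(0)
  e_from <- character(0); e_to <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line) || startsWith(line, "H") || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "S") {
      if (length(f) < 3L) stop("GFA parse error at line ", ln, ": short S line")
      if (!nzchar(f[3L]) || f[3L] == "*") {
        stop("GFA parse error at line ", ln, ": empty label on segment ", f[2L])
      }
      bl <- NA_integer_
      if (length(f) > 3L) {
        tag <- grep("^bl:i:", f[-(1:3)], value = TRUE)
        if (length(tag)) bl <- as.integer(sub("^bl:i:", "", tag[1L]))
      }
      seg_id <- c(seg_id, f[2L]); seg_lab <- c(seg_lab, f[3L]); seg_bl <- c(seg_bl, bl)
    } else if (f[1L] == "L") {
      if (length(f) < 6L) stop("GFA parse error at line ", ln, ": short L line")
      if (f[3L] != "+" || f[5L] != "+") {
        stop("GFA parse error at line ", ln, ": only forward (+) links are supported")
      }
      if (!(f[6L] %in% c("0M", "*"))) {
        stop("GFA parse error at line ", ln, ": only 0M overlaps are supported")
      }
      e_from <- c(e_from, f[2L]); e_to <- c(e_to, f[4L])
    } else if (!(f[1L] %in% c("P", "W"))) {
      stop("GFA parse error at line ", ln, ": unsupported record type '", f[1L], "'")
    }
  }
  if (!length(seg_id)) stop("GFA file contains no segments")
  if (anyDuplicated(seg_id)) {
    stop("duplicate node id in GFA: ", seg_id[duplicated(seg_id)][1L])
  }
  if (all(is.na(seg_bl))) {
    seg_bl <- infer_blocks(seg_id, e_from, e_to)
  } else if (anyNA(seg_bl)) {
    stop("inconsistent block tags: some segments carry bl:i and some do not")
  }
  edges <- if (length(e_from)) data.frame(from = e_from, to = e_to) else NULL
  efg(data.frame(id = seg_id, block = seg_bl, label = seg_lab), edges)
}

## Longest-path levels from in-degree-0 nodes; used when bl:i tags are absent.
infer_blocks <- function(ids, e_from, e_to) {
  lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  indeg <- stats::setNames(integer(length(ids)), ids)
  tb <- table(e_to)
  indeg[names(tb)] <- as.integer(tb)
  queue <- ids[indeg == 0L]
  lev[queue] <- 1L
  remaining <- indeg
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in e_to[e_from == u]) {
      lev[v] <- max(lev[v], lev[u] + 1L, na.rm = TRUE)
      remaining[v] <- remaining[v] - 1L
      if (remaining[v] == 0L) queue <- c(queue, v)
    }
  }
  if (anyNA(lev)) stop("block inference failed: graph has a cycle or unreachable node")
  as.integer(lev[ids])
}

#' Write an elastic founder graph to GFA1
#'
#' Serializes the graph with `bl:i` block tags, nodes ordered by
#' `(block, label)` and links as forward `0M` overlaps, so that
#' `parse_gfa(write_gfa(g))` reproduces `g`.
#'
#' @param g an `efg` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path) {
  stopifnot(inherits(g, "efg"))
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s\tbl:i:%d", g$nodes$id, g$nodes$label, g$nodes$block))
  if (nrow(g$edges)) {
    lines <- c(lines, sprintf("L\t%s\t+\t%s\t+\t0M", g$edges$from, g$edges$to))
  }
  writeLines(lines, path)
  invisible(path)
}
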