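#' Multiple sequence alignments
#'
#' An MSA is an `m x n` matrix over `A,C,G,T,N,-` stored as `m` equal-length
#' row strings. Every row must spell a nonempty sequence once gaps are
#' removed.
#'
#' @param rows character vector of gapped row strings, all the same length.
#' @param names optional row names; defaults to `row1..rowm`.
#' @return An `efg_msa` object with components `rows`, `names`, `m`, `n`.
#' @examples
#' m0 <- msa(c("ACGT", "ATGT"))
#' spell("A-C-")
#' @export
msa <- function(rows, names = NULL) {
  rows <- toupper(as.character(rows))
  if (length(rows) < 1L) stop("MSA needs at least one row")
  n <- unique(nchar(rows))
  if (length(n) != 1L || n < 1L) stop("all MSA rows must have the same positive length")
  bad <- !vapply(strsplit(rows, ""), function(ch) all(ch %in% c(EFG_ALPHABET, "-")), TRUE)
  if (any(bad)) stop("MSA row ", which(bad)[1L], " has a symbol outside {A,C,G,T,N,-}")
  if (any(!nzchar(spell(rows)))) {
    stop("MSA row ", which(!nzchar(spell(rows)))[1L], " spells the empty string")
  }
  if (is.null(names)) names <- paste0("row", seq_along(rows))
  structure(list(rows = rows, names = as.character(names),
                 m = length(rows), n = as.integer(n)),
            class = "efg_msa")
}

#' @export
print.efg_msa <- function(x, ...) {
  cat(sprintf("MSA: %d rows x %d columns\n", x$m, x$n))
  invisible(x)
}

#' Spell a gapped sequence
#'
#' Removes gap characters (`-`), recovering the original sequence of an
#' aligned row or row segment.
#'
#' @param x character vector of (possibly gapped) strings.
#' @return character vector with all `-` removed.
#' @export
spell <- function(x) gsub("-", "", x, fixed = TRUE)

#' Read / write a gapped FASTA multiple sequence alignment
#'
#' @param path file path.
#' @return `read_msa_fasta()` returns an `efg_msa`.
#' @export
read_msa_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  msa(as.character(ss), names = names(ss))
}

#' @rdname read_msa_fasta
#' @param x an `efg_msa`.
#' @export
write_msa_fasta <- function(x, path) {
  stopifnot(inherits(x, "efg_msa"))
  ss <- Biostrings::BStringSet(stats::setNames(x$rows, x$names))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## Precomputed context: spelled rows and per-row cumulative non-gap counts
## (cum[i, c+1] = number of non-gap symbols in row i, columns 1..c).
seg_context <- function(x) {
  stopifnot(inherits(x, "efg_msa"))
  m <- x$m; n <- x$n
  cum <- matrix(0L, nrow = m, ncol = n + 1L)
  for (i in seq_len(m)) {
    ng <- strsplit(x$rows[i], "")[[1L]] != "-"
    cum[i, ] <- c(0L, cumsum(ng))
  }
  list(msa = x, m = m, n = n, spelled = spell(x$rows), cum = cum)
}

## Spelled segment strings of columns [x..y], one per row (may be empty).
seg_strings <- function(ctx, x, y) {
  substr(ctx$spelled, ctx$cum[, x] + 1L, ctx$cum[, y + 1L])
}
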