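#' Read FASTA/FASTQ reads
#'
#' @param path read file; FASTQ is detected by extension
#'   (`.fq`/`.fastq`), everything else is parsed as FASTA.
#' @return named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

## Map an anchor found on the reverse complement of a read back to original
## read coordinates (path stays on the forward graph).
orient_anchor_to_read <- function(a, qlen) {
  if (a$strand == "+") return(a)
  anchor(qlen - a$y + 1L, qlen - a$x + 1L, a$subpath, strand = "-")
}

#' Seed-and-optionally-chain alignment pipeline
#'
#' For every read (and its reverse complement unless `both_strands =
#' FALSE`), finds greedy semi-repeat-free seeds ([greedy_srf_seeds()]), or
#' the expanded seed set when `o_x` is given ([top_x_expand()]). With
#' `chain = TRUE`, seeds are split into node anchors and chained per strand
#' ([chain_chainx()]); only the chained anchors of the lower-cost strand
#' are emitted (ties prefer `+`). Output is GAF sorted by read name, with
#' query coordinates always on the original read.
#'
#' @param g an `efg` object (validated as an iEFG unless `validate = FALSE`).
#' @param reads named character vector of read sequences.
#' @param chain chain the seeds and emit only chained anchors.
#' @param mode chaining mode, see [chain_dp()].
#' @param o_x optional `-o X` expansion parameter.
#' @param both_strands also seed the reverse complement.
#' @param min_seed_length drop seeds shorter than this.
#' @param b1,alpha,beta chaining parameters, see [chain_chainx()].
#' @param validate run [validate_efg()] on the graph first.
#' @return list with `gaf` (character lines), `summary` (read count, seed
#'   count, mean read coverage by emitted seeds), and `per_read` details.
#' @export
pipeline_seed_chain <- function(g, reads, chain = FALSE,
                                mode = c("semiglobal", "global"), o_x = NULL,
                                both_strands = TRUE, min_seed_length = 1L,
                                b1 = 128, alpha = 4, beta = NULL,
                                validate = TRUE) {
  mode <- match.arg(mode)
  if (validate) {
    rep <- validate_efg(g)
    if (!rep$is_iefg) stop("input graph is not a valid iEFG; see validate_efg()")
  }
  idx <- build_edge_text_index(g)
  tab <- block_tables(g)
  reads <- reads[order(names(reads))]
  gaf <- character(0)
  per_read <- list()
  n_seeds_total <- 0L
  cov_sum <- 0
  for (rn in names(reads)) {
    seq <- reads[[rn]]
    qlen <- nchar(seq)
    strands <- if (both_strands) c("+", "-") else "+"
    seeds_by_strand <- lapply(strands, function(st) {
      s <- if (st == "+") seq else revcomp(seq)
      sds <- if (is.null(o_x)) greedy_srf_seeds(g, idx, s, strand = st)
             else top_x_expand(g, idx, s, X = o_x, strand = st)
      Filter(function(a) a$y - a$x + 1L >= min_seed_length, sds)
    })
    names(seeds_by_strand) <- strands
    if (chain) {
      chains <- lapply(strands, function(st) {
        node_anchors <- unlist(lapply(seeds_by_strand[[st]],
                                      function(a) split_to_node_anchors(g, a)),
                               recursive = FALSE)
        chain_chainx(node_anchors, tab, qlen, mode = mode,
                     b1 = b1, alpha = alpha, beta = beta)
      })
      names(chains) <- strands
      costs <- vapply(chains, function(ch) ch$cost, numeric(1L))
      best <- strands[which.min(costs)]  # ties resolve to '+', listed first
      emitted <- lapply(chains[[best]]$chain, function(a) {
        a$strand <- best
        orient_anchor_to_read(a, qlen)
      })
      per_read[[rn]] <- list(strand = best, cost = chains[[best]]$cost,
                             anchors = emitted, chain = chains[[best]])
    } else {
      emitted <- unlist(lapply(strands, function(st) {
        lapply(seeds_by_strand[[st]], orient_anchor_to_read, qlen = qlen)
      }), recursive = FALSE)
      per_read[[rn]] <- list(anchors = emitted)
    }
    n_seeds_total <- n_seeds_total + length(emitted)
    cov <- logical(qlen)
    for (a in emitted) cov[a$x:a$y] <- TRUE
    cov_sum <- cov_sum + if (length(emitted)) mean(cov) else 0
    gaf <- c(gaf, seeds_to_gaf(emitted, g, rn, qlen))
  }
  list(gaf = gaf,
       summary = list(n_reads = length(reads),
                      n_seeds = n_seeds_total,
                      mean_coverage = if (length(reads)) cov_sum / length(reads) else 0),
       per_read = per_read)
}

#' Write simulated reads and their ground truth
#'
#' Emits FASTQ (constant quality) plus a tab-separated truth table with the
#' source subpath of each read: name, strand, path, start and end offsets,
#' true sequence.
#'
#' @param records list of `efg_read` objects.
#' @param fastq_path,truth_path output paths.
#' @return invisibly, the truth data.frame.
#' @export
write_simulated_reads <- function(records, fastq_path, truth_path) {
  fq <- unlist(lapply(records, function(r) {
    c(paste0("@", r$name), r$seq, "+", strrep("I", nchar(r$seq)))
  }))
  writeLines(fq, fastq_path)
  truth <- data.frame(
    name = vapply(records, `[[`, character(1L), "name"),
    strand = vapply(records, `[[`, character(1L), "strand"),
    path = vapply(records, function(r) paste0(">", r$truth$nodes, collapse = ""), character(1L)),
    i = vapply(records, function(r) r$truth$i, integer(1L)),
    j = vapply(records, function(r) r$truth$j, integer(1L)),
    true_seq = vapply(records, `[[`, character(1L), "true_seq"))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
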