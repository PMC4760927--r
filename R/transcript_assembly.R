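#' From item trajectories to transcripts
#'
#' Each live item at packing termination occupies one edge at every gap of
#' the canonical order; collapsing the run of edges gives one s-t path,
#' whose interior nodes are spelled into a nucleotide sequence (adjacent
#' nodes overlap by `k - 1` bases).  The item's size is reported as the
#' transcript abundance, in the same coverage units as the edge weights.
#'
#' @name transcript_assembly
NULL

#' Induce the s-t node path of an item
#'
#' @param graph the balanced `splicing_graph` the item was packed on.
#' @param item one element of `run_packing()$items`.
#' @param keep_sentinels keep `s`/`t` in the returned path?
#' @return character vector of node ids in path order (sentinels stripped
#'   by default).
#' @export
trajectory_to_path <- function(graph, item, keep_sentinels = FALSE) {
  traj <- item$traj
  if (!length(traj)) stop("empty trajectory for item ", item$id)
  gaps <- as.integer(names(traj))
  traj <- traj[as.character(sort(gaps))]
  if (!identical(sort(gaps), seq(min(gaps), max(gaps))))
    stop("non-contiguous trajectory for item ", item$id)
  edges <- unname(traj[c(TRUE, traj[-1L] != traj[-length(traj)])])
  parts <- split_edge_key(edges)
  ## consecutive edges must chain head to tail
  if (length(edges) > 1L && !all(parts$v[-length(edges)] == parts$u[-1L]))
    stop("trajectory of item ", item$id, " does not induce a path")
  path <- c(parts$u[[1L]], parts$v)
  if (!keep_sentinels) path <- path[!(path %in% c("s", "t"))]
  path
}

#' Spell the nucleotide sequence of a node path
#'
#' Concatenates the node sequences, collapsing the `k - 1` base overlap at
#' every junction once.  Balancing edges from `s` or to `t` contribute no
#' sequence.
#'
#' @param graph a `splicing_graph` whose nodes carry sequences.
#' @param path character vector of interior node ids.
#' @param k the k-mer length (defaults to `graph$k`).
#' @return a nucleotide string.
#' @export
path_to_sequence <- function(graph, path, k = graph$k) {
  if (is.na(k)) stop("k is unknown; pass it explicitly")
  path <- path[!(path %in% c("s", "t"))]
  if (!length(path)) stop("empty path")
  seqs <- graph$node_seq[path]
  if (any(is.na(seqs))) stop("node without sequence in path")
  out <- seqs[[1L]]
  for (i in seq_along(path)[-1L]) {
    prev <- seqs[[i - 1L]]; cur <- seqs[[i]]
    if (substring(prev, nchar(prev) - k + 2L) != substring(cur, 1L, k - 1L))
      stop("overlap mismatch at junction ", path[[i - 1L]], " -> ", path[[i]])
    out <- paste0(out, substring(cur, k))
  }
  out
}

#' Assemble all transcripts of one balanced component
#'
#' Runs the packing engine and converts every live item into a transcript.
#' A component with a single interior node and no junctions is emitted
#' directly as one transcript with abundance equal to the node coverage.
#'
#' @param graph a balanced `splicing_graph` with sequences.
#' @param gene_id component identifier used in transcript ids.
#' @param min_length minimum reported transcript length in bases
#'   (community convention; `0` disables the filter).
#' @return data.frame with columns `transcript_id`, `gene_id`, `node_path`,
#'   `sequence`, `abundance`, `length`.
#' @export
assemble_component <- function(graph, gene_id = "g1", min_length = 200L) {
  interior <- setdiff(graph$nodes, c("s", "t"))
  k <- graph$k
  if (length(interior) == 1L) {
    seq1 <- graph$node_seq[[interior]]
    cov <- if (!is.null(graph$node_cov) && !is.na(graph$node_cov[interior]))
      graph$node_cov[[interior]] else edge_weight(graph, edge_key("s", interior))
    tr <- data.frame(transcript_id = paste0("BP.", gene_id, ".1"),
                     gene_id = gene_id, node_path = interior,
                     sequence = seq1, abundance = cov, length = nchar(seq1),
                     stringsAsFactors = FALSE)
  } else {
    run <- run_packing(graph)
    rows <- lapply(run$items, function(it) {
      path <- trajectory_to_path(graph, it)
      seq1 <- path_to_sequence(graph, path, k)
      data.frame(node_path = paste(path, collapse = ","), sequence = seq1,
                 abundance = it$size, length = nchar(seq1),
                 stringsAsFactors = FALSE)
    })
    tr <- do.call(rbind, rows)
    tr <- tr[order(-tr$abundance, tr$node_path), , drop = FALSE]
    tr$transcript_id <- sprintf("BP.%s.%d", gene_id, seq_len(nrow(tr)))
    tr$gene_id <- gene_id
    tr <- tr[, c("transcript_id", "gene_id", "node_path", "sequence",
                 "abundance", "length")]
  }
  tr[tr$length >= min_length, , drop = FALSE]
}

#' Write transcripts to FASTA
#'
#' Headers are `BP.<gene>.<n> len=<L> cov=<abundance>`; records are ordered
#' by gene then descending abundance (ties by transcript id) and wrapped at
#' 60 columns.
#'
#' @param transcripts data.frame as produced by [assemble_component()].
#' @param path output FASTA path.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  if (!nrow(transcripts)) stop("no transcripts to write")
  tr <- transcripts[order(transcripts$gene_id, -transcripts$abundance,
                          transcripts$transcript_id), , drop = FALSE]
  x <- Biostrings::DNAStringSet(tr$sequence)
  names(x) <- sprintf("%s len=%d cov=%.4g", tr$transcript_id, tr$length, tr$abundance)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write the per-transcript path report
#'
#' @param transcripts data.frame as produced by [assemble_component()].
#' @param path output TSV path.
#' @export
write_path_report <- function(transcripts, path) {
  utils::write.table(
    transcripts[, c("gene_id", "transcript_id", "node_path", "abundance", "length")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
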