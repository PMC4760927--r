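#' Assemble transcripts from reads
#'
#' The full pipeline over an in-memory read collection: build weighted
#' splicing graphs, augment and balance each component, run the packing
#' engine, and spell transcripts.  Components are processed serially in
#' their deterministic order, so identical inputs give identical outputs.
#'
#' @param reads character vector of read sequences.
#' @param build a [build_config()].
#' @param params a [balance_params()].
#' @param min_length minimum reported transcript length (bases).
#' @return data.frame of transcripts (see [assemble_component()]); the
#'   per-gene balanced graphs are attached as attribute `"graphs"`.
#' @export
assemble_reads <- function(reads, build = build_config(),
                           params = balance_params(), min_length = 200L) {
  comps <- build_splicing_graphs(reads, build)
  balanced <- lapply(comps, function(g) balance_graph(add_source_sink(g), params))
  rows <- Map(function(g, id) assemble_component(g, id, min_length),
              balanced, names(balanced))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "graphs") <- balanced
  out
}

#' Assemble transcripts from FASTA/FASTQ files
#'
#' Thin wrapper around [assemble_reads()] that reads the input files,
#' writes the transcript FASTA, the per-gene path TSV and a JSON run
#' manifest (package version, configuration, seed and per-stage counts)
#' into `out_dir`.
#'
#' @param paths input read files (FASTA/FASTQ, plain or gzip; paired
#'   files are passed as two paths).
#' @param out_dir output directory.
#' @param build a [build_config()].
#' @param params a [balance_params()].
#' @param min_length minimum reported transcript length.
#' @param seed integer recorded in the manifest (the assembler itself is
#'   deterministic).
#' @return the transcript data.frame, invisibly.
#' @export
assemble_files <- function(paths, out_dir, build = build_config(),
                           params = balance_params(), min_length = 200L,
                           seed = 1L) {
  reads <- read_sequences(paths)
  if (!length(reads)) stop("no reads in input: ", paste(paths, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- assemble_reads(reads, build, params, min_length)
  if (nrow(tr)) {
    write_transcript_fasta(tr, file.path(out_dir, "transcripts.fa"))
    write_path_report(tr, file.path(out_dir, "paths.tsv"))
  }
  graphs <- attr(tr, "graphs")
  manifest <- list(
    package = "sgpack",
    version = as.character(utils::packageVersion("sgpack")),
    seed = seed,
    inputs = paths,
    n_reads = length(reads),
    config = build[c("k", "min_kmer_count", "min_junction_reads",
                     "tip_length_factor", "stranded")],
    balance = unclass(params),
    min_length = min_length,
    n_components = length(graphs),
    n_transcripts = nrow(tr))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tr)
}
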