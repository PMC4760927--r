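#' Full-length recovery evaluation
#'
#' A reference transcript is *full-length recovered* by an assembled
#' transcript when a single local alignment covers at least 95% of the
#' reference at 95% identity or better with at most 0.5% indels.
#' Sensitivity is the number of full-length recovered references; the
#' reference true positive rate divides it by the number of assembled
#' transcripts, and the assembled true positive rate is the fraction of
#' assembled transcripts that fully recover some reference.
#'
#' @name evaluation
NULL

#' Align one assembled transcript against one reference
#'
#' Best local alignment (match +1, mismatch -2, gap open -3, gap extend
#' -1).  Identity is matching bases over alignment columns, coverage is
#' the aligned fraction of the *reference* length, and the indel rate is
#' indel bases over alignment columns.  Identical sequences short-circuit
#' the aligner.
#'
#' @param assembled,reference nucleotide strings.
#' @param identity_min,coverage_min,indel_max full-length thresholds.
#' @return a `match_record` list with `identity`, `ref_covered`,
#'   `indel_rate`, `full_length`.
#' @export
align_pair <- function(assembled, reference,
                       identity_min = 0.95, coverage_min = 0.95,
                       indel_max = 0.005) {
  stopifnot(nchar(assembled) > 0, nchar(reference) > 0)
  if (assembled == reference ||
      grepl(reference, assembled, fixed = TRUE)) {
    rec <- list(identity = 1, ref_covered = 1, indel_rate = 0)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(assembled), Biostrings::DNAString(reference),
      type = "local", substitutionMatrix = mat,
      gapOpening = 3, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::pattern(aln))) # columns incl. gaps
    nmat <- Biostrings::nmatch(aln)
    ins <- Biostrings::indel(aln)
    n_indel <- sum(IRanges::width(unlist(Biostrings::insertion(ins)))) +
      sum(IRanges::width(unlist(Biostrings::deletion(ins))))
    ref_span <- IRanges::width(Biostrings::subject(aln))
    rec <- list(identity = if (cols > 0) nmat / cols else 0,
                ref_covered = ref_span / nchar(reference),
                indel_rate = if (cols > 0) n_indel / cols else 0)
  }
  rec$full_length <- rec$identity >= identity_min &&
    rec$ref_covered >= coverage_min && rec$indel_rate <= indel_max
  class(rec) <- "match_record"
  rec
}

#' Score an assembly against a reference set
#'
#' Every (reference, assembled) pair is aligned; references are matched
#' one-to-one to assembled transcripts greedily by identity x coverage
#' (each assembled transcript consumable once; the adopted rule is that a
#' reference counts as recovered only through a single assembled
#' transcript, not a union of fragments).  The assembled true positive
#' rate is computed without consumption: an assembled transcript is a true
#' positive if it fully recovers some reference.
#'
#' @param assembled named character vector of assembled transcript
#'   sequences.
#' @param reference named character vector of reference transcripts.
#' @param identity_min,coverage_min,indel_max thresholds, see
#'   [align_pair()].
#' @return an `eval_report` list: `sensitivity`, `reference_tpr`,
#'   `assembled_tpr`, `length_rate_histogram` (counts over 80..100% best
#'   reference coverage, 1% bins), `matches` (per-reference best match
#'   table), and the thresholds used.
#' @export
evaluate_assembly <- function(assembled, reference,
                              identity_min = 0.95, coverage_min = 0.95,
                              indel_max = 0.005) {
  if (!length(assembled) || !length(reference)) stop("empty input set")
  if (is.null(names(assembled))) names(assembled) <- paste0("asm", seq_along(assembled))
  if (is.null(names(reference))) names(reference) <- paste0("ref", seq_along(reference))
  nr <- length(reference); na <- length(assembled)
  recs <- vector("list", nr * na)
  score <- matrix(0, nr, na, dimnames = list(names(reference), names(assembled)))
  fl <- matrix(FALSE, nr, na)
  cov <- matrix(0, nr, na)
  for (i in seq_len(nr)) for (j in seq_len(na)) {
    r <- align_pair(assembled[[j]], reference[[i]],
                    identity_min, coverage_min, indel_max)
    recs[[(i - 1L) * na + j]] <- r
    score[i, j] <- r$identity * r$ref_covered
    fl[i, j] <- r$full_length
    cov[i, j] <- r$ref_covered
  }
  ## greedy one-to-one matching by score, deterministic tie order
  ord <- order(-as.vector(score), as.vector(row(score)), as.vector(col(score)))
  used_r <- logical(nr); used_a <- logical(na)
  pair_of <- integer(nr)                    # assembled index matched to ref i
  for (idx in ord) {
    i <- row(score)[idx]; j <- col(score)[idx]
    if (used_r[i] || used_a[j] || score[i, j] <= 0) next
    used_r[i] <- TRUE; used_a[j] <- TRUE
    pair_of[i] <- j
  }
  recovered <- vapply(seq_len(nr), function(i) pair_of[i] > 0 && fl[i, pair_of[i]],
                      logical(1))
  sensitivity <- sum(recovered)
  assembled_tp <- sum(vapply(seq_len(na), function(j) any(fl[, j]), logical(1)))
  best_cov <- apply(cov, 1L, max)
  pct <- pmin(100L, as.integer(floor(best_cov * 100)))
  hist_bins <- stats::setNames(integer(21L), paste0(80:100, "%"))
  for (p in pct[pct >= 80L]) hist_bins[[paste0(p, "%")]] <-
    hist_bins[[paste0(p, "%")]] + 1L
  matches <- data.frame(
    reference_id = names(reference),
    assembled_id = ifelse(pair_of > 0, names(assembled)[pmax(pair_of, 1L)], NA),
    identity = vapply(seq_len(nr), function(i)
      if (pair_of[i] > 0) recs[[(i - 1L) * na + pair_of[i]]]$identity else NA_real_,
      numeric(1)),
    ref_covered = vapply(seq_len(nr), function(i)
      if (pair_of[i] > 0) cov[i, pair_of[i]] else NA_real_, numeric(1)),
    full_length = recovered, stringsAsFactors = FALSE)
  structure(list(sensitivity = sensitivity,
                 reference_tpr = sensitivity / na,
                 assembled_tpr = assembled_tp / na,
                 length_rate_histogram = hist_bins,
                 matches = matches,
                 thresholds = c(identity = identity_min,
                                coverage = coverage_min, indel = indel_max),
                 aligner = "pairwiseAlignment(local, +1/-2, gap -3/-1)"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("sensitivity: %d full-length recovered reference transcripts\n",
              x$sensitivity))
  cat(sprintf("reference TPR: %.4f   assembled TPR: %.4f\n",
              x$reference_tpr, x$assembled_tpr))
  invisible(x)
}

#' Write the per-reference evaluation report
#'
#' One row per reference plus a summary block of the three headline
#' statistics.
#'
#' @param report an `eval_report`.
#' @param path output TSV path.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sensitivity\t%d", report$sensitivity), con)
  writeLines(sprintf("# reference_tpr\t%.6f", report$reference_tpr), con)
  writeLines(sprintf("# assembled_tpr\t%.6f", report$assembled_tpr), con)
  utils::write.table(report$matches, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate, assemble and score end to end
#'
#' Runs the generator, the graph builder, balancing, packing, transcript
#' assembly and the evaluator in one call and returns the report with
#' provenance (config and seed).
#'
#' @param config a [sim_config()].
#' @param build a [build_config()].
#' @param params a [balance_params()].
#' @param min_length minimum reported transcript length.
#' @param expression optional list of per-gene expression vectors.
#' @return an `eval_report` with extra fields `transcripts` (assembled
#'   table) and `provenance`.
#' @export
simulate_and_score <- function(config = sim_config(), build = build_config(),
                               params = balance_params(), min_length = 200L,
                               expression = NULL) {
  genes <- make_genes(config, expression = expression)
  sim <- simulate_reads(genes, config)
  tr <- assemble_reads(sim$reads, build, params, min_length)
  refs <- unlist(lapply(genes, function(gm) gm$transcripts))
  rep <- evaluate_assembly(stats::setNames(tr$sequence, tr$transcript_id), refs)
  rep$transcripts <- tr
  rep$truth <- unique(sim$truth[, c("gene_id", "isoform", "depth")])
  rep$provenance <- list(sim = config, build = build, balance = params)
  rep
}
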