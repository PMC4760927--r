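#' Simulation configuration
#'
#' Defines the study conditions for the synthetic RNA-seq generator: toy
#' genes with alternative-splicing isoform sets, expression levels over a
#' wide dynamic range, and error-free or error-bearing reads with known
#' ground truth.
#'
#' @param n_genes number of genes.
#' @param event_types per-gene splicing structure, recycled over genes:
#'   `"single"`, `"skipped_exon"`, `"retained_intron"`,
#'   `"mutually_exclusive"`.
#' @param exon_length_range integer range exon lengths are drawn from.
#' @param read_length read length in bases (a range allows variable-length
#'   reads, drawn uniformly).
#' @param depth_range fold-coverage range expression levels are drawn from
#'   (log-uniform; transcripts span a wide dynamic range, some very low,
#'   some dramatically high).
#' @param error_rate i.i.d. substitution error probability per base,
#'   in `[0, 0.05]`.
#' @param paired emit mate pairs instead of single-end reads?
#' @param fragment_mean,fragment_sd fragment length distribution for
#'   paired mode (normal, truncated to the transcript).
#' @param stranded strand-specific library?
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 10L,
                       event_types = "skipped_exon",
                       exon_length_range = c(200L, 400L),
                       read_length = 100L,
                       depth_range = c(5, 200),
                       error_rate = 0,
                       paired = FALSE,
                       fragment_mean = 250, fragment_sd = 25,
                       stranded = TRUE,
                       seed = 1L) {
  stopifnot(n_genes >= 1, all(exon_length_range > 0), all(read_length > 0),
            all(depth_range > 0), error_rate >= 0, error_rate <= 0.05)
  structure(list(n_genes = as.integer(n_genes), event_types = event_types,
                 exon_length_range = as.integer(exon_length_range),
                 read_length = as.integer(read_length),
                 depth_range = depth_range, error_rate = error_rate,
                 paired = paired, fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, stranded = stranded,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

kmer_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) character() else substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE))
}

#' Generate one synthetic gene model
#'
#' Exon sequences are uniform random DNA; isoform structures realize the
#' requested alternative-splicing event.  Cross-gene k-mer sharing is
#' avoided by rejection sampling against `avoid_kmers` so that each gene
#' yields its own splicing graph.
#'
#' @param gene_id gene identifier.
#' @param event one of `"single"`, `"skipped_exon"`, `"retained_intron"`,
#'   `"mutually_exclusive"`.
#' @param config a [sim_config()] (uses the exon length range and
#'   `depth_range`).
#' @param expression optional per-isoform fold-coverage vector; drawn
#'   log-uniformly from `depth_range` when missing.
#' @param avoid_kmers k-mers that must not occur in this gene (both
#'   strands are checked); rejection-sampled with k = 25.
#' @return a `gene_model` list with `gene_id`, `exons`, `isoforms`
#'   (exon-index lists), `event`, `expression` and the spelled
#'   `transcripts`.
#' @export
make_gene <- function(gene_id, event = "skipped_exon", config = sim_config(),
                      expression = NULL, avoid_kmers = character()) {
  k <- 25L
  n_exons <- switch(event, single = 1L, skipped_exon = 3L,
                    retained_intron = 3L, mutually_exclusive = 4L,
                    stop("unknown event type: ", event))
  isoforms <- switch(event,
    single = list(1L),
    skipped_exon = list(c(1L, 2L, 3L), c(1L, 3L)),
    ## isoform 2 retains the "intron" (exon 2 stands for the intron)
    retained_intron = list(c(1L, 3L), c(1L, 2L, 3L)),
    mutually_exclusive = list(c(1L, 2L, 4L), c(1L, 3L, 4L)))
  for (attempt in 1:50) {
    lens <- sample(seq(config$exon_length_range[1], config$exon_length_range[2]),
                   n_exons, replace = TRUE)
    exons <- vapply(lens, random_dna, character(1))
    tr <- vapply(isoforms, function(ix) paste(exons[ix], collapse = ""), character(1))
    km <- kmer_set(c(tr, as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tr)))), k)
    if (!any(km %in% avoid_kmers)) break
    if (attempt == 50L) stop("could not avoid k-mer collisions for ", gene_id)
  }
  if (is.null(expression)) {
    lo <- log(config$depth_range[1]); hi <- log(config$depth_range[2])
    expression <- exp(stats::runif(length(isoforms), lo, hi))
  }
  stopifnot(length(expression) == length(isoforms), all(expression > 0))
  structure(list(gene_id = gene_id, exons = exons, isoforms = isoforms,
                 event = event, expression = expression,
                 transcripts = stats::setNames(
                   tr, paste0(gene_id, ".iso", seq_along(isoforms)))),
            class = "gene_model")
}

#' Generate a full synthetic gene set
#'
#' @param config a [sim_config()]; `event_types` is recycled over genes.
#' @param expression optional list of per-gene expression vectors.
#' @return list of `gene_model`s.
#' @export
make_genes <- function(config = sim_config(), expression = NULL) {
  set.seed(config$seed)
  events <- rep_len(config$event_types, config$n_genes)
  genes <- vector("list", config$n_genes)
  seen <- character()
  for (i in seq_len(config$n_genes)) {
    genes[[i]] <- make_gene(sprintf("gene%02d", i), events[[i]], config,
                            expression = expression[[i]], avoid_kmers = seen)
    seen <- c(seen, kmer_set(c(genes[[i]]$transcripts,
                               revcomp(genes[[i]]$transcripts)), 25L))
  }
  genes
}

add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1L]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate reads from gene models
#'
#' Per isoform, `round(depth * length / yield)` fragments are drawn with
#' uniform start positions (`yield` = read length, or twice that in
#' paired mode).  Paired mode emits mates from the two fragment ends at a
#' truncated-normal fragment length; substitution errors are i.i.d. at
#' `error_rate`.  Strand-specific mode emits reads on the transcript
#' strand; otherwise each fragment's strand is flipped with probability
#' one half.
#'
#' @param genes list of `gene_model`s (see [make_genes()]).
#' @param config a [sim_config()].
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame read -> gene/isoform, with the target depths).
#' @export
simulate_reads <- function(genes, config = sim_config()) {
  set.seed(config$seed + 1L)
  rl_range <- range(config$read_length)
  reads <- character(); rnames <- character()
  truth <- list()
  for (gm in genes) {
    for (ii in seq_along(gm$isoforms)) {
      iso <- gm$transcripts[[ii]]
      iso_id <- names(gm$transcripts)[[ii]]
      L <- nchar(iso)
      depth <- gm$expression[[ii]]
      if (rl_range[2] > L) stop("read length exceeds isoform length for ", iso_id)
      yield <- if (config$paired) 2L * rl_range[2] else rl_range[2]
      n_frag <- max(1L, round(depth * L / yield))
      rl <- if (rl_range[1] == rl_range[2]) rep(rl_range[1], n_frag)
            else sample(seq(rl_range[1], rl_range[2]), n_frag, replace = TRUE)
      if (config$paired) {
        fl <- pmin(L, pmax(rl, round(stats::rnorm(n_frag, config$fragment_mean,
                                                  config$fragment_sd))))
        start <- floor(stats::runif(n_frag, 1, L - fl + 1 + 1))
        frag <- substring(iso, start, start + fl - 1L)
        r1 <- substring(frag, 1L, rl)
        r2 <- revcomp(substring(frag, pmax(1L, fl - rl + 1L), fl))
        new <- c(r1, r2)
        ids <- c(sprintf("%s_f%d/1", iso_id, seq_len(n_frag)),
                 sprintf("%s_f%d/2", iso_id, seq_len(n_frag)))
      } else {
        start <- floor(stats::runif(n_frag, 1, L - rl + 1 + 1))
        new <- substring(iso, start, start + rl - 1L)
        ids <- sprintf("%s_f%d", iso_id, seq_len(n_frag))
      }
      if (!config$stranded) {
        flip <- stats::runif(length(new)) < 0.5
        new[flip] <- revcomp(new[flip])
      }
      new <- add_errors(new, config$error_rate)
      reads <- c(reads, new); rnames <- c(rnames, ids)
      truth[[length(truth) + 1L]] <-
        data.frame(read_id = ids, gene_id = gm$gene_id, isoform = iso_id,
                   depth = depth, stringsAsFactors = FALSE)
    }
  }
  if (!length(reads)) stop("no reads generated")
  list(reads = stats::setNames(reads, rnames), truth = do.call(rbind, truth))
}

#' Write ground truth to disk
#'
#' Emits the reference transcript FASTA (the evaluation module's reference
#' input) and a TSV of gene, isoform, length and expression.
#'
#' @param genes list of `gene_model`s.
#' @param dir output directory (created if needed).
#' @return invisible list of the two paths.
#' @export
write_truth <- function(genes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- unlist(lapply(genes, function(gm) gm$transcripts))
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tr), fa, width = 60L)
  tab <- do.call(rbind, lapply(genes, function(gm) {
    data.frame(gene_id = gm$gene_id, isoform = names(gm$transcripts),
               length = nchar(gm$transcripts),
               expression = gm$expression, stringsAsFactors = FALSE)
  }))
  tsv <- file.path(dir, "truth.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fa, tsv = tsv))
}

#' Write simulated reads as FASTQ
#'
#' @param reads named character vector from [simulate_reads()].
#' @param path output FASTQ path (fixed quality `"I"`).
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  invisible(path)
}
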