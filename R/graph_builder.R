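#' Builder configuration
#'
#' @param k k-mer length (default 25), `15 <= k <=` read length.
#' @param min_kmer_count noise floor: k-mers seen fewer times are dropped
#'   (default 2, which removes singleton sequencing errors).
#' @param min_junction_reads junction edges supported by fewer spanning
#'   reads are trimmed (default 2).
#' @param tip_length_factor dead-end nodes shorter than
#'   `tip_length_factor * k` with coverage below `min_kmer_count` are
#'   trimmed (default 2).
#' @param stranded is the library strand-specific? If `FALSE`, k-mers are
#'   canonicalized and each component's strand is chosen by a read vote.
#' @return a `build_config` list.
#' @export
build_config <- function(k = 25L, min_kmer_count = 2L, min_junction_reads = 2L,
                         tip_length_factor = 2.0, stranded = TRUE) {
  stopifnot(k >= 2L, min_kmer_count >= 0, min_junction_reads >= 0,
            tip_length_factor >= 0)
  structure(list(k = as.integer(k), min_kmer_count = min_kmer_count,
                 min_junction_reads = min_junction_reads,
                 tip_length_factor = tip_length_factor, stranded = stranded),
            class = "build_config")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## All length-w windows of all reads (reads shorter than w are skipped;
## windows with non-ACGT symbols dropped), as a named count vector.
count_windows <- function(reads, w, canonical = FALSE) {
  lens <- nchar(reads)
  reads <- reads[lens >= w]
  if (!length(reads)) return(stats::setNames(integer(), character()))
  wins <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    substring(r, 1:(n - w + 1L), w:n)
  }), use.names = FALSE)
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (canonical) {
    rc <- revcomp(wins)
    wins <- ifelse(wins <= rc, wins, rc)
  }
  tab <- table(wins)
  stats::setNames(as.integer(tab), names(tab))
}

#' Count k-mers of a read collection
#'
#' Every k-window of every retained read is counted (reads shorter than
#' `k` are skipped and their number logged as attribute `"skipped_reads"`;
#' windows with non-ACGT symbols are dropped).  In unstranded mode a
#' k-mer and its reverse complement are merged under the lexicographically
#' smaller canonical form.
#'
#' @param reads character vector of read sequences.
#' @param config a [build_config()].
#' @return a `kmer_graph` list with `k` and the named count vector
#'   `counts`; adjacency is implied by (k-1)-suffix/prefix overlap.
#' @export
count_kmers <- function(reads, config = build_config()) {
  if (!length(reads)) stop("no reads")
  k <- config$k
  if (k > max(nchar(reads))) stop("k exceeds the longest read length")
  skipped <- sum(nchar(reads) < k)
  counts <- count_windows(reads, k, canonical = !config$stranded)
  structure(list(k = k, counts = counts, skipped_reads = skipped),
            class = "kmer_graph")
}

## index of each k-mer's up-to-4 successors (overlap k-1) within `kmers`
successor_index <- function(kmers, k) {
  suf <- substring(kmers, 2L)
  sapply(c("A", "C", "G", "T"), function(b) match(paste0(suf, b), kmers))
}

#' Collapse maximal unbranched k-mer chains into splicing-graph nodes
#'
#' k-mers surviving the noise floor are linked by (k-1)-overlap; maximal
#' chains in which every interior k-mer has a unique successor whose
#' unique predecessor it is are merged into single nodes (chain spelling,
#' coverage = mean member k-mer count).  Every branching boundary becomes
#' a junction edge (weights are assigned later by [weight_junctions()]).
#' In unstranded mode both orientations are expanded first; components are
#' deduplicated and oriented afterwards by [trim_and_split()].
#'
#' @param kgraph result of [count_kmers()], already filtered to
#'   `counts >= min_kmer_count` by [build_splicing_graphs()] (or by hand).
#' @param config a [build_config()].
#' @return a `splicing_graph` with node sequences and coverages; edge
#'   weights are initialized to 0.
#' @export
collapse_linear_paths <- function(kgraph, config = build_config()) {
  k <- kgraph$k
  kmers <- names(kgraph$counts)
  cnt <- unname(kgraph$counts)
  if (!config$stranded) {
    rc <- revcomp(kmers)
    keep <- rc != kmers
    kmers <- c(kmers, rc[keep]); cnt <- c(cnt, cnt[keep])
    ord <- order(kmers)
    kmers <- kmers[ord]; cnt <- cnt[ord]
  }
  n <- length(kmers)
  if (!n) stop("no k-mers above the noise floor")
  succ <- successor_index(kmers, k)            # n x 4 matrix of indices
  if (is.null(dim(succ))) succ <- matrix(succ, nrow = n)
  outdeg <- rowSums(!is.na(succ))
  indeg <- tabulate(succ[!is.na(succ)], nbins = n)
  uniq_succ <- ifelse(outdeg == 1L, succ[cbind(seq_len(n), max.col(!is.na(succ)))], NA_integer_)
  ## linear link i -> j: i's unique successor is j and j's unique pred is i
  link <- ifelse(!is.na(uniq_succ) & indeg[pmax(uniq_succ, 1L)] == 1L, uniq_succ, NA_integer_)
  has_pred_link <- rep(FALSE, n)
  has_pred_link[link[!is.na(link)]] <- TRUE
  starts <- which(!has_pred_link)
  visited <- rep(FALSE, n)
  node_of <- integer(n)
  chains <- list()
  walk <- function(s) {
    chain <- integer()
    i <- s
    while (!visited[i]) {
      visited[i] <<- TRUE
      chain <- c(chain, i)
      j <- link[i]
      if (is.na(j) || visited[j]) break
      i <- j
    }
    chain
  }
  for (s in starts) if (!visited[s]) chains[[length(chains) + 1L]] <- walk(s)
  for (s in seq_len(n)) if (!visited[s]) chains[[length(chains) + 1L]] <- walk(s) # pure cycles
  ## deterministic node order by chain spelling
  spell <- vapply(chains, function(ch) {
    if (length(ch) == 1L) kmers[ch] else
      paste0(kmers[ch[1L]], paste(substring(kmers[ch[-1L]], k, k), collapse = ""))
  }, character(1))
  ord <- order(spell)
  chains <- chains[ord]; spell <- spell[ord]
  ids <- paste0("n", seq_along(chains))
  for (ci in seq_along(chains)) node_of[chains[[ci]]] <- ci
  covs <- vapply(chains, function(ch) mean(cnt[ch]), numeric(1))
  ## junction edges: de Bruijn links not merged into a chain
  eu <- character(); ev <- character()
  for (ci in seq_along(chains)) {
    tail_k <- chains[[ci]][[length(chains[[ci]])]]
    for (j in succ[tail_k, ]) {
      if (is.na(j)) next
      if (!is.na(link[tail_k]) && link[tail_k] == j) next  # merged internally
      eu <- c(eu, ids[ci]); ev <- c(ev, ids[node_of[j]])
    }
  }
  keep <- !duplicated(paste(eu, ev))
  g <- splicing_graph(ids,
                      data.frame(u = eu[keep], v = ev[keep],
                                 weight = rep(0, sum(keep)), stringsAsFactors = FALSE),
                      node_seq = stats::setNames(spell, ids),
                      node_cov = stats::setNames(covs, ids), k = k)
  g
}

#' Weight junction edges by spanning reads
#'
#' The support of edge `u -> v` is the number of reads containing the
#' junction window: the last `k` bases of `u` followed by the first base
#' of `v` beyond the shared `(k-1)`-overlap (window length `k + 1`, the
#' shortest exactly-matching window that identifies the junction on both
#' sides of a branch).  With `normalize = TRUE` counts are converted to
#' fold-coverage units by the factor `sum(L) / sum(L - w + 1)` over read
#' lengths `L`, so weights estimate the junction's sequencing depth; node
#' coverages are rescaled the same way (window `k`).  Edges with zero
#' support are removed and their number logged as attribute
#' `"dropped_edges"`.
#'
#' @param graph a `splicing_graph` from [collapse_linear_paths()].
#' @param reads the read collection.
#' @param config a [build_config()].
#' @param normalize convert counts to coverage units?
#' @return the weighted graph; raw spanning counts kept in
#'   `graph$edges$count`.
#' @export
weight_junctions <- function(graph, reads, config = build_config(),
                             normalize = FALSE) {
  k <- graph$k
  w <- k + 1L
  if (!nrow(graph$edges)) return(graph)
  tab <- count_windows(reads, w, canonical = !config$stranded)
  useq <- graph$node_seq[graph$edges$u]
  vseq <- graph$node_seq[graph$edges$v]
  jwin <- paste0(substring(useq, nchar(useq) - k + 1L), substring(vseq, k, k))
  if (!config$stranded) {
    rc <- revcomp(jwin)
    jwin <- ifelse(jwin <= rc, jwin, rc)
  }
  count <- tab[jwin]
  count[is.na(count)] <- 0L
  lens <- nchar(reads)
  graph$edges$count <- as.numeric(count)
  if (normalize) {
    f_edge <- sum(lens) / max(1, sum(pmax(lens - w + 1L, 0L)))
    f_node <- sum(lens) / max(1, sum(pmax(lens - k + 1L, 0L)))
    graph$edges$weight <- as.numeric(count) * f_edge
    if (!is.null(graph$node_cov)) graph$node_cov <- graph$node_cov * f_node
  } else {
    graph$edges$weight <- as.numeric(count)
  }
  dropped <- sum(count == 0)
  graph$edges <- graph$edges[count > 0, , drop = FALSE]
  rownames(graph$edges) <- NULL
  attr(graph, "dropped_edges") <- dropped
  graph
}

## merge linear chains at the splicing-graph level (single edge u->v with
## outdeg(u) == 1, indeg(v) == 1): spelling overlap k-1, length-weighted cov
simplify_graph <- function(g) {
  k <- g$k
  repeat {
    outdeg <- table(factor(g$edges$u, levels = g$nodes))
    indeg <- table(factor(g$edges$v, levels = g$nodes))
    cand <- which(outdeg[g$edges$u] == 1L & indeg[g$edges$v] == 1L &
                    g$edges$u != g$edges$v)
    if (!length(cand)) break
    i <- cand[[1L]]
    u <- g$edges$u[i]; v <- g$edges$v[i]
    us <- g$node_seq[[u]]; vs <- g$node_seq[[v]]
    lu <- nchar(us) - k + 1L; lv <- nchar(vs) - k + 1L
    g$node_seq[[u]] <- paste0(us, substring(vs, k))
    if (!is.null(g$node_cov))
      g$node_cov[[u]] <- (g$node_cov[[u]] * lu + g$node_cov[[v]] * lv) / (lu + lv)
    g$edges <- g$edges[-i, , drop = FALSE]
    g$edges$u[g$edges$u == v] <- u
    g$nodes <- g$nodes[g$nodes != v]
    g$node_seq <- g$node_seq[g$nodes]
    if (!is.null(g$node_cov)) g$node_cov <- g$node_cov[g$nodes]
  }
  rownames(g$edges) <- NULL
  g
}

weak_components <- function(g) {
  lab <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  nbrs <- function(n) c(g$edges$v[g$edges$u == n], g$edges$u[g$edges$v == n])
  comp <- 0L
  for (start in g$nodes) {
    if (!is.na(lab[[start]])) next
    comp <- comp + 1L
    queue <- start
    lab[[start]] <- comp
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      for (nb in nbrs(cur)) if (is.na(lab[[nb]])) {
        lab[[nb]] <- comp
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

subgraph_of <- function(g, keep_nodes) {
  sel <- g$edges$u %in% keep_nodes & g$edges$v %in% keep_nodes
  splicing_graph(keep_nodes, g$edges[sel, , drop = FALSE],
                 node_seq = g$node_seq[keep_nodes],
                 node_cov = if (!is.null(g$node_cov)) g$node_cov[keep_nodes],
                 k = g$k)
}

flip_graph <- function(g) {
  g$node_seq <- stats::setNames(revcomp(g$node_seq), names(g$node_seq))
  g$edges <- data.frame(u = g$edges$v, v = g$edges$u, weight = g$edges$weight,
                        stringsAsFactors = FALSE)
  g
}

#' Trim a weighted graph and split it into per-gene components
#'
#' Iterates to a fixed point: junction edges with fewer spanning reads
#' than `min_junction_reads` are removed; dead-end tip nodes shorter than
#' `tip_length_factor * k` with coverage below `min_kmer_count` are
#' removed; surviving linear chains are re-collapsed.  Weakly connected
#' components are then returned as separate graphs, each assumed to be one
#' expressed gene.  In unstranded mode reverse-complement twin components
#' are deduplicated and each survivor is oriented by a read vote over its
#' longest node.
#'
#' @param graph a weighted `splicing_graph`.
#' @param config a [build_config()].
#' @param reads the read collection (needed for unstranded orientation
#'   votes; optional for stranded data).
#' @return named list of `splicing_graph` components (`g1`, `g2`, ...).
#' @export
trim_and_split <- function(graph, config = build_config(), reads = NULL) {
  g <- graph
  k <- g$k
  repeat {
    changed <- FALSE
    ## short, weak tips: dead-end nodes, plus nodes orphaned by earlier
    ## edge removal (legitimate mono-exon nodes are long and stay)
    outdeg <- table(factor(g$edges$u, levels = g$nodes))
    indeg <- table(factor(g$edges$v, levels = g$nodes))
    islen <- nchar(g$node_seq[g$nodes])
    iscov <- if (!is.null(g$node_cov)) g$node_cov[g$nodes] else rep(Inf, length(g$nodes))
    deadend <- indeg[g$nodes] == 0L | outdeg[g$nodes] == 0L
    tip <- as.logical(deadend) &
      islen < config$tip_length_factor * k & iscov < config$min_kmer_count
    if (any(tip) && sum(!tip) >= 1L) {
      drop <- g$nodes[tip]
      g <- subgraph_of(g, setdiff(g$nodes, drop))
      changed <- TRUE
    }
    ## weak junctions (threshold on raw spanning counts when available)
    support <- if (!is.null(g$edges$count)) g$edges$count else g$edges$weight
    weak <- support < config$min_junction_reads
    if (any(weak)) {
      g$edges <- g$edges[!weak, , drop = FALSE]
      changed <- TRUE
    }
    g2 <- simplify_graph(g)
    if (length(g2$nodes) != length(g$nodes)) changed <- TRUE
    g <- g2
    if (!changed) break
  }
  lab <- weak_components(g)
  comps <- lapply(sort(unique(lab)), function(ci) subgraph_of(g, names(lab)[lab == ci]))
  if (!config$stranded) comps <- orient_components(comps, reads)
  ## deterministic component order by smallest node sequence
  keyseq <- vapply(comps, function(cg) min(cg$node_seq), character(1))
  comps <- comps[order(keyseq)]
  stats::setNames(comps, paste0("g", seq_along(comps)))
}

## unstranded mode: drop reverse-complement twins, orient by read vote
orient_components <- function(comps, reads) {
  sig <- vapply(comps, function(cg) paste(sort(cg$node_seq), collapse = "|"), character(1))
  rcsig <- vapply(comps, function(cg) paste(sort(revcomp(cg$node_seq)), collapse = "|"), character(1))
  keep <- sig <= rcsig & !duplicated(pmin(sig, rcsig))
  comps <- comps[keep]
  if (is.null(reads)) return(comps)
  probe_reads <- utils::head(reads, 500L)
  rc_reads <- revcomp(probe_reads)
  lapply(comps, function(cg) {
    longest <- cg$node_seq[[which.max(nchar(cg$node_seq))]]
    fwd <- sum(vapply(probe_reads, function(r) grepl(r, longest, fixed = TRUE),
                      logical(1)))
    rev <- sum(vapply(rc_reads, function(r) grepl(r, longest, fixed = TRUE),
                      logical(1)))
    if (rev > fwd) flip_graph(cg) else cg
  })
}

#' Read sequences from FASTA/FASTQ
#'
#' Paired files are simply concatenated (pairing is not exploited by this
#' builder beyond strand voting).
#'
#' @param paths one or more FASTA/FASTQ paths (plain or gzip).
#' @return character vector of read sequences.
#' @export
read_sequences <- function(paths) {
  out <- lapply(paths, function(p) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p)) "fastq" else "fasta"
    as.character(Biostrings::readDNAStringSet(p, format = fmt))
  })
  unname(unlist(out))
}

#' Build weighted splicing graphs from reads
#'
#' The full front end: k-mer counting, noise-floor filtering, linear-path
#' collapse, junction weighting (in coverage units), cycle breaking,
#' trimming and component splitting.
#'
#' @param reads character vector of read sequences.
#' @param config a [build_config()].
#' @return named list of per-gene `splicing_graph`s.
#' @export
build_splicing_graphs <- function(reads, config = build_config()) {
  kg <- count_kmers(reads, config)
  kg$counts <- kg$counts[kg$counts >= config$min_kmer_count]
  g <- collapse_linear_paths(kg, config)
  g <- weight_junctions(g, reads, config, normalize = TRUE)
  g <- break_cycles(g)
  trim_and_split(g, config, reads)
}
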