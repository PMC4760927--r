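#' Read and write splicing graphs as plain text
#'
#' One graph per record: a header line `>graph <id>`, node lines
#' `N <id> <sequence>` (sequence may be `.` when absent, with an optional
#' fourth column carrying node coverage) and edge lines `E <u> <v> <weight>`
#' with decimal real weights.
#'
#' @param path file path.
#' @return `read_splicing_graphs()` returns a named list of
#'   `splicing_graph` objects.
#' @export
read_splicing_graphs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>graph\\b", lines)
  if (!length(heads)) stop("no '>graph' records in ", path)
  bounds <- c(heads, length(lines) + 1L)
  graphs <- list()
  for (i in seq_along(heads)) {
    id <- trimws(sub("^>graph", "", lines[[heads[[i]]]]))
    body <- lines[seq(heads[[i]] + 1L, bounds[[i + 1L]] - 1L)]
    if (heads[[i]] + 1L > bounds[[i + 1L]] - 1L) body <- character()
    fields <- strsplit(body, "[ \t]+")
    nodes <- character(); seqs <- character(); covs <- numeric()
    eu <- character(); ev <- character(); ew <- numeric()
    for (f in fields) {
      if (f[[1L]] == "N") {
        nodes <- c(nodes, f[[2L]])
        seqs <- c(seqs, if (length(f) >= 3L) f[[3L]] else ".")
        covs <- c(covs, if (length(f) >= 4L) as.numeric(f[[4L]]) else NA_real_)
      } else if (f[[1L]] == "E") {
        eu <- c(eu, f[[2L]]); ev <- c(ev, f[[3L]]); ew <- c(ew, as.numeric(f[[4L]]))
      } else stop("unrecognized line type '", f[[1L]], "' in ", path)
    }
    seqs[seqs == "."] <- NA_character_
    graphs[[id]] <- splicing_graph(
      nodes, data.frame(u = eu, v = ev, weight = ew, stringsAsFactors = FALSE),
      node_seq = stats::setNames(seqs, nodes),
      node_cov = stats::setNames(covs, nodes))
  }
  graphs
}

#' @rdname read_splicing_graphs
#' @param graphs a named list of `splicing_graph` objects (or a single one).
#' @export
write_splicing_graphs <- function(graphs, path) {
  if (inherits(graphs, "splicing_graph")) graphs <- list(graph = graphs)
  if (is.null(names(graphs))) names(graphs) <- paste0("g", seq_along(graphs))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(graphs)) {
    g <- graphs[[id]]
    writeLines(paste0(">graph ", id), con)
    for (nd in g$nodes) {
      sq <- if (!is.null(g$node_seq) && !is.na(g$node_seq[[nd]])) g$node_seq[[nd]] else "."
      cv <- if (!is.null(g$node_cov) && !is.na(g$node_cov[nd])) sprintf(" %g", g$node_cov[[nd]]) else ""
      writeLines(sprintf("N %s %s%s", nd, sq, cv), con)
    }
    if (nrow(g$edges)) {
      writeLines(sprintf("E %s %s %g", g$edges$u, g$edges$v, g$edges$weight), con)
    }
  }
  invisible(path)
}

#' Export a splicing graph as GFA 1.0 for visualization
#'
#' Nodes become `S` segments and junction edges `L` links with the rounded
#' read support in an `RC:i:` tag.  Overlaps are written as `(k-1)M` when
#' the k-mer length is known, else `0M`.
#'
#' @param g a `splicing_graph`.
#' @param path output file.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (nd in g$nodes) {
    sq <- if (!is.null(g$node_seq) && !is.na(g$node_seq[[nd]])) g$node_seq[[nd]] else "*"
    writeLines(sprintf("S\t%s\t%s", nd, sq), con)
  }
  ov <- if (!is.na(g$k)) sprintf("%dM", g$k - 1L) else "0M"
  if (nrow(g$edges)) {
    writeLines(sprintf("L\t%s\t+\t%s\t+\t%s\tRC:i:%d",
                       g$edges$u, g$edges$v, ov, as.integer(round(g$edges$weight))), con)
  }
  invisible(path)
}
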