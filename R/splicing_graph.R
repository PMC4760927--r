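#' Weighted splicing graphs
#'
#' A splicing graph is a weighted directed acyclic graph in which nodes are
#' maximal unspliced sequence segments ("generalized exons") and edges are
#' splice junctions weighted by read support (sequencing depth).  The graph
#' is the central data structure of the assembler: it is balanced with a
#' source `s` and sink `t`, decomposed into s-t paths by the packing engine,
#' and spelled back into transcript sequences.
#'
#' Node identifiers are character strings; `"s"` and `"t"` are reserved for
#' the source and sink sentinels added during augmentation.
#'
#' @param nodes character vector of node ids (no duplicates; `->` forbidden).
#' @param edges data.frame with columns `u`, `v`, `weight` (non-negative).
#' @param node_seq optional named character vector of nucleotide sequences.
#' @param node_cov optional named numeric vector of per-node mean coverage.
#' @param k the k-mer length the graph was built with (adjacent node
#'   sequences overlap by `k - 1` bases), or `NA` for hand-built graphs.
#' @return an object of class `splicing_graph`.
#' @export
splicing_graph <- function(nodes, edges = NULL, node_seq = NULL,
                           node_cov = NULL, k = NA_integer_) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  if (any(grepl("->", nodes, fixed = TRUE))) stop("node ids must not contain '->'")
  if (is.null(edges)) {
    edges <- data.frame(u = character(), v = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    e2 <- data.frame(u = as.character(edges$u), v = as.character(edges$v),
                     weight = as.numeric(edges$weight), stringsAsFactors = FALSE)
    if (!is.null(edges$count)) e2$count <- as.numeric(edges$count)
    edges <- e2
    if (!all(c(edges$u, edges$v) %in% nodes)) stop("edge endpoint not in node set")
    if (any(edges$weight < 0)) stop("negative edge weight")
    if (anyDuplicated(paste(edges$u, edges$v))) stop("duplicate edge")
  }
  g <- list(nodes = nodes, edges = edges,
            node_seq = node_seq, node_cov = node_cov, k = k)
  class(g) <- "splicing_graph"
  g
}

#' @export
print.splicing_graph <- function(x, ...) {
  cat(sprintf("splicing_graph: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is_augmented(x)) " (augmented with s/t)" else ""))
  invisible(x)
}

#' @rdname splicing_graph
#' @param g a `splicing_graph`.
#' @export
is_augmented <- function(g) all(c("s", "t") %in% g$nodes)

edge_key <- function(u, v) paste0(u, "->", v)

edge_keys <- function(g) edge_key(g$edges$u, g$edges$v)

split_edge_key <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)
  list(u = vapply(parts, `[[`, "", 1L), v = vapply(parts, `[[`, "", 2L))
}

edge_weight <- function(g, key) {
  w <- g$edges$weight[match(key, edge_keys(g))]
  if (anyNA(w)) stop("unknown edge: ", paste(key[is.na(w)], collapse = ", "))
  w
}

out_edges <- function(g, node) edge_keys(g)[g$edges$u == node]
in_edges  <- function(g, node) edge_keys(g)[g$edges$v == node]

## Deterministic node ordering: numeric ids compare numerically, with a
## lexicographic fallback, so that "2" < "10" and "s"/"t" sort stably.
node_sort_key <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  order(is.na(num), num, ids)
}

sorted_nodes <- function(ids) ids[node_sort_key(ids)]

adjacency_list <- function(g, reverse = FALSE) {
  e <- g$edges
  if (reverse) split(e$u, factor(e$v, levels = g$nodes))
  else split(e$v, factor(e$u, levels = g$nodes))
}

## Can `from` reach `to` along directed edges (reflexive)?
reaches <- function(g, from, to, adj = NULL) {
  if (from == to) return(TRUE)
  if (is.null(adj)) adj <- adjacency_list(g)
  seen <- character()
  stack <- from
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (nxt in adj[[cur]]) {
      if (nxt == to) return(TRUE)
      if (!(nxt %in% seen)) {
        seen <- c(seen, nxt)
        stack <- c(stack, nxt)
      }
    }
  }
  FALSE
}

#' Remove cycles from a raw directed graph
#'
#' k-mer graphs can contain cycles (repeats); the assembler requires a DAG.
#' Back-edges found by depth-first search are removed, each the
#' minimum-weight edge of the cycle it closes, which sacrifices the least
#' read support.  Acyclic input is returned unchanged.
#'
#' @param g a `splicing_graph` (possibly cyclic).
#' @return an acyclic `splicing_graph`; the number of removed edges is
#'   attached as attribute `"removed_edges"`.
#' @export
break_cycles <- function(g) {
  stopifnot(length(g$nodes) >= 1)
  removed <- 0L
  repeat {
    cyc <- find_cycle(g)
    if (is.null(cyc)) break
    ## cyc: character vector of edge keys forming the cycle
    w <- edge_weight(g, cyc)
    drop <- cyc[which.min(w)]
    g$edges <- g$edges[edge_keys(g) != drop, , drop = FALSE]
    removed <- removed + 1L
  }
  attr(g, "removed_edges") <- removed
  g
}

## Return one directed cycle as a vector of edge keys, or NULL if acyclic.
## Iterative DFS with colouring; deterministic via sorted roots/children.
find_cycle <- function(g) {
  adj <- adjacency_list(g)
  colour <- stats::setNames(rep(0L, length(g$nodes)), g$nodes) # 0 white 1 grey 2 black
  parent <- stats::setNames(rep(NA_character_, length(g$nodes)), g$nodes)
  for (root in sorted_nodes(g$nodes)) {
    if (colour[[root]] != 0L) next
    stack <- list(list(node = root, nbrs = sorted_nodes(adj[[root]]), i = 0L))
    colour[[root]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      if (top$i < length(top$nbrs)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- top$nbrs[[top$i + 1L]]
        if (colour[[nxt]] == 1L) {
          ## back edge top$node -> nxt closes a cycle along grey parents
          path <- top$node
          while (path[[1L]] != nxt) path <- c(parent[[path[[1L]]]], path)
          cyc_nodes <- c(path, nxt)
          return(edge_key(cyc_nodes[-length(cyc_nodes)], cyc_nodes[-1L]))
        }
        if (colour[[nxt]] == 0L) {
          colour[[nxt]] <- 1L
          parent[[nxt]] <- top$node
          stack[[length(stack) + 1L]] <- list(node = nxt,
                                              nbrs = sorted_nodes(adj[[nxt]]), i = 0L)
        }
      } else {
        colour[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      }
    }
  }
  NULL
}

#' Canonical (topological) node order
#'
#' Linearly arranges the nodes of an acyclic splicing graph so that every
#' edge points left to right ("canonical splicing graph").  Kahn's algorithm
#' with a smallest-id priority queue makes the order deterministic; the
#' source `s` (if present) is first and the sink `t` last.
#'
#' @param g an acyclic `splicing_graph`.
#' @return named integer vector: node id -> 0-based contiguous rank.
#' @export
topological_order <- function(g) {
  n <- length(g$nodes)
  indeg <- stats::setNames(rep(0L, n), g$nodes)
  tab <- table(g$edges$v)
  indeg[names(tab)] <- as.integer(tab)
  adj <- adjacency_list(g)
  ## priority: s always first, t always last, else smallest id
  prio <- function(ids) {
    if (!length(ids)) return(ids)
    ids <- sorted_nodes(ids)
    ids <- c(ids[ids == "s"], ids[!(ids %in% c("s", "t"))], ids[ids == "t"])
    ids
  }
  avail <- prio(names(indeg)[indeg == 0L])
  pos <- integer(0)
  rank <- 0L
  while (length(avail)) {
    cur <- avail[[1L]]
    avail <- avail[-1L]
    pos[[cur]] <- rank
    rank <- rank + 1L
    for (nxt in adj[[cur]]) {
      indeg[[nxt]] <- indeg[[nxt]] - 1L
      if (indeg[[nxt]] == 0L) avail <- prio(c(avail, nxt))
    }
  }
  if (rank < n) {
    cyc <- find_cycle(g)
    stop("graph has a cycle: ", paste(cyc, collapse = " , "))
  }
  pos
}

#' Edge compatibility
#'
#' Two edges are compatible if some directed path contains both, i.e. they
#' could be splice junctions of one transcript.  For `e1 = (a,b)` and
#' `e2 = (c,d)` this holds iff `b` reaches `c`, or `d` reaches `a`, or the
#' edges are identical.
#'
#' @param g a `splicing_graph`.
#' @param e1,e2 edge keys of the form `"u->v"`.
#' @return logical scalar.
#' @export
are_compatible <- function(g, e1, e2) {
  keys <- edge_keys(g)
  if (!(e1 %in% keys)) stop("unknown edge: ", e1)
  if (!(e2 %in% keys)) stop("unknown edge: ", e2)
  if (e1 == e2) return(TRUE)
  p1 <- split_edge_key(e1); p2 <- split_edge_key(e2)
  adj <- adjacency_list(g)
  reaches(g, p1$v, p2$u, adj) || reaches(g, p2$v, p1$u, adj)
}

#' Edges crossing a gap of the canonical order
#'
#' Gap `p` sits between ranks `p` and `p + 1` (0-based).  An edge `(u,v)`
#' crosses the gap iff `rank(u) <= p < rank(v)`.  The crossing edges of any
#' gap are pairwise incompatible: a directed path visits the gap at most
#' once.
#'
#' @param g a `splicing_graph`.
#' @param order result of [topological_order()].
#' @param p gap index, `0 <= p < |V| - 1`.
#' @return list with `gap_index` and `crossing_edges` (edge keys).
#' @export
crossing_edges <- function(g, order, p) {
  if (p < 0 || p >= length(g$nodes) - 1L) stop("gap index out of range: ", p)
  sel <- order[g$edges$u] <= p & order[g$edges$v] > p
  list(gap_index = as.integer(p), crossing_edges = edge_keys(g)[sel])
}

#' Maximal set of pairwise incompatible edges
#'
#' Scans every gap of the canonical order and returns the crossing set of
#' maximum cardinality (leftmost gap on ties).  On a balanced graph, where
#' every edge lies on some s-t path, this set is maximal: no further edge
#' can be added while keeping all pairs incompatible.  It seeds the packing
#' iteration with one item per edge.
#'
#' @inheritParams crossing_edges
#' @return list with `gap_index` and `crossing_edges`.
#' @export
max_incompatible_set <- function(g, order) {
  if (nrow(g$edges) == 0L) stop("nothing to pack: graph has no edges")
  n_gaps <- length(g$nodes) - 1L
  sizes <- vapply(seq_len(n_gaps) - 1L,
                  function(p) length(crossing_edges(g, order, p)$crossing_edges),
                  integer(1))
  best <- which.max(sizes) - 1L # which.max returns the first (leftmost) max
  crossing_edges(g, order, best)
}
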