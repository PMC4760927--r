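#' Random balanced splicing graphs for property checking
#'
#' Generates a sparse random DAG on `n` interior nodes (every non-source
#' node gets one in-edge from a random earlier node, plus a few extra
#' forward edges; integer weights in `[1, 50]`), then augments and
#' balances it.  Splicing graphs of real genes are sparse -- alternative
#' splicing adds a handful of branches to a mostly linear backbone -- and
#' the generator mirrors that.  Used by the property tests of the cut
#' detector and the packing engine.
#'
#' @param n number of interior nodes (>= 2).
#' @param seed integer seed.
#' @param extra_edge_prob probability scale for additional forward edges.
#' @param params a [balance_params()].
#' @return a balanced `splicing_graph`.
#' @export
random_balanced_graph <- function(n, seed, extra_edge_prob = 1,
                                  params = balance_params()) {
  stopifnot(n >= 2)
  set.seed(seed)
  ids <- as.character(seq_len(n))
  eu <- character(); ev <- character()
  for (j in 2:n) {
    i <- sample(j - 1L, 1L)
    eu <- c(eu, ids[[i]]); ev <- c(ev, ids[[j]])
  }
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < extra_edge_prob / n &&
        !any(eu == ids[[i]] & ev == ids[[j]])) {
      eu <- c(eu, ids[[i]]); ev <- c(ev, ids[[j]])
    }
  }
  w <- sample(50L, length(eu), replace = TRUE)
  g <- splicing_graph(ids, data.frame(u = eu, v = ev, weight = as.numeric(w),
                                      stringsAsFactors = FALSE))
  balance_graph(add_source_sink(g), params)
}

#' A worked trap/reversal example graph
#'
#' A balanced nine-node graph (interior nodes `1..7`) whose packing run
#' starts at node 4, traps at node 2 (reversing right), traps again at
#' node 6 (reversing left), reaches the source, and jumps back to node 6
#' to finish rightwards -- the canonical forth-and-back iteration pattern
#' with direction sequence `left, right, left, (jump), right`.
#'
#' @return a balanced `splicing_graph`.
#' @export
example_trap_graph <- function() {
  E <- rbind(
    c("s", "1", 25), c("s", "2", 15), c("s", "3", 60),
    c("1", "2", 25), c("2", "3", 40), c("3", "4", 40),
    c("3", "5", 20), c("3", "7", 40), c("4", "5", 10), c("4", "7", 30),
    c("5", "6", 30), c("6", "7", 20), c("6", "t", 15), c("7", "t", 85))
  splicing_graph(c("s", as.character(1:7), "t"),
                 data.frame(u = E[, 1], v = E[, 2],
                            weight = as.numeric(E[, 3]),
                            stringsAsFactors = FALSE))
}
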