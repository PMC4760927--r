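#' Balancing parameters
#'
#' The balancing threshold at a node `u` is
#' `c = alpha * (gamma - beta) / w_min + beta`, with
#' `w_min = min(w_in(u), w_out(u))`.  The threshold decays from large values
#' at weakly covered nodes towards `beta` at deeply covered ones, so a given
#' in/out imbalance must be more extreme to be trusted at low coverage.
#' Defaults are `alpha = 10`, `beta = 1.4`, `gamma = 1.5`.
#'
#' @param alpha,beta,gamma non-negative reals with `gamma >= beta >= 1`.
#' @return a `balance_params` list.
#' @export
balance_params <- function(alpha = 10, beta = 1.4, gamma = 1.5) {
  stopifnot(alpha >= 0, beta >= 1, gamma >= beta)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "balance_params")
}

#' Augment a splicing graph with source and sink
#'
#' Adds sentinel nodes `s` and `t`; `s` is connected to every node with no
#' in-edges (edge weight = the sum of that node's out-weights) and every
#' node with no out-edges is connected to `t` (weight = sum of its
#' in-weights).  An isolated node gets both edges, weighted by its coverage.
#'
#' @param g an acyclic `splicing_graph` without sentinels.
#' @return the augmented graph, with `$source` and `$sink` set.
#' @export
add_source_sink <- function(g) {
  if (any(c("s", "t") %in% g$nodes)) stop("already augmented with s/t")
  stopifnot(length(g$nodes) >= 1)
  wout <- vapply(g$nodes, function(n) sum(g$edges$weight[g$edges$u == n]), numeric(1))
  win  <- vapply(g$nodes, function(n) sum(g$edges$weight[g$edges$v == n]), numeric(1))
  has_out <- g$nodes %in% g$edges$u
  has_in  <- g$nodes %in% g$edges$v
  cov <- function(n) {
    if (!is.null(g$node_cov) && !is.na(g$node_cov[n])) g$node_cov[[n]] else 1
  }
  new_e <- list()
  for (i in seq_along(g$nodes)) {
    n <- g$nodes[[i]]
    if (!has_in[i]) {
      w <- if (has_out[i]) wout[[i]] else cov(n)
      new_e[[length(new_e) + 1L]] <- data.frame(u = "s", v = n, weight = w)
    }
    if (!has_out[i]) {
      w <- if (has_in[i]) win[[i]] else cov(n)
      new_e[[length(new_e) + 1L]] <- data.frame(u = n, v = "t", weight = w)
    }
  }
  g2 <- g
  g2$nodes <- c("s", g$nodes, "t")
  g2$edges <- rbind_edges(g$edges, do.call(rbind, new_e))
  if (!is.null(g2$node_seq)) g2$node_seq <- c(s = NA_character_, g$node_seq, t = NA_character_)
  g2$source <- "s"; g2$sink <- "t"
  g2
}

#' In/out weight balance of an interior node
#'
#' Computes `w_in`, `w_out`, `w_min` and the threshold
#' `c = alpha * (gamma - beta) / w_min + beta` for one node.  When
#' `w_min = 0` the threshold is reported as `Inf` (such nodes are always
#' treated as transcript ends by [balance_graph()]).
#'
#' @param g an augmented `splicing_graph`.
#' @param u an interior node id (not `s`/`t`); sentinel edges count towards
#'   the weights.
#' @param params a [balance_params()] object.
#' @return list with `node`, `w_in`, `w_out`, `w_min`, `c`.
#' @export
node_balance <- function(g, u, params = balance_params()) {
  if (u %in% c("s", "t")) stop("node_balance is undefined for sentinels")
  if (!(u %in% g$nodes)) stop("unknown node: ", u)
  w_in <- sum(g$edges$weight[g$edges$v == u])
  w_out <- sum(g$edges$weight[g$edges$u == u])
  w_min <- min(w_in, w_out)
  cthr <- if (w_min > 0) params$alpha * (params$gamma - params$beta) / w_min + params$beta else Inf
  list(node = u, w_in = w_in, w_out = w_out, w_min = w_min, c = cthr)
}

#' Balance a splicing graph
#'
#' A node whose out-weight dominates its in-weight (`w_out / w_in >= c`)
#' is taken to be the start of a transcript interior to the graph: an edge
#' `s -> u` with weight `w_out - w_in` is added.  Symmetrically,
#' `w_in / w_out >= c` adds `u -> t` with weight `w_in - w_out`.  All
#' decisions use the pre-balancing weights in a single pass over the nodes
#' in canonical order, so the outcome does not depend on node order and a
#' second pass adds nothing (the augmented side is equalized).
#'
#' @param g an augmented `splicing_graph` (see [add_source_sink()]).
#' @param params a [balance_params()] object.
#' @return the balanced graph.
#' @export
balance_graph <- function(g, params = balance_params()) {
  if (!is_augmented(g)) stop("balance_graph requires an s/t-augmented graph")
  ord <- topological_order(g)
  interior <- names(sort(ord))
  interior <- interior[!(interior %in% c("s", "t"))]
  add <- list()
  for (u in interior) {
    nb <- node_balance(g, u, params)
    if (nb$w_min == 0) {
      ## a one-sided node missed by augmentation (weight-0 side): treat as
      ## always unbalanced, weight = the nonzero side
      if (nb$w_out > nb$w_in && !any(g$edges$u == "s" & g$edges$v == u)) {
        add[[length(add) + 1L]] <- data.frame(u = "s", v = u, weight = nb$w_out - nb$w_in)
      } else if (nb$w_in > nb$w_out && !any(g$edges$u == u & g$edges$v == "t")) {
        add[[length(add) + 1L]] <- data.frame(u = u, v = "t", weight = nb$w_in - nb$w_out)
      }
      next
    }
    if (nb$w_out / nb$w_in >= nb$c && !any(g$edges$u == "s" & g$edges$v == u)) {
      add[[length(add) + 1L]] <- data.frame(u = "s", v = u, weight = nb$w_out - nb$w_in)
    }
    if (nb$w_in / nb$w_out >= nb$c && !any(g$edges$u == u & g$edges$v == "t")) {
      add[[length(add) + 1L]] <- data.frame(u = u, v = "t", weight = nb$w_in - nb$w_out)
    }
  }
  if (length(add)) {
    g$edges <- rbind_edges(g$edges, do.call(rbind, add))
  }
  g
}

## rbind edge tables whose optional raw-count columns may differ
rbind_edges <- function(a, b) {
  if (!is.null(a$count) && is.null(b$count) && !is.null(b)) b$count <- NA_real_
  if (is.null(a$count) && !is.null(b$count)) a$count <- NA_real_
  out <- rbind(a, b)
  rownames(out) <- NULL
  out
}
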