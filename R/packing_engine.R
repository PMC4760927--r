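#' The forth-and-back bin-packing iteration
#'
#' The engine decomposes a balanced splicing graph into s-t paths.  Items
#' (tracked tokens whose sizes approximate isoform coverages) are seeded on
#' the maximal pairwise-incompatible edge cut, then pushed node by node
#' towards the source; at each node the items carried by the edges on one
#' side are packed into the edges (bins) on the other side by an exact 0-1
#' solve.  A *trap node* -- fewer item-carrying edges than receiving edges
#' -- retires the local items, replaces them with one new item per
#' receiving edge, and reverses the sweep direction.  Reaching a terminal
#' with unprocessed nodes left jumps back to the start of the current
#' sweep.  Previously processed nodes are never trapped again; re-crossing
#' them re-solves the local packing with per-bin occupancy lower bounds so
#' earlier structure is refined, not contradicted.
#'
#' At termination every live item occupies one edge at every gap of the
#' canonical order; the run of edges of one item is its *trajectory* and
#' induces one s-t path.
#'
#' @name packing_engine
NULL

other_direction <- function(direction) if (direction == "left") "right" else "left"

new_packing_state <- function(graph, order, trace = FALSE) {
  ranks <- sort(order)
  env <- new.env(parent = emptyenv())
  env$graph <- graph
  env$order <- order
  env$nodes_by_rank <- names(ranks)          # rank r -> node id (1-based index r+1)
  env$items <- list()                        # item_id -> list(id, size, origin, traj)
  env$next_item <- 1L
  env$processed <- character()
  env$gap_lo <- NA_integer_; env$gap_hi <- NA_integer_ # assigned gap range
  env$events <- list()                       # sweep/trap/jump log
  env$trace <- if (trace) list() else NULL
  env$reversals <- 0L
  env
}

node_at_rank <- function(state, r) state$nodes_by_rank[[r + 1L]]

## items occupying edge `key` at gap `p`
items_at <- function(state, p, keys) {
  kp <- as.character(p)
  Filter(function(it) !is.na(it$traj[kp]) && it$traj[[kp]] %in% keys, state$items)
}

occupancy_at <- function(state, p, keys) {
  kp <- as.character(p)
  here <- vapply(state$items, function(it) {
    v <- it$traj[kp]
    if (is.na(v)) NA_character_ else unname(v)
  }, character(1))
  occ <- vapply(keys, function(k) sum(!is.na(here) & here == k), numeric(1))
  stats::setNames(as.integer(occ), keys)
}

#' Seed items on the maximal incompatible cut
#'
#' One item per cut edge, sized by the edge weight; the cursor starts at
#' the left endpoint of the cut's gap and the first sweep moves left.
#'
#' @param graph a balanced `splicing_graph`.
#' @param cut result of [max_incompatible_set()].
#' @param order result of [topological_order()]; recomputed when missing.
#' @param trace keep a per-node-visit debug trace?
#' @return a packing state (environment).
#' @export
init_items <- function(graph, cut, order = NULL, trace = FALSE) {
  if (!length(cut$crossing_edges)) stop("empty cut: nothing to seed")
  if (is.null(order)) order <- topological_order(graph)
  state <- new_packing_state(graph, order, trace)
  p <- cut$gap_index
  for (e in cut$crossing_edges) {
    id <- sprintf("i%03d", state$next_item)
    state$next_item <- state$next_item + 1L
    traj <- stats::setNames(e, as.character(p))
    state$items[[id]] <- list(id = id, size = edge_weight(graph, e),
                              origin = list(iteration = 0L, edge = e), traj = traj)
  }
  state$gap_lo <- p; state$gap_hi <- p
  state$start_gap <- p
  state
}

#' Partition the incident and passing edges at a node
#'
#' Relative to the sweep direction, the node's edges split into the
#' item-carrying side, the bin side, and `I_m`, the edges that pass over
#' the node and whose items stay unchanged.  Moving left the items sit in
#' the node's out-edges (`I_out`) and the bins are its in-edges (`I_in`);
#' moving right the roles mirror.
#'
#' @param state a packing state.
#' @param node interior node id.
#' @param direction `"left"` or `"right"`.
#' @return list with `I_in`, `I_out`, `I_m`, `item_side`, `bin_side`,
#'   `item_gap`, `bin_gap`.
#' @export
partition_at <- function(state, node, direction = c("left", "right")) {
  direction <- match.arg(direction)
  if (node %in% c("s", "t")) stop("sentinels are never processed")
  g <- state$graph
  r <- state$order[[node]]
  I_in <- in_edges(g, node)
  I_out <- out_edges(g, node)
  item_gap <- if (direction == "left") r else r - 1L
  bin_gap  <- if (direction == "left") r - 1L else r
  cross_item <- crossing_edges(g, state$order, item_gap)$crossing_edges
  cross_bin  <- crossing_edges(g, state$order, bin_gap)$crossing_edges
  I_m <- intersect(cross_item, cross_bin)
  list(I_in = I_in, I_out = I_out, I_m = I_m,
       item_side = if (direction == "left") I_out else I_in,
       bin_side  = if (direction == "left") I_in else I_out,
       item_gap = item_gap, bin_gap = bin_gap)
}

#' Trap test
#'
#' A node is a trap when the item-carrying side has strictly fewer edges
#' than the bin side (moving left: `|I_out| < |I_in|`; mirrored moving
#' right), so the items cannot cover every bin and must be replaced.
#'
#' @param partition result of [partition_at()].
#' @param direction `"left"` or `"right"`.
#' @return logical scalar.
#' @export
is_trap <- function(partition, direction = c("left", "right")) {
  direction <- match.arg(direction)
  length(partition$item_side) < length(partition$bin_side)
}

trace_row <- function(state, node, direction, part, objective, trap) {
  if (is.null(state$trace)) return(invisible())
  state$trace[[length(state$trace) + 1L]] <- data.frame(
    node = node, direction = direction,
    n_in = length(part$I_in), n_out = length(part$I_out), n_m = length(part$I_m),
    objective = objective, trap = trap, stringsAsFactors = FALSE)
  invisible()
}

## Reduce per-bin lower bounds until their sum fits the item count,
## trimming the largest bounds first but never below 1.
clamp_min_counts <- function(min_counts, n_items) {
  while (sum(min_counts) > n_items) {
    i <- which.max(min_counts)
    if (min_counts[i] <= 1L) stop("cannot satisfy per-bin lower bounds with ",
                                  n_items, " items")
    min_counts[i] <- min_counts[i] - 1L
  }
  min_counts
}

#' Process one non-trap node
#'
#' Builds the node-local instance (bins = the bin-side edges with their
#' weights as capacities; items = those carried by the item-side edges),
#' solves it exactly, and extends each moved item's trajectory by its
#' assigned bin; items on passing edges extend with the same edge.  When
#' the bin-side gap was assigned before (re-crossing a processed node) the
#' previous per-bin occupancies become lower bounds.
#'
#' @param state a packing state.
#' @param node interior node id.
#' @param direction `"left"` or `"right"`.
#' @return the state, invisibly.
#' @export
step_node <- function(state, node, direction = c("left", "right")) {
  direction <- match.arg(direction)
  part <- partition_at(state, node, direction)
  movers <- items_at(state, part$item_gap, part$item_side)
  bins <- part$bin_side
  kb <- as.character(part$bin_gap)
  revisit <- !is.na(state$gap_lo) &&
    part$bin_gap >= state$gap_lo && part$bin_gap <= state$gap_hi
  min_counts <- if (revisit) occupancy_at(state, part$bin_gap, bins)
                else rep(1L, length(bins))
  if (length(movers) < length(bins) && !revisit)
    stop("step_node called on a trap node: ", node)
  min_counts <- clamp_min_counts(pmax(min_counts, 0L), length(movers))
  if (all(min_counts == 0L)) min_counts <- pmax(min_counts, 1L)
  sizes <- vapply(movers, function(it) it$size, numeric(1))
  inst <- packing_instance(edge_weight(state$graph, bins), sizes, min_counts)
  sol <- solve_packing(inst)
  for (jj in seq_along(movers)) {
    id <- movers[[jj]]$id
    state$items[[id]]$traj[kb] <- bins[[sol$assignment[jj]]]
  }
  for (it in items_at(state, part$item_gap, part$I_m)) {
    state$items[[it$id]]$traj[kb] <- it$traj[[as.character(part$item_gap)]]
  }
  state$gap_lo <- min(state$gap_lo, part$bin_gap)
  state$gap_hi <- max(state$gap_hi, part$bin_gap)
  state$processed <- union(state$processed, node)
  trace_row(state, node, direction, part, sol$objective, FALSE)
  invisible(state)
}

#' Replace items at a trap node
#'
#' The items carried by the item-side edges are retired; one new item per
#' bin-side edge is created, sized by that edge's weight.  The new items
#' are then packed back into the item-side edges, each of which must
#' receive at least as many items as it held before (occupancy lower
#' bounds), and each new item inherits the already-processed trajectory
#' segment of one retired item from the edge it is packed into.  The sweep
#' then reverses from the trap node.
#'
#' @inheritParams step_node
#' @return the state, invisibly.
#' @export
handle_trap <- function(state, node, direction = c("left", "right")) {
  direction <- match.arg(direction)
  part <- partition_at(state, node, direction)
  if (!is_trap(part, direction)) stop("handle_trap called on a non-trap node: ", node)
  g <- state$graph
  old <- items_at(state, part$item_gap, part$item_side)
  old <- old[order(vapply(old, function(it) it$id, ""))]
  occ <- occupancy_at(state, part$item_gap, part$item_side)
  m <- length(part$bin_side)
  min_counts <- clamp_min_counts(pmax(occ, 1L), m)
  ## new items, one per bin-side edge, sized by its weight
  new_ids <- character(m)
  kb <- as.character(part$bin_gap); ki <- as.character(part$item_gap)
  for (ii in seq_len(m)) {
    e <- part$bin_side[[ii]]
    id <- sprintf("i%03d", state$next_item)
    state$next_item <- state$next_item + 1L
    new_ids[[ii]] <- id
    state$items[[id]] <- list(id = id, size = edge_weight(g, e),
                              origin = list(iteration = state$reversals + 1L, edge = e),
                              traj = stats::setNames(e, kb))
  }
  inst <- formulate_eq2(edge_weight(g, part$item_side),
                        vapply(new_ids, function(id) state$items[[id]]$size, numeric(1)),
                        min_counts)
  sol <- solve_packing(inst)
  ## assign each new item its item-side edge and inherit the processed-side
  ## trajectory segment of a retired item (donor) from that edge
  retired <- character()
  orphans <- character()
  for (ei in seq_along(part$item_side)) {
    e <- part$item_side[[ei]]
    N_e <- new_ids[sol$assignment == ei]
    O_e <- Filter(function(it) identical(unname(it$traj[ki]), e), old)
    for (ii in seq_along(N_e)) {
      id <- N_e[[ii]]
      state$items[[id]]$traj[ki] <- e
      if (length(O_e)) {
        d <- O_e[[((ii - 1L) %% length(O_e)) + 1L]]
        seg <- d$traj[setdiff(names(d$traj), c(ki, kb))]
        if (length(seg)) state$items[[id]]$traj[names(seg)] <- seg
      }
    }
    retired <- c(retired, vapply(O_e[seq_len(min(length(N_e), length(O_e)))],
                                 function(it) it$id, ""))
    if (length(O_e) > length(N_e))
      orphans <- c(orphans, vapply(O_e[(length(N_e) + 1L):length(O_e)],
                                   function(it) it$id, ""))
  }
  ## more items were trapped than new ones created: the surplus items keep
  ## their downstream paths (dropping them would orphan the edges only they
  ## cover) and pass through the node into the already-full source-side
  ## bins (zero residual capacity)
  if (length(orphans)) {
    osz <- vapply(orphans, function(id) state$items[[id]]$size, numeric(1))
    osol <- solve_packing(packing_instance(rep(0, m), osz, rep(0L, m)))
    for (ii in seq_along(orphans)) {
      state$items[[orphans[ii]]]$traj[kb] <- part$bin_side[[osol$assignment[ii]]]
    }
  }
  ## passing items extend over the node; retire the replaced items
  for (it in items_at(state, part$item_gap, part$I_m)) {
    state$items[[it$id]]$traj[kb] <- it$traj[[ki]]
  }
  for (id in retired) state$items[[id]] <- NULL
  state$gap_lo <- min(state$gap_lo, part$bin_gap)
  state$gap_hi <- max(state$gap_hi, part$bin_gap)
  state$processed <- union(state$processed, node)
  trace_row(state, node, direction, part, sol$objective, TRUE)
  invisible(state)
}

#' Run the packing engine on a balanced graph
#'
#' Seeds items on the maximal incompatible cut and sweeps forth and back
#' until every interior node is processed, bounding the number of
#' direction changes by `|V|` (exceeding the bound signals an
#' implementation bug and raises an error).
#'
#' @param graph a balanced `splicing_graph` with sentinels `s` and `t`.
#' @param trace keep a per-node-visit debug trace (`attr(, "trace")`)?
#' @return list with `items` (live items, each with a complete trajectory),
#'   `state`, and `events` (the sweep/trap/jump log used to verify the
#'   iteration pattern).
#' @export
run_packing <- function(graph, trace = FALSE) {
  if (!is_augmented(graph)) stop("run_packing requires a balanced graph with s and t")
  order <- topological_order(graph)
  cut <- max_incompatible_set(graph, order)
  state <- init_items(graph, cut, order, trace)
  nV <- length(graph$nodes)
  interior <- setdiff(graph$nodes, c("s", "t"))
  direction <- "left"
  cursor <- cut$gap_index                 # rank of the node to process next
  iter_start <- cursor
  log_event <- function(type, ...) {
    state$events[[length(state$events) + 1L]] <- c(list(type = type), list(...))
  }
  log_event("sweep", direction = direction, start = node_at_rank(state, cursor))
  repeat {
    node <- node_at_rank(state, cursor)
    if (node %in% c("s", "t")) {
      if (all(interior %in% state$processed)) break
      ## terminal reached with work left: jump back to the sweep's start
      direction <- other_direction(direction)
      state$reversals <- state$reversals + 1L
      if (state$reversals > nV)
        stop("direction reversals exceeded |V|: packing failed to terminate")
      log_event("jump", direction = direction,
                start = node_at_rank(state, iter_start))
      cursor <- iter_start + if (direction == "left") -1L else 1L
      next
    }
    if (node %in% state$processed) {
      step_node(state, node, direction)
      cursor <- cursor + if (direction == "left") -1L else 1L
      next
    }
    part <- partition_at(state, node, direction)
    if (is_trap(part, direction)) {
      handle_trap(state, node, direction)
      direction <- other_direction(direction)
      state$reversals <- state$reversals + 1L
      if (state$reversals > nV)
        stop("direction reversals exceeded |V|: packing failed to terminate")
      iter_start <- cursor
      log_event("trap", node = node, direction = direction)
      cursor <- cursor + if (direction == "left") -1L else 1L
    } else {
      step_node(state, node, direction)
      cursor <- cursor + if (direction == "left") -1L else 1L
    }
  }
  ## every live item must now span every gap
  gaps <- as.character(0:(nV - 2L))
  for (it in state$items) {
    if (!all(gaps %in% names(it$traj)))
      stop("incomplete trajectory for item ", it$id)
  }
  items <- state$items[order(names(state$items))]
  items <- lapply(items, function(it) {
    it$traj <- it$traj[as.character(sort(as.integer(names(it$traj))))]
    it
  })
  res <- list(items = items, state = state, events = state$events)
  if (trace) attr(res, "trace") <- do.call(rbind, state$trace)
  res
}

#' Direction sequence of a packing run
#'
#' Convenience accessor: the sweep directions in order, with `"(jump)"`
#' marking terminal jump-backs, e.g. `c("left","right","left","(jump)","right")`.
#'
#' @param run result of [run_packing()].
#' @return character vector.
#' @export
direction_sequence <- function(run) {
  out <- character()
  for (ev in run$events) {
    if (ev$type == "sweep") out <- c(out, ev$direction)
    else if (ev$type == "trap") out <- c(out, ev$direction)
    else if (ev$type == "jump") out <- c(out, "(jump)", ev$direction)
  }
  out
}
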