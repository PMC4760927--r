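balanced_chain <- function(weights = c(7, 7, 7)) {
  balance_graph(add_source_sink(chain_graph(weights)))
}

test_that("items are seeded one per cut edge with the edge weights", {
  dm <- balance_graph(add_source_sink(diamond_graph(wb = 30, wc = 10)))
  ord <- topological_order(dm)
  cut <- max_incompatible_set(dm, ord)
  st <- init_items(dm, cut, ord)
  sizes <- sort(vapply(st$items, function(it) it$size, numeric(1)))
  expect_equal(length(st$items), length(cut$crossing_edges))
  expect_equal(unname(sizes), c(10, 30))
  expect_error(init_items(dm, list(gap_index = 0L, crossing_edges = character())),
               "empty cut")

  ## item count equals cut cardinality on random fixtures
  for (s in 1:10) {
    bg <- random_balanced_graph(sample(3:8, 1), s + 60)
    ord <- topological_order(bg)
    cut <- max_incompatible_set(bg, ord)
    expect_equal(length(init_items(bg, cut, ord)$items),
                 length(cut$crossing_edges))
  }
})

test_that("edge partitions are disjoint and cover both cuts", {
  ch <- balanced_chain()
  ord <- topological_order(ch)
  st <- init_items(ch, max_incompatible_set(ch, ord), ord)
  part <- partition_at(st, "2", "left")
  expect_equal(length(part$I_in), 1L)
  expect_equal(length(part$I_out), 1L)
  expect_equal(length(part$I_m), 0L)

  for (s in 1:10) {
    bg <- random_balanced_graph(sample(4:8, 1), s + 70)
    ord <- topological_order(bg)
    st <- init_items(bg, max_incompatible_set(bg, ord), ord)
    interior <- setdiff(bg$nodes, c("s", "t"))
    for (node in interior) for (dir in c("left", "right")) {
      r <- ord[[node]]
      if (dir == "left" && r < 1L) next
      if (dir == "right" && r > length(bg$nodes) - 2L) next
      part <- partition_at(st, node, dir)
      expect_equal(length(intersect(part$I_in, part$I_out)), 0L)
      expect_equal(length(intersect(part$I_m, c(part$I_in, part$I_out))), 0L)
      both <- union(crossing_edges(bg, ord, part$item_gap)$crossing_edges,
                    crossing_edges(bg, ord, part$bin_gap)$crossing_edges)
      expect_setequal(c(part$I_in, part$I_out, part$I_m), both)
    }
  }
  expect_error(partition_at(st, "s", "left"), "sentinel")
})

test_that("the trap test compares item-side and bin-side cardinalities", {
  p_left <- list(item_side = c("e1", "e2"), bin_side = "e3")
  expect_false(is_trap(p_left, "left"))
  p_trap <- list(item_side = "e1", bin_side = c("e2", "e3"))
  expect_true(is_trap(p_trap, "left"))
  ## chain nodes are never traps (1 vs 1)
  ch <- balanced_chain()
  ord <- topological_order(ch)
  st <- init_items(ch, max_incompatible_set(ch, ord), ord)
  for (node in setdiff(ch$nodes, c("s", "t"))[-1L]) {
    expect_false(is_trap(partition_at(st, node, "left"), "left"))
  }
})

test_that("step_node packs optimally and keeps every bin occupied", {
  ## forced single upstream bin: both items land there with objective 0
  g <- splicing_graph(c("a", "u", "v", "w"),
                      data.frame(u = c("a", "u", "u"), v = c("u", "v", "w"),
                                 weight = c(40, 10, 30)))
  bg <- balance_graph(add_source_sink(g))
  run <- run_packing(bg, trace = TRUE)
  tr <- attr(run, "trace")
  expect_equal(tr$objective[tr$node == "u"][1], 0)

  ## items {10, 30} into bins {12, 29}: objective 5 matches the oracle
  g2 <- splicing_graph(c("a", "b", "u", "v", "w"),
                       data.frame(u = c("a", "b", "u", "u"),
                                  v = c("u", "u", "v", "w"),
                                  weight = c(12, 29, 10, 30)))
  bg2 <- balance_graph(add_source_sink(g2))
  run2 <- run_packing(bg2, trace = TRUE)
  tr2 <- attr(run2, "trace")
  expect_equal(tr2$objective[tr2$node == "u"][1],
               brute_force_pack(packing_instance(c(12, 29), c(10, 30)))$objective)

  ## after every step, each bin at the new cut holds >= 1 item
  for (s in 1:10) {
    bg <- random_balanced_graph(sample(3:8, 1), s + 80)
    run <- run_packing(bg)
    ord <- topological_order(bg)
    for (p in 0:(length(bg$nodes) - 2L)) {
      occ <- table(vapply(run$items, function(it) it$traj[[as.character(p)]],
                          character(1)))
      cutp <- crossing_edges(bg, ord, p)$crossing_edges
      expect_true(all(cutp %in% names(occ)), info = paste("seed", s, "gap", p))
    }
  }
})

test_that("trap replacement sizes new items by the bin-side weights", {
  ## u has in-edges {10, 30} and a single out-edge 35: moving left the one
  ## item is replaced by two items sized 10 and 30, both re-packed into the
  ## out-edge (objective (35 - 40)^2 = 25)
  g <- splicing_graph(c("a", "b", "u", "v"),
                      data.frame(u = c("a", "b", "u"), v = c("u", "u", "v"),
                                 weight = c(10, 30, 35)))
  ord <- topological_order(g)
  st <- init_items(g, crossing_edges(g, ord, 2L), ord, trace = TRUE)
  part <- partition_at(st, "u", "left")
  expect_true(is_trap(part, "left"))
  handle_trap(st, "u", "left")
  sizes <- sort(vapply(st$items, function(it) it$size, numeric(1)))
  expect_equal(unname(sizes), c(10, 30))
  expect_equal(length(st$items), 2L)
  tr <- do.call(rbind, st$trace)
  expect_equal(tr$objective[tr$node == "u"], 25)
  expect_true(tr$trap[tr$node == "u"])
  ## both new items sit in the single out-edge
  at_out <- vapply(st$items, function(it) it$traj[["2"]], character(1))
  expect_true(all(at_out == "u->v"))

  ## chains never invoke the trap path
  run <- run_packing(balanced_chain(), trace = TRUE)
  expect_false(any(attr(run, "trace")$trap))
})

test_that("run decomposes chains and diamonds into the expected paths", {
  run <- run_packing(balanced_chain(c(7, 7)))
  expect_equal(length(run$items), 1L)
  it <- run$items[[1L]]
  expect_equal(length(unique(it$traj)), 4L)   # s->1, 1->2, 2->3, 3->t

  dm <- balance_graph(add_source_sink(diamond_graph(wb = 30, wc = 10)))
  run <- run_packing(dm)
  expect_equal(length(run$items), 2L)
  paths <- lapply(run$items, function(it) trajectory_to_path(dm, it))
  sizes <- vapply(run$items, function(it) it$size, numeric(1))
  expect_equal(unname(paths[[which(sizes == 10)]]), c("a", "c", "d"))
  expect_equal(unname(paths[[which(sizes == 30)]]), c("a", "b", "d"))
})

test_that("the worked trap example reproduces the forth-and-back pattern", {
  g <- example_trap_graph()
  ord <- topological_order(g)
  expect_equal(max_incompatible_set(g, ord)$gap_index, 4L)  # starts at node 4
  run <- run_packing(g)
  expect_equal(direction_sequence(run),
               c("left", "right", "left", "(jump)", "right"))
  traps <- vapply(Filter(function(e) e$type == "trap", run$events),
                  function(e) e$node, "")
  expect_equal(traps, c("2", "6"))
  covered <- unique(unlist(lapply(run$items, function(it) it$traj)))
  expect_setequal(covered, edge_key(g$edges$u, g$edges$v))
})

test_that("termination, path validity and item conservation hold on random graphs", {
  for (s in 1:40) {
    bg <- random_balanced_graph(3 + (s %% 13), s)
    run <- run_packing(bg, trace = TRUE)
    expect_lte(run$state$reversals, length(bg$nodes))
    for (it in run$items) expect_no_error(trajectory_to_path(bg, it))
    ## live item count is constant across trap-free stretches
    tr <- attr(run, "trace")
    if (!any(tr$trap)) {
      expect_equal(length(run$items),
                   length(max_incompatible_set(bg, topological_order(bg))$crossing_edges))
    }
  }
})
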