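test_that("break_cycles leaves DAGs alone and removes minimum-weight back-edges", {
  ch <- chain_graph(c(5, 3))
  expect_identical(break_cycles(ch)$edges, ch$edges)
  expect_equal(attr(break_cycles(ch), "removed_edges"), 0L)

  two <- splicing_graph(c("a", "b"),
                        data.frame(u = c("a", "b"), v = c("b", "a"),
                                   weight = c(10, 1)))
  fixed <- break_cycles(two)
  expect_equal(nrow(fixed$edges), 1L)
  expect_equal(fixed$edges$u, "a")
  expect_equal(attr(fixed, "removed_edges"), 1L)

  ## random graphs with planted cycles always come out acyclic
  for (s in 1:20) {
    g <- random_dag(8L, s)
    back <- g$edges[sample(nrow(g$edges), min(3L, nrow(g$edges))), ]
    gc <- splicing_graph(g$nodes,
                         rbind(g$edges,
                               data.frame(u = back$v, v = back$u,
                                          weight = back$weight + 0.5)))
    out <- break_cycles(gc)
    expect_no_error(topological_order(out))
  }
})

test_that("topological order is canonical and deterministic", {
  g <- splicing_graph(c("1", "2", "3"),
                      data.frame(u = c("1", "1", "2"), v = c("2", "3", "3"),
                                 weight = c(1, 1, 1)))
  expect_equal(topological_order(g), c("1" = 0L, "2" = 1L, "3" = 2L))
  expect_equal(topological_order(splicing_graph("7")), c("7" = 0L))

  ## every edge points left -> right on random DAGs; ranks are contiguous
  for (s in 1:25) {
    g <- random_dag(sample(3:10, 1), s)
    ord <- topological_order(g)
    expect_setequal(unname(ord), seq_along(g$nodes) - 1L)
    expect_true(all(ord[g$edges$u] < ord[g$edges$v]))
    expect_identical(ord, topological_order(g))
  }

  cyc <- splicing_graph(c("a", "b"),
                        data.frame(u = c("a", "b"), v = c("b", "a"),
                                   weight = c(1, 1)))
  expect_error(topological_order(cyc), "cycle")
})

test_that("edge compatibility means co-occurrence on one directed path", {
  ch <- chain_graph(c(1, 1))   # 1 -> 2 -> 3
  expect_true(are_compatible(ch, "1->2", "2->3"))
  expect_true(are_compatible(ch, "1->2", "1->2"))

  fork <- splicing_graph(c("a", "b", "c"),
                         data.frame(u = c("a", "a"), v = c("b", "c"),
                                    weight = c(1, 1)))
  expect_false(are_compatible(fork, "a->b", "a->c"))
  expect_error(are_compatible(fork, "a->b", "b->c"), "unknown edge")

  ## diamond: (a,b) vs (c,d) can never be on one path -- verified against
  ## exhaustive path enumeration
  dm <- diamond_graph()
  paths <- all_paths(dm)
  on_one_path <- function(e1, e2) {
    any(vapply(paths, function(p) {
      keys <- edge_key(p[-length(p)], p[-1L])
      e1 %in% keys && e2 %in% keys
    }, logical(1)))
  }
  expect_false(are_compatible(dm, "a->b", "c->d"))
  expect_false(on_one_path("a->b", "c->d"))
  keys <- edge_key(dm$edges$u, dm$edges$v)
  for (e1 in keys) for (e2 in keys) {
    expect_equal(are_compatible(dm, e1, e2), on_one_path(e1, e2),
                 info = paste(e1, e2))
  }
})

test_that("crossing edges follow the gap definition and are pairwise incompatible", {
  ch <- chain_graph(c(1, 1))
  expect_equal(crossing_edges(ch, topological_order(ch), 0)$crossing_edges, "1->2")
  expect_error(crossing_edges(ch, topological_order(ch), 2), "out of range")

  dm <- diamond_graph()
  ord <- topological_order(dm)   # a b c d
  expect_setequal(crossing_edges(dm, ord, 1)$crossing_edges, c("a->c", "b->d"))

  for (s in 1:15) {
    g <- random_dag(sample(3:8, 1), s + 100)
    ord <- topological_order(g)
    for (p in 0:(length(g$nodes) - 2L)) {
      cut <- crossing_edges(g, ord, p)$crossing_edges
      if (length(cut) < 2L) next
      for (i in seq_along(cut)[-1L]) for (j in 1:(i - 1L)) {
        expect_false(are_compatible(g, cut[[i]], cut[[j]]))
      }
    }
  }
})

test_that("the maximum cut is a maximal pairwise-incompatible set", {
  ch <- chain_graph(c(1, 1, 1))
  mis <- max_incompatible_set(ch, topological_order(ch))
  expect_equal(mis$gap_index, 0L)  # all cuts size 1; leftmost wins
  expect_equal(length(mis$crossing_edges), 1L)

  dm <- diamond_graph()
  mis <- max_incompatible_set(dm, topological_order(dm))
  expect_equal(length(mis$crossing_edges), 2L)
  expect_equal(mis$gap_index, 0L)

  expect_error(max_incompatible_set(splicing_graph("x"), c(x = 0L)),
               "nothing to pack")

  ## maximality on balanced graphs: no edge outside the cut is
  ## incompatible with every cut edge
  for (s in 1:30) {
    bg <- random_balanced_graph(sample(3:7, 1), s)
    ord <- topological_order(bg)
    mis <- max_incompatible_set(bg, ord)
    others <- setdiff(edge_key(bg$edges$u, bg$edges$v), mis$crossing_edges)
    for (e in others) {
      expect_true(any(vapply(mis$crossing_edges,
                             function(f) are_compatible(bg, e, f), logical(1))),
                  info = paste("seed", s, "edge", e))
    }
    expect_identical(mis, max_incompatible_set(bg, ord))
  }
})

test_that("graph text format and GFA export round-trip", {
  dm <- diamond_graph()
  dm$node_seq <- stats::setNames(c("ACGT", "CGTA", "GTAC", "TACG"), dm$nodes)
  dm$node_cov <- stats::setNames(c(10, 20, 30, 40), dm$nodes)
  tf <- tempfile(fileext = ".txt")
  write_splicing_graphs(list(d1 = dm, d2 = chain_graph(7)), tf)
  back <- read_splicing_graphs(tf)
  expect_named(back, c("d1", "d2"))
  expect_equal(back$d1$edges, dm$edges)
  expect_equal(back$d1$node_seq, dm$node_seq)
  expect_equal(back$d1$node_cov, dm$node_cov)
  expect_equal(back$d2$edges$weight, 7)

  gfa <- tempfile(fileext = ".gfa")
  write_gfa(dm, gfa)
  lines <- readLines(gfa)
  expect_equal(sum(startsWith(lines, "S")), 4L)
  expect_equal(sum(startsWith(lines, "L")), 4L)
  expect_true(all(grepl("RC:i:", lines[startsWith(lines, "L")])))
})
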