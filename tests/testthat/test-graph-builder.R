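cfg4 <- build_config(k = 15L, min_kmer_count = 1L, min_junction_reads = 1L)

test_that("k-mer counting windows every retained read", {
  cfg <- build_config(k = 4L, min_kmer_count = 1L)
  kg <- count_kmers("ACGTA", cfg)
  expect_equal(kg$counts, c(ACGT = 1L, CGTA = 1L))
  kg2 <- count_kmers(c("ACGTA", "ACGTA"), cfg)
  expect_equal(unname(kg2$counts), unname(kg$counts * 2L))

  ## error-free reads tiling a sequence: distinct k-mers = L - k + 1 and
  ## total multiplicity equals the total number of windows
  sq <- random_seq(500L, 11)
  reads <- tile_reads(sq, 60L)
  kg3 <- count_kmers(reads, build_config(k = 25L, min_kmer_count = 1L))
  expect_equal(length(kg3$counts), 500L - 25L + 1L)
  expect_equal(sum(kg3$counts), sum(nchar(reads) - 25L + 1L))

  ## short reads are skipped with a logged count
  kg4 <- count_kmers(c("ACGTA", "ACG"), cfg)
  expect_equal(kg4$skipped_reads, 1L)
  expect_equal(sum(kg4$counts), 2L)

  ## unstranded mode merges canonical forms
  kg5 <- count_kmers(c("ACGT", "ACGT"), build_config(k = 4L, stranded = FALSE))
  expect_equal(kg5$counts, c(ACGT = 2L))   # ACGT is its own reverse complement
  expect_error(count_kmers(character(), cfg), "no reads")
  expect_error(count_kmers("ACGTACGTACGTAC", build_config(k = 25L)), "longest read")
})

test_that("linear chains collapse to single nodes; branches become edges", {
  sq <- random_seq(200L, 12)
  g <- collapse_linear_paths(count_kmers(tile_reads(sq, 40L), cfg4), cfg4)
  expect_equal(length(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_equal(unname(g$node_seq[[1L]]), sq)

  ## a skipped-exon locus forms a bubble whose maximal incompatible cut
  ## has cardinality 2
  set.seed(13)
  ex <- vapply(c(150L, 90L, 150L), rand_dna, character(1))
  iso1 <- paste0(ex[1], ex[2], ex[3]); iso2 <- paste0(ex[1], ex[3])
  reads <- c(tile_reads(iso1, 40L), tile_reads(iso2, 40L))
  g2 <- collapse_linear_paths(count_kmers(reads, cfg4), cfg4)
  expect_gte(length(g2$nodes), 3L)
  expect_gte(nrow(g2$edges), 3L)
  g2 <- weight_junctions(g2, reads, cfg4)
  ord <- topological_order(g2)
  expect_equal(length(max_incompatible_set(g2, ord)$crossing_edges), 2L)

  ## collapsing is a fixed point at the splicing-graph level
  g3 <- sgpack:::simplify_graph(g2)
  expect_equal(length(g3$nodes), length(g2$nodes))
})

test_that("junction weights count spanning reads exactly", {
  ## thirty identical reads across one junction of a bubble
  set.seed(14)
  ex <- vapply(c(80L, 60L, 80L), rand_dna, character(1))
  iso1 <- paste0(ex[1], ex[2], ex[3]); iso2 <- paste0(ex[1], ex[3])
  reads <- c(rep(tile_reads(iso1, 40L), 2L), tile_reads(iso2, 40L))
  g <- collapse_linear_paths(count_kmers(reads, cfg4), cfg4)
  gw <- weight_junctions(g, reads, cfg4)
  ## oracle: brute-force substring search for each junction window
  k <- gw$k
  for (i in seq_len(nrow(gw$edges))) {
    us <- gw$node_seq[[gw$edges$u[i]]]; vs <- gw$node_seq[[gw$edges$v[i]]]
    win <- paste0(substring(us, nchar(us) - k + 1L), substring(vs, k, k))
    expect_equal(gw$edges$weight[i],
                 sum(vapply(reads, function(r) grepl(win, r, fixed = TRUE),
                            logical(1))))
  }
  ## a read set not touching any junction leaves no weight behind
  far <- tile_reads(substring(ex[1], 1L, 60L), 30L)
  g0 <- weight_junctions(g, far, cfg4)
  expect_equal(nrow(g0$edges), 0L)
  expect_gte(attr(g0, "dropped_edges"), 1L)
})

test_that("isoform coverage ratios survive junction weighting", {
  ## two isoforms at 10x and 50x equivalent read multiplicity: the skip
  ## edge weight is about one fifth of the inclusion weights
  set.seed(15)
  ex <- vapply(c(120L, 80L, 120L), rand_dna, character(1))
  iso1 <- paste0(ex[1], ex[2], ex[3]); iso2 <- paste0(ex[1], ex[3])
  reads <- c(rep(tile_reads(iso1, 50L, step = 1L), 5L), tile_reads(iso2, 50L))
  g <- weight_junctions(collapse_linear_paths(count_kmers(reads, cfg4), cfg4),
                        reads, cfg4)
  stopifnot(nrow(g$edges) == 4L)
  ord <- topological_order(g)
  cut <- max_incompatible_set(g, ord)$crossing_edges
  w <- sort(edge_weight(g, cut))
  expect_equal(unname(w[2] / w[1]), 5, tolerance = 0.1)
})

test_that("trimming removes weak spurs and splits loci", {
  ## hand-built: strong linear path with a weak short spur
  g <- splicing_graph(c("p1", "p2", "spur"),
                      data.frame(u = c("p1", "p2"), v = c("p2", "spur"),
                                 weight = c(50, 1)),
                      node_seq = c(p1 = strrep("A", 40), p2 = strrep("C", 40),
                                   spur = strrep("G", 18)),
                      node_cov = c(p1 = 50, p2 = 50, spur = 1), k = 15L)
  comps <- trim_and_split(g, build_config(k = 15L, min_kmer_count = 2L,
                                          min_junction_reads = 3L))
  expect_equal(length(comps), 1L)
  expect_equal(length(comps[[1L]]$nodes), 1L)
  expect_equal(nrow(comps[[1L]]$edges), 0L)

  ## two loci with no shared k-mers give exactly two components
  sq1 <- random_seq(300L, 21); sq2 <- random_seq(300L, 22)
  reads <- c(tile_reads(sq1, 40L), tile_reads(sq2, 40L))
  comps2 <- trim_and_split(
    weight_junctions(collapse_linear_paths(count_kmers(reads, cfg4), cfg4),
                     reads, cfg4), cfg4)
  expect_equal(length(comps2), 2L)
  expect_setequal(vapply(comps2, function(g) unname(g$node_seq[[1L]]), ""),
                  c(sq1, sq2))

  ## a clean single-isoform graph is a fixed point
  g1 <- comps2[[1L]]
  expect_equal(trim_and_split(g1, cfg4)[[1L]]$node_seq, g1$node_seq)
})

test_that("end-to-end: error-free reads reproduce single- and two-isoform loci", {
  sq <- random_seq(400L, 31)
  comps <- build_splicing_graphs(tile_reads(sq, 60L),
                                 build_config(min_kmer_count = 1L,
                                              min_junction_reads = 1L))
  expect_equal(length(comps), 1L)
  expect_equal(length(comps[[1L]]$nodes), 1L)
  expect_equal(unname(comps[[1L]]$node_seq[[1L]]), sq)

  set.seed(33)
  ex <- vapply(c(200L, 120L, 200L), rand_dna, character(1))
  iso1 <- paste0(ex[1], ex[2], ex[3]); iso2 <- paste0(ex[1], ex[3])
  reads <- c(rep(tile_reads(iso1, 75L, step = 2L), 5L),
             tile_reads(iso2, 75L, step = 2L))
  comps2 <- build_splicing_graphs(reads, build_config(min_kmer_count = 1L,
                                                      min_junction_reads = 1L))
  expect_equal(length(comps2), 1L)
  g <- comps2[[1L]]
  expect_true(all(g$edges$weight > 0))
  cut <- max_incompatible_set(g, topological_order(g))
  expect_equal(length(cut$crossing_edges), 2L)
})

test_that("unstranded mode canonicalizes and recovers one orientation", {
  sq <- random_seq(300L, 44)
  reads <- tile_reads(sq, 60L)
  flip <- seq_along(reads) %% 2L == 0L
  reads[flip] <- sgpack:::revcomp(reads[flip])
  comps <- build_splicing_graphs(reads,
                                 build_config(min_kmer_count = 1L,
                                              min_junction_reads = 1L,
                                              stranded = FALSE))
  expect_equal(length(comps), 1L)
  got <- unname(comps[[1L]]$node_seq[[1L]])
  expect_true(got == sq || got == sgpack:::revcomp(sq))
})
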