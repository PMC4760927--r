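---
title: "Transcript assembly by bin packing on weighted splicing graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript assembly by bin packing on weighted splicing graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgpack)
```

## The problem

A gene with alternative splicing expresses several isoforms that share most
of their sequence. Short RNA-seq reads observe fragments of all of them at
once, and de novo assembly must reconstruct the full-length isoforms --
and ideally their relative abundances -- without a reference genome. The
natural data structure is the *splicing graph*: a weighted DAG whose nodes
are maximal unspliced sequence segments ("generalized exons") and whose
edges are observed splice junctions, each weighted by its sequencing depth
(the number of reads spanning the junction). Every isoform of the gene is
an s-t path in this graph, so assembly reduces to decomposing the graph
into a small set of weighted paths that together use every edge -- an
*edge-path cover* that explains every observed splicing event.

`sgpack` performs this decomposition by an iterative bin-packing
procedure. Items -- tokens whose sizes approximate per-isoform coverage --
are pushed through the graph node by node; at each node the items carried
by the edges on one side must be packed into the edges (bins) on the other
side so that each bin's load matches its capacity (the edge weight) as
closely as possible in squared error. The node-local subproblems are tiny
0-1 quadratic programs, solved exactly after linearization to 0-1 integer
programs.

## Pipeline

1. **Graph construction** (`build_splicing_graphs()`): k-mer counting
   (default `k = 25`), a noise floor on k-mer multiplicities, collapse of
   unbranched k-mer chains into nodes, junction weighting, trimming of
   weak tips and junctions, and splitting into weakly connected
   components, each treated as one expressed gene.
2. **Balancing** (`add_source_sink()`, `balance_graph()`): a source `s`
   and sink `t` are attached, and interior nodes whose in- and out-weights
   differ beyond a threshold are marked as transcript ends by extra
   `s->u` / `u->t` edges.
3. **Packing** (`run_packing()`): items are seeded on the maximal set of
   pairwise incompatible edges and swept forth and back; trap nodes
   replace items and reverse the sweep until every node is processed.
4. **Transcript recovery** (`assemble_component()`): each surviving item's
   bin sequence induces one s-t path, which is spelled into a nucleotide
   sequence; the item size is reported as the transcript's abundance.

## The node-local model

At a node, with bins `i = 1..m` of capacities `c_i` and items `j = 1..n`
of sizes `w_j`, the regular step solves

```
min  sum_i (c_i - sum_j w_j x_ij)^2
s.t. sum_i x_ij  = 1   for every item j
     sum_j x_ij >= 1   for every bin i,   x_ij in {0,1}
```

so each item lands in exactly one bin and no bin is left empty. At a
*trap node* -- where the item-carrying side has fewer edges than the
receiving side -- the local items are replaced by one new item per
receiving edge (sized by that edge's weight) and the re-pack uses per-bin
lower bounds `n_i`, the occupancy each bin held before the reversal, so
established structure is never contradicted.

Each squared term is linearized by a product variable `x_ijik` per
quadratic monomial with the linking constraints `x_ijik <= x_ij`,
`x_ijik <= x_ik`, `x_ij + x_ik - 1 <= x_ijik`, giving
`m*n*(n+3)/2` binary variables. Because every product variable has a
positive objective coefficient, any optimal solution pins it to the actual
product, so the linear and quadratic optima coincide; the test suite
verifies this equivalence against an independent exhaustive oracle
(`brute_force_pack()`) on hundreds of random instances. Instances at real
nodes are tiny (usually `m, n < 3`), so the exact solver enumerates the
assignment space directly, with closed-form shortcuts for `m = 1` and
`n = 1`; ties between equal-objective optima are broken by the
lexicographically smallest flattened assignment matrix, which makes every
stage of the pipeline deterministic.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 25 | k-mer length of the graph front end |
| `min_kmer_count` | 2 | noise floor; drops singleton error k-mers |
| `min_junction_reads` | 2 | minimum spanning reads to keep a junction |
| `tip_length_factor` | 2.0 | dead-end tips shorter than this times `k` are trimmed |
| `alpha, beta, gamma` | 10, 1.4, 1.5 | balancing threshold `c = alpha*(gamma-beta)/w_min + beta` |
| `min_length` | 200 | minimum reported transcript length (community convention, not part of the method) |

The balancing threshold decays from large values at weakly covered nodes
towards `beta` at deeply covered ones: a given in/out imbalance must be
more extreme to be trusted where coverage (and hence relative noise) is
low. For **error-free** simulated data the noise floors have nothing to
filter and are best disabled (`min_kmer_count = 1`,
`min_junction_reads = 1`); the error-free experiments below do exactly
that, while defaults stay at the error-robust values.

## Design choices where the procedure is open

* **Edge weights in coverage units.** A junction's support is counted as
  the reads containing its spanning window. The shortest window that
  identifies a junction on both sides of a branch is `k + 1` bases (the
  last `k` of the upstream node plus the first novel base downstream); a
  `k`-window starting inside the shared `(k-1)`-overlap cannot separate
  sibling in-edges. The raw count is converted to fold-coverage units by
  `L / (L - w + 1)` over the read lengths `L`, so item sizes and reported
  abundances are directly comparable to per-base coverage.
* **Cycle breaking.** k-mer graphs of repetitive sequence may contain
  cycles; depth-first search removes the minimum-weight edge of each
  detected cycle, sacrificing the least read support.
* **Determinism.** Topological ordering uses Kahn's algorithm with a
  smallest-id priority queue; equal-cardinality maximum cuts resolve to
  the leftmost gap; solver ties resolve lexicographically. Identical
  inputs give byte-identical outputs.
* **Trap bookkeeping.** A trapped node's new items inherit, on the
  already-processed side, the trajectory segment of the items they
  replace (per receiving edge, cycling over donors). When *more* items
  occupy the trapped side than new items are created, the surplus items
  are not discarded -- dropping them would orphan the downstream edges
  only they cover and break the edge-path-cover guarantee -- but survive
  and pass through the node into the already-full source-side bins.
  Re-crossing a previously processed node never traps again; the local
  problem is re-solved with the previous per-bin occupancies as lower
  bounds, so item counts at any gap never decrease.
* **Mono-exon genes.** A component with a single node and no junctions is
  emitted directly as one transcript with abundance equal to the node's
  mean k-mer coverage.

## What the synthetic generator emulates -- and what it does not

`make_genes()` + `simulate_reads()` produce toy genes with single-isoform,
skipped-exon, retained-intron and mutually-exclusive-exon structures, with
random exon sequences rejection-sampled so that distinct genes share no
k-mer (each gene then yields exactly one splicing graph -- a sharp
integration assertion). Expression levels span a wide, log-uniform dynamic
range by default. Fragment starts are uniform over the valid positions
and `round(depth * length / read_yield)` fragments are drawn per isoform,
which keeps coverage targets analytic for tests. Substitution errors are
i.i.d.; there is no positional bias, no quality model, no homology between
genes, and no intron retention of genomic sequence beyond the designated
"intron" exon. Passing tests on this generator therefore demonstrate the
graph-algorithmic core -- not robustness to real library artifacts, nor
behaviour on homologous gene families, which can merge splicing graphs.

Two statistical properties of the generator matter when reading results:

* With fragments drawn uniformly over the `L - R + 1` valid starts, the
  coverage of an interior point exceeds the whole-transcript average by
  `L / (L - R + 1)`, so depth estimates carry a ~10-15% upward bias at
  these transcript lengths.
* An isoform's *specific* evidence in a skipped-exon gene is a point
  feature -- its junction -- observed by a ~Poisson number of reads with
  mean about `d * (R - w + 1) / R`. At 10x coverage with 100 bp reads
  this is ~7.5 reads, so any junction-based abundance estimate has an
  irreducible ~35% relative standard deviation. Abundance recovery at low
  coverage is therefore noisy by nature, and the test suite's recovery
  experiment reflects exactly that spread; tightening it would require
  pooling non-junction evidence (EM-style re-estimation), which is
  deliberately out of scope -- abundance is the raw item size.

## Problem sizes used in the checks

The property suites run on 200 random balanced sparse DAGs (3-15 interior
nodes -- real splicing graphs are sparse, a mostly linear backbone with a
handful of branches), 200 random packing instances (`m <= 3`, `n <= 6`,
integer weights up to 50), and an end-to-end simulation of 10 two-isoform
skipped-exon genes (exons 250-450 bp, 100 bp single-end stranded
error-free reads at 50x/10x). These sizes exercise every code path --
traps, reversals, jump-backs, re-solves -- while keeping the whole suite
fast enough to run routinely.

## A worked example

```{r diamond}
g <- splicing_graph(
  c("a", "b", "c", "d"),
  data.frame(u = c("a", "a", "b", "c"), v = c("b", "c", "d", "d"),
             weight = c(30, 10, 30, 10)))
bal <- balance_graph(add_source_sink(g))
run <- run_packing(bal)
for (it in run$items) {
  cat(it$id, "size", it$size, ":",
      paste(trajectory_to_path(bal, it), collapse = " -> "), "\n")
}
```

The two isoforms of this skipped-exon-like bubble are recovered with their
coverages 30 and 10. The worked trap example (`example_trap_graph()`)
shows the full forth-and-back pattern:

```{r trap}
run <- run_packing(example_trap_graph())
direction_sequence(run)
```

## Known limitations

* The graph front end is a minimal k-mer assembler: no paired-end
  bridging across coverage gaps, no quality-aware error correction, no
  scaffolding; paired reads are used only as extra sequence (and for
  strand voting in unstranded mode).
* The packing procedure is node-local and greedy by design; it carries no
  global optimality claim over whole-graph path decompositions.
* Abundances are raw item sizes in coverage units -- no statistical
  re-estimation, no length normalization to TPM-like units.
* Exact solving is restricted to the tiny node-local instances the method
  generates; there is no large-instance packing support.
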