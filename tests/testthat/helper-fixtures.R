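## shared fixtures built in code

chain_graph <- function(weights = c(5, 3)) {
  n <- length(weights) + 1L
  ids <- as.character(seq_len(n))
  splicing_graph(ids, data.frame(u = ids[-n], v = ids[-1L], weight = weights,
                                 stringsAsFactors = FALSE))
}

diamond_graph <- function(wb = 30, wc = 10) {
  splicing_graph(c("a", "b", "c", "d"),
                 data.frame(u = c("a", "a", "b", "c"),
                            v = c("b", "c", "d", "d"),
                            weight = c(wb, wc, wb, wc),
                            stringsAsFactors = FALSE))
}

## raw random DAG (possibly with multiple sources/sinks), no balancing
random_dag <- function(n, seed, p = 0.35) {
  set.seed(seed)
  ids <- as.character(seq_len(n))
  eu <- character(); ev <- character()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p) { eu <- c(eu, ids[[i]]); ev <- c(ev, ids[[j]]) }
  }
  if (!length(eu)) { eu <- ids[[1L]]; ev <- ids[[2L]] }
  splicing_graph(ids, data.frame(u = eu, v = ev,
                                 weight = sample(50L, length(eu), replace = TRUE),
                                 stringsAsFactors = FALSE))
}

## enumerate all maximal directed paths (small graphs only)
all_paths <- function(g) {
  sources <- setdiff(g$nodes, g$edges$v)
  out <- list()
  grow <- function(path) {
    nxt <- g$edges$v[g$edges$u == path[[length(path)]]]
    if (!length(nxt)) { out[[length(out) + 1L]] <<- path; return() }
    for (v in nxt) grow(c(path, v))
  }
  for (s in sources) grow(s)
  out
}

## error-free reads tiling a sequence at every offset (deterministic)
tile_reads <- function(seq, read_len, step = 1L) {
  L <- nchar(seq)
  starts <- unique(c(seq.int(1L, L - read_len + 1L, by = step),
                     L - read_len + 1L))
  substring(seq, starts, starts + read_len - 1L)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random DNA using the ambient RNG state (callers set.seed first)
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

random_instance <- function(seed, m_max = 3L, n_max = 6L) {
  set.seed(seed)
  m <- sample(m_max, 1L)
  n <- sample(seq(m, n_max), 1L)
  packing_instance(sample(50L, m, replace = TRUE),
                   sample(50L, n, replace = TRUE))
}
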