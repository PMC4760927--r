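#' Node-local bin-packing instances
#'
#' At each node the packing engine must distribute the items carried by the
#' edges on one side of the node into the edges (bins) on the other side.
#' Bins have capacities `c_i` (edge weights) and items sizes `w_j`; an
#' assignment packs every item into exactly one bin and minimizes
#' `sum_i (c_i - sum_j w_j x_ij)^2`, the squared deviation of each bin's
#' load from its capacity.  Two variants exist: the regular step requires
#' every bin to receive at least one item (`min_counts = 1`), while the
#' trap-replacement step requires bin `i` to receive at least `n_i` items,
#' the occupancy it held before the reversal.
#'
#' @param bins numeric vector of bin capacities (`c_i`).
#' @param items numeric vector of item sizes (`w_j`), all `> 0`.
#' @param min_counts optional integer vector of per-bin lower bounds.
#' @return a `packing_instance` list with `capacities`, `sizes`,
#'   `min_counts`, `m`, `n`.
#' @export
packing_instance <- function(bins, items, min_counts = NULL) {
  m <- length(bins); n <- length(items)
  stopifnot(m >= 1, n >= 1, all(items > 0), all(bins >= 0))
  if (is.null(min_counts)) min_counts <- rep(1L, m)
  stopifnot(length(min_counts) == m, all(min_counts >= 0))
  if (sum(min_counts) > n)
    stop("infeasible lower bounds: sum(min_counts) > number of items")
  structure(list(capacities = as.numeric(bins), sizes = as.numeric(items),
                 min_counts = as.integer(min_counts), m = m, n = n),
            class = "packing_instance")
}

#' @rdname packing_instance
#' @details `formulate_eq1()` is the regular-step variant (requires at
#'   least as many items as bins, every bin gets one); `formulate_eq2()` is
#'   the trap variant with explicit per-bin occupancy lower bounds.
#' @export
formulate_eq1 <- function(bins, items) {
  if (length(items) < length(bins))
    stop("fewer items than bins: this node is a trap; use formulate_eq2 via handle_trap")
  packing_instance(bins, items, rep(1L, length(bins)))
}

#' @rdname packing_instance
#' @export
formulate_eq2 <- function(bins, items, min_counts) {
  packing_instance(bins, items, min_counts)
}

#' Number of variables of the linearized 0-1 ILP
#'
#' With `m` bins and `n` items the linearization has `m*n` assignment
#' variables plus `m * n*(n+1)/2` pair variables (one per unordered item
#' pair within each bin, diagonal included), i.e. `m*n*(n+3)/2` in total.
#'
#' @param m,n bin and item counts.
#' @return integer variable count.
#' @export
ilp_variable_count <- function(m, n) as.integer(m * n * (n + 3) / 2)

#' Linearize a quadratic packing instance to a 0-1 ILP
#'
#' Expands each squared bin deviation
#' `(c_i - sum_j w_j x_ij)^2 = c_i^2 - 2 c_i sum_j w_j x_ij +
#'  sum_{j <= k} kappa_{jk} w_j w_k x_ijik` (with `kappa = 1` on the
#' diagonal and `2` off it) and introduces one product variable `x_ijik`
#' per quadratic term, linked to its factors by the three constraint
#' families `x_ijik <= x_ij`, `x_ijik <= x_ik` and
#' `x_ij + x_ik - 1 <= x_ijik`.
#'
#' @param inst a [packing_instance()].
#' @return a `linearized_ilp` list with the constant, the assignment
#'   variables (`i`, `j`, `coef`) and pair variables (`i`, `j`, `k`,
#'   `coef`), plus the carried-over assignment constraints.
#' @export
linearize <- function(inst) {
  stopifnot(inherits(inst, "packing_instance"))
  m <- inst$m; n <- inst$n
  cc <- inst$capacities; w <- inst$sizes
  lin <- expand.grid(j = seq_len(n), i = seq_len(m))[, c("i", "j")]
  lin$name <- sprintf("x_%d_%d", lin$i, lin$j)
  lin$coef <- -2 * cc[lin$i] * w[lin$j]
  pairs <- list()
  for (i in seq_len(m)) for (j in seq_len(n)) for (k in j:n) {
    pairs[[length(pairs) + 1L]] <-
      data.frame(i = i, j = j, k = k,
                 name = sprintf("y_%d_%d_%d", i, j, k),
                 coef = (if (j == k) 1 else 2) * w[j] * w[k])
  }
  pairs <- do.call(rbind, pairs)
  out <- list(instance = inst, m = m, n = n,
              constant = sum(cc^2), linear = lin, pair = pairs,
              n_variables = nrow(lin) + nrow(pairs))
  stopifnot(out$n_variables == ilp_variable_count(m, n))
  class(out) <- "linearized_ilp"
  out
}

## Enumerate all feasible assignments (item -> bin maps satisfying the
## per-bin lower bounds) as an (n_assignments x n_items) integer matrix.
## Fails when the search space m^n exceeds `limit`.
enumerate_assignments <- function(m, n, min_counts, limit = 1e6) {
  if (m^n > limit) stop("instance too large for enumeration: m^n = ", m^n)
  A <- as.matrix(expand.grid(rep(list(seq_len(m)), n)))
  dimnames(A) <- NULL
  keep <- rep(TRUE, nrow(A))
  for (i in seq_len(m)) {
    cnt <- rowSums(A == i)
    keep <- keep & cnt >= min_counts[i]
  }
  A[keep, , drop = FALSE]
}

## Flattened row-major x matrix (bins x items) per assignment row,
## used for the deterministic lexicographic tie rule.
flatten_x <- function(A, m, n) {
  X <- matrix(0L, nrow(A), m * n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    X[, (i - 1L) * n + j] <- as.integer(A[, j] == i)
  }
  X
}

## Among rows of A minimizing obj (within tol), pick the one whose
## flattened x vector is lexicographically smallest.
pick_optimum <- function(A, obj, m, n, tol = 1e-9) {
  best <- min(obj)
  cand <- which(obj <= best + tol * max(1, abs(best)))
  if (length(cand) > 1L) {
    X <- flatten_x(A[cand, , drop = FALSE], m, n)
    ord <- do.call(order, as.data.frame(X))
    cand <- cand[ord[1L]]
  }
  cand[1L]
}

assignment_result <- function(assign_vec, inst, objective) {
  x <- matrix(0L, inst$m, inst$n)
  x[cbind(assign_vec, seq_len(inst$n))] <- 1L
  loads <- as.numeric(x %*% inst$sizes)
  structure(list(x = x, assignment = assign_vec, objective = objective,
                 loads = loads, instance = inst),
            class = "packing_assignment")
}

#' Solve a linearized packing ILP exactly
#'
#' Exhaustively solves the 0-1 ILP produced by [linearize()].  Because all
#' pair-variable objective coefficients are positive, any optimal solution
#' sets `x_ijik = x_ij * x_ik` (the linking constraints pin the product
#' from below, the objective from above), so the solver enumerates the
#' assignment variables, completes the pair variables through the linking
#' constraints, and evaluates the *linear* objective.  Ties are broken by
#' the lexicographically smallest flattened `x` matrix.  The common
#' degenerate shapes `m = 1` (all items into the single bin) and `n = 1`
#' bypass enumeration.
#'
#' @param ilp a `linearized_ilp` from [linearize()].
#' @return a `packing_assignment` with binary matrix `x` (bins x items),
#'   the per-item bin `assignment`, bin `loads` and the optimal
#'   `objective`.
#' @export
solve_exact <- function(ilp) {
  stopifnot(inherits(ilp, "linearized_ilp"))
  inst <- ilp$instance
  m <- ilp$m; n <- ilp$n
  if (m == 1L) {
    ## single bin: the assignment is forced
    av <- rep(1L, n)
    obj <- eval_linear_objective(ilp, matrix(av, nrow = 1))[1L]
    return(assignment_result(av, inst, obj))
  }
  if (n == 1L) {
    if (sum(inst$min_counts) > 1L) stop("infeasible: one item cannot satisfy the per-bin lower bounds")
    forced <- which(inst$min_counts == 1L)
    cand <- if (length(forced)) forced else seq_len(m)
    objs <- eval_linear_objective(ilp, matrix(cand, ncol = 1))
    best <- cand[pick_optimum(matrix(cand, ncol = 1), objs, m, n)]
    return(assignment_result(best, inst, min(objs)))
  }
  A <- enumerate_assignments(m, n, inst$min_counts)
  if (!nrow(A)) stop("infeasible: no assignment satisfies the per-bin lower bounds")
  obj <- eval_linear_objective(ilp, A)
  sel <- pick_optimum(A, obj, m, n)
  assignment_result(A[sel, ], inst, obj[sel])
}

## Evaluate the linearized objective (constant + linear + pair terms) for
## each assignment row; pair variables take their linked values x_ij*x_ik.
eval_linear_objective <- function(ilp, A) {
  obj <- rep(ilp$constant, nrow(A))
  for (r in seq_len(nrow(ilp$linear))) {
    i <- ilp$linear$i[r]; j <- ilp$linear$j[r]
    obj <- obj + ilp$linear$coef[r] * (A[, j] == i)
  }
  for (r in seq_len(nrow(ilp$pair))) {
    i <- ilp$pair$i[r]; j <- ilp$pair$j[r]; k <- ilp$pair$k[r]
    obj <- obj + ilp$pair$coef[r] * ((A[, j] == i) & (A[, k] == i))
  }
  obj
}

#' Exhaustive oracle for packing instances
#'
#' Enumerates every item-to-bin map, filters by the per-bin lower bounds,
#' and evaluates the quadratic objective
#' `sum_i (c_i - load_i)^2` directly (no linearization), with the same
#' lexicographic tie rule as [solve_exact()].  This is the independent
#' reference the exact solver is checked against.
#'
#' @param inst a [packing_instance()].
#' @return a `packing_assignment`.
#' @export
brute_force_pack <- function(inst) {
  stopifnot(inherits(inst, "packing_instance"))
  m <- inst$m; n <- inst$n
  A <- enumerate_assignments(m, n, inst$min_counts)
  if (!nrow(A)) stop("infeasible: no assignment satisfies the per-bin lower bounds")
  obj <- rep(0, nrow(A))
  for (i in seq_len(m)) {
    load <- rowSums(matrix(inst$sizes, nrow(A), n, byrow = TRUE) * (A == i))
    obj <- obj + (inst$capacities[i] - load)^2
  }
  sel <- pick_optimum(A, obj, m, n)
  assignment_result(A[sel, ], inst, obj[sel])
}

#' Solve a packing instance (linearize + exact 0-1 solve)
#'
#' Convenience wrapper used by the packing engine.
#'
#' @param inst a [packing_instance()].
#' @return a `packing_assignment`.
#' @export
solve_packing <- function(inst) solve_exact(linearize(inst))

#' Serialize / restore packing instances as JSON regression fixtures
#' @param inst a [packing_instance()].
#' @param path file path.
#' @export
write_packing_instance <- function(inst, path) {
  jsonlite::write_json(list(capacities = inst$capacities, sizes = inst$sizes,
                            min_counts = inst$min_counts),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_packing_instance
#' @export
read_packing_instance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  packing_instance(x$capacities, x$sizes, x$min_counts)
}
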