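#' Constraints on treatment sequences and allocation matrices
#'
#' A constraint set defines which length-`T` arm sequences a cluster may
#' follow and which combinations of sequences form an allowed allocation
#' matrix. Constraints compose conjunctively.
#'
#' @param monotone rows nondecreasing, `X[i,j] >= X[i,j-1]` (the
#'   nested-intervention setting). Default `TRUE`.
#' @param start_at_control every cluster starts on arm 0 (`X[i,1] = 0`).
#' @param end_at_top every cluster finishes on arm `D - 1`.
#' @param receives_all_arms every cluster receives every arm at some point.
#' @param equal_allocation the design uses `k` distinct sequences, each
#'   allocated to exactly `C / k` clusters, for some divisor `k` of `C`.
#' @param require_identifiable drop allocation matrices under which the fixed
#'   effects are not estimable (default `TRUE`).
#' @return Object of class `masw_constraints`.
#' @export
constraint_set <- function(monotone = TRUE, start_at_control = FALSE,
                           end_at_top = FALSE, receives_all_arms = FALSE,
                           equal_allocation = FALSE,
                           require_identifiable = TRUE) {
  structure(
    list(monotone = monotone, start_at_control = start_at_control,
         end_at_top = end_at_top, receives_all_arms = receives_all_arms,
         equal_allocation = equal_allocation,
         require_identifiable = require_identifiable),
    class = "masw_constraints"
  )
}

#' Enumerate allowed treatment sequences
#'
#' All length-`T` sequences over arms `0:(D-1)` satisfying the row-level
#' constraints, in lexicographic order. For the unconstrained monotone
#' (nondecreasing) case the count is `choose(T + D - 1, D - 1)`
#' (stars and bars).
#'
#' @param T number of periods.
#' @param D number of arms.
#' @param constraints a [constraint_set()]; only its row-level flags
#'   (`monotone`, `start_at_control`, `end_at_top`, `receives_all_arms`) are
#'   used here.
#' @return integer matrix, one row per sequence.
#' @examples
#' enumerate_sequences(2, 2)  # 00, 01, 11
#' @export
enumerate_sequences <- function(T, D, constraints = constraint_set()) {
  stopifnot(T >= 1, D >= 2)
  if (constraints$monotone) {
    seqs <- monotone_sequences(T, D)
  } else {
    grid <- do.call(expand.grid, rev(replicate(T, 0:(D - 1), simplify = FALSE)))
    seqs <- as.matrix(grid)[, rev(seq_len(T)), drop = FALSE]
    dimnames(seqs) <- NULL
    seqs <- seqs[do.call(order, as.data.frame(seqs)), , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(seqs))
  if (constraints$start_at_control) keep <- keep & seqs[, 1L] == 0L
  if (constraints$end_at_top) keep <- keep & seqs[, T] == D - 1L
  if (constraints$receives_all_arms) {
    keep <- keep & apply(seqs, 1L, function(s) length(unique(s)) == D)
  }
  seqs[keep, , drop = FALSE]
}

# Nondecreasing sequences over 0:(D-1), lexicographic; recursive stars-and-bars.
monotone_sequences <- function(T, D) {
  rec <- function(T, lo) {
    if (T == 0L) return(matrix(integer(0), 1L, 0L))
    out <- lapply(lo:(D - 1L), function(a) {
      tail <- rec(T - 1L, a)
      cbind(rep(a, nrow(tail)), tail)
    })
    do.call(rbind, out)
  }
  m <- rec(T, 0L)
  storage.mode(m) <- "integer"
  m
}

# All multisets of size C from S items as an index matrix (one row per
# multiset, entries nondecreasing). Uses the bijection with C-subsets of
# {1, ..., S + C - 1}.
multiset_index_matrix <- function(S, C) {
  n <- choose(S + C - 1, C)
  if (n > 5e6) {
    stop("design space stratum has ", format(n, big.mark = ","),
         " allocation matrices; too large to materialize - use ce_search()")
  }
  t(combn(S + C - 1L, C) - 0:(C - 1L))
}

n_multisets <- function(S, C) choose(S + C - 1, C)

# Row multiplicities all equal to C/k for some divisor k of C?
is_equal_allocation <- function(idx_row) {
  tab <- table(idx_row)
  length(unique(tab)) == 1L
}

#' Enumerate allowed allocation matrices
#'
#' Clusters are exchangeable under the model (no cluster-level covariates),
#' so two allocation matrices that differ only by a row permutation are
#' equivalent: the enumeration yields one canonical representative per
#' *multiset* of `C` sequences, with rows sorted lexicographically. This
#' symmetry reduction shrinks e.g. the `7^10` ordered two-arm matrices for
#' `C = 10, T = 6` to 8008 canonical designs while preserving every
#' criterion used in this package.
#'
#' @param C,T,m,D design dimensions.
#' @param constraints a [constraint_set()]. With `equal_allocation`, only
#'   designs whose sequence multiplicities are all `C/k` (for a divisor `k`
#'   of `C`) are kept; with `require_identifiable`, non-identifiable designs
#'   are dropped.
#' @return list of [masw_design()] objects.
#' @export
enumerate_designs <- function(C, T, m, D, constraints = constraint_set()) {
  stopifnot(C >= 1, T >= 1, m >= 1, D >= 2)
  seqs <- enumerate_sequences(T, D, constraints)
  if (nrow(seqs) == 0L) return(list())
  idx <- multiset_index_matrix(nrow(seqs), C)
  if (constraints$equal_allocation) {
    idx <- idx[apply(idx, 1L, is_equal_allocation), , drop = FALSE]
  }
  designs <- lapply(seq_len(nrow(idx)), function(r) {
    X <- seqs[idx[r, ], , drop = FALSE]
    suppressWarnings(masw_design(X, m = m, D = D, monotone = FALSE))
  })
  if (constraints$require_identifiable) {
    designs <- Filter(check_identifiability, designs)
  }
  designs
}

#' Define a design space
#'
#' A design space is the set of all designs `{m, C, T, X}` with `T` drawn
#' from `T_set`, `C` from a per-`T` set, `m` from a per-`(C, T)` set, and `X`
#' ranging over the constrained allocation matrices for that `(C, T)`.
#'
#' @param T_set integer vector of allowed numbers of periods.
#' @param C_sets allowed numbers of clusters: a vector (same for every `T`)
#'   or a list named by the values of `T`.
#' @param M_sets allowed `m` values: a vector, a list named by the values of
#'   `T`, or a `function(C, T)` returning a vector.
#' @param D number of arms.
#' @param constraints a [constraint_set()].
#' @return Object of class `masw_space`.
#' @examples
#' # fixed C = 10, T = 6, m = 10, two arms:
#' design_space(6, 10, 10, D = 2)
#' @export
design_space <- function(T_set, C_sets, M_sets, D,
                         constraints = constraint_set()) {
  stopifnot(all(T_set >= 1), D >= 2)
  structure(
    list(T_set = as.integer(sort(T_set)), C_sets = C_sets, M_sets = M_sets,
         D = as.integer(D), constraints = constraints),
    class = "masw_space"
  )
}

# Expand a space into its (T, C, m) strata, deterministically ordered.
space_strata <- function(space) {
  strata <- list()
  for (T in space$T_set) {
    Cs <- if (is.list(space$C_sets)) space$C_sets[[as.character(T)]] else space$C_sets
    if (is.null(Cs)) next
    for (C in sort(Cs)) {
      ms <- if (is.function(space$M_sets)) {
        space$M_sets(C, T)
      } else if (is.list(space$M_sets)) {
        space$M_sets[[as.character(T)]]
      } else {
        space$M_sets
      }
      if (is.null(ms) || length(ms) == 0L) {
        stop("no allowed m values for C = ", C, ", T = ", T)
      }
      for (m in sort(ms)) {
        strata[[length(strata) + 1L]] <- c(T = T, C = C, m = m)
      }
    }
  }
  do.call(rbind, lapply(strata, function(s) as.data.frame(as.list(s))))
}

#' Count the designs in a space
#'
#' Exact count via multiset-coefficient arithmetic, without materializing any
#' design: for each `(T, C, m)` stratum with `S` allowed sequences the number
#' of canonical allocation matrices is `choose(S + C - 1, C)` (or, under
#' equal allocation, the sum of `choose(S, k)` over divisors `k` of `C` with
#' `k <= S`). The identifiability screen requires materializing designs and
#' is *not* applied here, so [exhaustive_search()] reports
#' `n_evaluated = space_size(space) - (number of non-identifiable designs)`.
#' All counts arising in practice are far below `2^53` and therefore exact
#' in double precision.
#'
#' @param space a [design_space()].
#' @return the number of designs (a double, exact).
#' @export
space_size <- function(space) {
  strata <- space_strata(space)
  total <- 0
  seq_count_cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(strata))) {
    T <- strata$T[r]; C <- strata$C[r]
    key <- as.character(T)
    if (is.null(seq_count_cache[[key]])) {
      seq_count_cache[[key]] <- nrow(enumerate_sequences(T, space$D, space$constraints))
    }
    S <- seq_count_cache[[key]]
    if (S == 0L) next
    if (space$constraints$equal_allocation) {
      ks <- Filter(function(k) C %% k == 0 && k <= S, seq_len(C))
      total <- total + sum(vapply(ks, function(k) choose(S, k), 0))
    } else {
      total <- total + n_multisets(S, C)
    }
  }
  total
}

#' @export
print.masw_space <- function(x, ...) {
  strata <- space_strata(x)
  cat(sprintf("Design space: D = %d arms, %d (T, C, m) strata, %s designs\n",
              x$D, nrow(strata), format(space_size(x), big.mark = ",")))
  flags <- names(Filter(isTRUE, unclass(x$constraints)))
  cat("Constraints:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
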