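#' Model matrices for one trial design
#'
#' Builds the per-cluster fixed-effect matrices and the (common) within-cluster
#' covariance matrix of the linear mixed model. Observations within a cluster
#' are ordered period-major, subject-minor: the first `m` rows are the `m`
#' subjects in period 1, and subject index `k` refers to the same individual
#' in every period (closed cohort; the cross-sectional model is the exact
#' `sigma_s2 = 0` special case).
#'
#' The covariance of the `m * T` responses of one cluster is
#' `sigma_c2 * J + sigma_theta2 * (period-block J) + sigma_s2 * (same-subject
#' cross-period) + sigma_eps2 * I`, with `J` the all-ones matrix. It is
#' positive definite for any admissible variance components.
#'
#' @param design a [masw_design()].
#' @param vc a [variance_components()] object.
#' @return List with `A` (list of `C` matrices, each `(m*T) x (T + D - 1)`)
#'   and `V` (the `(m*T) x (m*T)` covariance block, identical across
#'   clusters).
#' @export
build_model_matrices <- function(design, vc) {
  stopifnot(inherits(design, "masw_design"), inherits(vc, "masw_vc"))
  A <- lapply(seq_len(design$C), function(i) {
    A1 <- sequence_fixed_matrix(design$X[i, ], design$T, design$D)
    A1[rep(seq_len(design$T), each = design$m), , drop = FALSE]
  })
  list(A = A, V = cluster_covariance(design$m, design$T, vc))
}

cluster_covariance <- function(m, T, vc) {
  n <- m * T
  V <- matrix(vc$sigma_c2, n, n)
  if (vc$sigma_theta2 != 0) {
    V <- V + vc$sigma_theta2 * kronecker(diag(T), matrix(1, m, m))
  }
  if (vc$sigma_s2 != 0) {
    V <- V + vc$sigma_s2 * kronecker(matrix(1, T, T), diag(m))
  }
  V + vc$sigma_eps2 * diag(n)
}

# Singularity rule shared by every evaluation path: the information matrix
# is usable only when its smallest singular value exceeds
# p * eps * largest * 1e3 (robust across the near-collinear designs that
# arise during search).
information_nonsingular <- function(K) {
  sv <- svd(K, nu = 0, nv = 0)$d
  sv[length(sv)] >= nrow(K) * .Machine$double.eps * sv[1L] * 1e3
}

# Per-sequence information blocks A_s' V^{-1} A_s, returned as an S x p^2
# matrix (row s = vec of the p x p block). Information is additive over
# clusters, so any design's information matrix is a multiplicity-weighted sum
# of these rows; caching them per distinct sequence is what makes exhaustive
# search over multisets of sequences feasible.
sequence_information_blocks <- function(seqs, m, T, D, vc) {
  V <- cluster_covariance(m, T, vc)
  Vi <- chol2inv(chol(V))
  p <- T + D - 1L
  S <- nrow(seqs)
  out <- matrix(0, S, p * p)
  for (s in seq_len(S)) {
    A1 <- sequence_fixed_matrix(seqs[s, ], T, D)
    A <- A1[rep(seq_len(T), each = m), , drop = FALSE]
    out[s, ] <- as.vector(crossprod(A, Vi %*% A))
  }
  out
}

#' Covariance of the treatment-effect estimators under GLS
#'
#' Computes \eqn{\Lambda = \{\sum_i A_i^\top V_i^{-1} A_i\}^{-1}}, the
#' covariance matrix of the GLS estimator of all fixed effects, exploiting the
#' block-diagonal covariance across clusters, and extracts the
#' \eqn{q = D - 1} treatment-effect block \eqn{\Lambda_q} (coordinates
#' `arm1 ... arm(D-1)`) together with the information levels
#' \eqn{I_f = 1/\Lambda_q[f,f]}.
#'
#' The result is invariant under permutation of the rows of `X` (information
#' is additive over clusters), and only the multiset of distinct sequences
#' matters: each distinct sequence's contribution is computed once and
#' weighted by its multiplicity.
#'
#' The accumulated information matrix is declared singular — the design
#' non-identifiable — when its smallest singular value falls below
#' `p * .Machine$double.eps * largest * 1e3`, a threshold chosen to be robust
#' across the near-collinear designs generated during search.
#'
#' @param design a [masw_design()].
#' @param vc a [variance_components()] object.
#' @return Object of class `masw_information`: `Lambda` (`p x p`, named),
#'   `Lambda_q` (`q x q`), `info` (length-`q` vector of `1/diag(Lambda_q)`),
#'   and the `design`/`vc` used.
#' @examples
#' d <- masw_design("001011", m = 2, C = 2, T = 3)
#' compute_information(d, vc_from_correlations(1, 0.05))
#' @export
compute_information <- function(design, vc) {
  stopifnot(inherits(design, "masw_design"), inherits(vc, "masw_vc"))
  T <- design$T; D <- design$D
  p <- T + D - 1L
  useq <- unique(design$X)
  mult <- integer(nrow(useq))
  key <- apply(design$X, 1L, paste, collapse = ",")
  ukey <- apply(useq, 1L, paste, collapse = ",")
  mult <- as.vector(table(factor(key, levels = ukey)))
  blocks <- sequence_information_blocks(useq, design$m, T, D, vc)
  K <- matrix(colSums(blocks * mult), p, p)
  if (!information_nonsingular(K)) {
    stop("non-identifiable design: fixed-effect information matrix is singular")
  }
  Lambda <- chol2inv(chol(K))
  nms <- fixed_effect_names(T, D)
  dimnames(Lambda) <- list(nms, nms)
  qidx <- intervention_coords(T, D)
  Lambda_q <- Lambda[qidx, qidx, drop = FALSE]
  structure(
    list(
      Lambda = Lambda,
      Lambda_q = Lambda_q,
      info = 1 / diag(Lambda_q),
      design = design, vc = vc
    ),
    class = "masw_information"
  )
}

#' @export
print.masw_information <- function(x, ...) {
  q <- ncol(x$Lambda_q)
  cat(sprintf("Treatment-effect covariance (q = %d):\n", q))
  print(x$Lambda_q)
  cat(sprintf("det = %.4g, trace/q = %.4g, maxDiag = %.4g\n",
              det(x$Lambda_q), mean(diag(x$Lambda_q)), max(diag(x$Lambda_q))))
  invisible(x)
}
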