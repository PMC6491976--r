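# Independent dense GLS oracle: builds the whole-trial fixed-effect matrix
# and the full N x N covariance observation-by-observation from the model's
# correlation rules (no per-cluster blocks, no kronecker shortcuts), then
# inverts in one piece. Deliberately written differently from the package's
# blockwise accumulation so the two can cross-check each other.
dense_gls_covariance <- function(design, vc) {
  C <- design$C; T <- design$T; m <- design$m; D <- design$D
  obs <- expand.grid(k = seq_len(m), j = seq_len(T), i = seq_len(C))
  obs <- obs[order(obs$i, obs$j, obs$k), ]
  N <- nrow(obs)
  p <- T + D - 1L
  A <- matrix(0, N, p)
  A[, 1] <- 1
  for (r in seq_len(N)) {
    j <- obs$j[r]
    if (j > 1) A[r, j] <- 1
    arm <- design$X[obs$i[r], j]
    for (d in seq_len(D - 1L)) if (arm >= d) A[r, T + d] <- 1
  }
  V <- matrix(0, N, N)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      if (obs$i[a] != obs$i[b]) next
      v <- vc$sigma_c2
      if (obs$j[a] == obs$j[b]) v <- v + vc$sigma_theta2
      if (obs$k[a] == obs$k[b]) v <- v + vc$sigma_s2
      if (a == b) v <- v + vc$sigma_eps2
      V[a, b] <- v
    }
  }
  solve(t(A) %*% solve(V) %*% A)
}

# Bisection inverse of the cluster mean correlation map (oracle for the
# closed-form inverse shipped in the package).
bisect_icc <- function(E_target, m, T, tol = 1e-14) {
  f <- function(rho) m * T * rho / (1 + (m * T - 1) * rho) - E_target
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random identifiable design + variance components, for property tests.
random_instance <- function(max_obs = 200) {
  repeat {
    D <- sample(2:3, 1)
    T <- sample(2:4, 1)
    C <- sample(2:4, 1)
    m_max <- max(1, floor(max_obs / (C * T)))
    m <- sample(seq_len(min(3, m_max)), 1)
    seqs <- enumerate_sequences(T, D)
    X <- seqs[sample.int(nrow(seqs), C, replace = TRUE), , drop = FALSE]
    d <- suppressWarnings(masw_design(X, m = m, D = D))
    if (!check_identifiability(d)) next
    vc <- variance_components(
      sigma_c2 = runif(1, 0, 0.3), sigma_theta2 = runif(1, 0, 0.2),
      sigma_s2 = runif(1, 0, 0.3), sigma_eps2 = runif(1, 0.3, 1.5)
    )
    return(list(design = d, vc = vc))
  }
}

canonical_string <- function(design) {
  X <- if (inherits(design, "masw_design")) design$X else design
  rows <- apply(X, 1L, paste, collapse = "")
  paste(sort(rows), collapse = "")
}
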