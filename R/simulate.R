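#' Simulation settings
#'
#' Ground truth for the Monte-Carlo validation of the analytic power
#' calculations. Under the linear model, power depends only on the
#' intervention effects and the variance components — not on the intercept
#' or period effects — so the nuisance defaults are zero (a test asserts
#' this invariance).
#'
#' @param n_sim number of simulated trials.
#' @param seed integer seed; identical specs give byte-identical output.
#' @param beta_true true intervention effects (length `q = D - 1`).
#' @param mu true intercept.
#' @param period_effects length-`T` vector of period effects; the first
#'   entry must be 0 (the identifiability constraint `pi_1 = 0`). `NULL`
#'   means all zero.
#' @return Object of class `masw_sim_spec`.
#' @export
simulation_spec <- function(n_sim, seed, beta_true, mu = 0,
                            period_effects = NULL) {
  stopifnot(n_sim >= 1, n_sim == round(n_sim))
  if (!is.null(period_effects) && period_effects[1L] != 0) {
    stop("period_effects[1] must be 0 (pi_1 = 0 for identifiability)")
  }
  structure(
    list(n_sim = as.integer(n_sim), seed = as.integer(seed),
         beta_true = as.numeric(beta_true), mu = mu,
         period_effects = period_effects),
    class = "masw_sim_spec"
  )
}

# One trial's responses as a C x T x m array, using the current RNG state.
draw_trial <- function(design, vc, sim) {
  C <- design$C; T <- design$T; m <- design$m; D <- design$D
  pi_j <- if (is.null(sim$period_effects)) rep(0, T) else sim$period_effects
  if (length(pi_j) != T) stop("period_effects must have length T")
  if (length(sim$beta_true) != D - 1L) stop("beta_true must have length D - 1")
  y <- array(0, dim = c(C, T, m))
  for (i in seq_len(C)) {
    ci <- rnorm(1L, 0, sqrt(vc$sigma_c2))
    th <- rnorm(T, 0, sqrt(vc$sigma_theta2))
    sk <- rnorm(m, 0, sqrt(vc$sigma_s2))
    for (j in seq_len(T)) {
      fixed <- sim$mu + pi_j[j] +
        sum(sim$beta_true * (design$X[i, j] >= seq_len(D - 1L)))
      y[i, j, ] <- fixed + ci + th[j] + sk + rnorm(m, 0, sqrt(vc$sigma_eps2))
    }
  }
  y
}

#' Simulate one trial under the mixed model
#'
#' Draws `y_ijk = mu + pi_j + sum_d beta_d 1{X_ij >= d} + c_i + theta_ij +
#' s_ik + eps_ijk` with independent normal random effects at the variances
#' in `vc`. Subject `k` is the same individual across periods (closed
#' cohort); cross-sectional sampling is the `sigma_s2 = 0` case.
#'
#' @param design a [masw_design()].
#' @param vc a [variance_components()] object.
#' @param sim a [simulation_spec()]; its `seed` is set before drawing, so
#'   the same spec always returns the same array.
#' @return numeric array of dimension `C x T x m`.
#' @export
simulate_trial <- function(design, vc, sim) {
  stopifnot(inherits(design, "masw_design"), inherits(vc, "masw_vc"),
            inherits(sim, "masw_sim_spec"))
  set.seed(sim$seed)
  draw_trial(design, vc, sim)
}

#' Export a simulated trial as a tidy data frame
#'
#' @param y array from [simulate_trial()].
#' @param design the design that produced it.
#' @return data frame with columns `cluster`, `period`, `subject`, `arm`,
#'   `response`.
#' @export
trial_as_data_frame <- function(y, design) {
  d <- dim(y)
  out <- expand.grid(subject = seq_len(d[3L]), period = seq_len(d[2L]),
                     cluster = seq_len(d[1L]))
  out <- out[, c("cluster", "period", "subject")]
  out$arm <- design$X[cbind(out$cluster, out$period)]
  out$response <- as.vector(aperm(y, c(3L, 2L, 1L)))
  out
}

# Flatten a trial array to the period-major, subject-minor per-cluster
# layout used by build_model_matrices().
flatten_trial <- function(y) {
  C <- dim(y)[1L]
  lapply(seq_len(C), function(i) as.vector(t(y[i, , , drop = TRUE])))
}

#' Known-variance GLS estimate from one simulated trial
#'
#' Computes `beta_hat = Lambda * sum_i A_i' V_i^{-1} y_i` with the variance
#' components taken as known (no REML/ML refitting — the simulator validates
#' the design-stage calculation, not a full analysis pipeline). The returned
#' `Lambda` does not depend on `y` and is identical to
#' [compute_information()]'s.
#'
#' @param y array from [simulate_trial()] (dimension `C x T x m`).
#' @param design a [masw_design()].
#' @param vc a [variance_components()] object.
#' @return list with `beta_hat` (all `p` fixed effects, named), `beta_q`
#'   (the intervention effects), `Lambda`, `Lambda_q`.
#' @export
gls_estimate <- function(y, design, vc) {
  info <- compute_information(design, vc)
  H <- gls_projector(design, vc, info)
  yflat <- unlist(flatten_trial(y))
  beta_hat <- as.numeric(H %*% yflat)
  names(beta_hat) <- rownames(info$Lambda)
  qidx <- intervention_coords(design$T, design$D)
  list(beta_hat = beta_hat, beta_q = beta_hat[qidx],
       Lambda = info$Lambda, Lambda_q = info$Lambda_q)
}

# p x (C*m*T) matrix mapping the stacked responses to beta_hat.
gls_projector <- function(design, vc, info = compute_information(design, vc)) {
  mm <- build_model_matrices(design, vc)
  Vi <- chol2inv(chol(mm$V))
  info$Lambda %*% do.call(cbind, lapply(mm$A, function(A) crossprod(A, Vi)))
}

#' Empirical power by Monte-Carlo simulation
#'
#' Simulates `n_sim` trials at `beta_true = delta`, applies the
#' known-variance GLS estimator and the Wald rule `Z_f > e`, and reports
#' per-hypothesis and any-rejection frequencies with binomial standard
#' errors. This is the package's independent oracle for
#' [individual_power()] and [combined_power()].
#'
#' @param design a [masw_design()].
#' @param vc a [variance_components()] object.
#' @param hyp a [hypothesis_spec()]; `delta` is used as the simulation
#'   truth.
#' @param sim a [simulation_spec()]; its `beta_true` (if different from
#'   `hyp$delta`) takes precedence, allowing null calibration checks with
#'   `beta_true = 0`.
#' @return list: `e`, `reject` (per-hypothesis frequencies), `reject_se`,
#'   `any_reject`, `any_reject_se`, `n_sim`.
#' @export
empirical_power <- function(design, vc, hyp, sim) {
  stopifnot(inherits(hyp, "masw_hypothesis"), inherits(sim, "masw_sim_spec"))
  info <- compute_information(design, vc)
  q <- hyp$q
  if (length(info$info) != q) stop("hyp$q does not match the design's arm count")
  e <- critical_value(hyp$alpha, q, hyp$correction)
  H <- gls_projector(design, vc, info)
  qidx <- intervention_coords(design$T, design$D)
  Hq <- H[qidx, , drop = FALSE]
  sqrtI <- sqrt(info$info)
  set.seed(sim$seed)
  rej <- matrix(FALSE, sim$n_sim, q)
  for (b in seq_len(sim$n_sim)) {
    y <- draw_trial(design, vc, sim)
    bq <- as.numeric(Hq %*% unlist(flatten_trial(y)))
    rej[b, ] <- bq * sqrtI > e
  }
  pr <- colMeans(rej)
  any_r <- mean(apply(rej, 1L, any))
  list(
    e = e,
    reject = pr,
    reject_se = sqrt(pr * (1 - pr) / sim$n_sim),
    any_reject = any_r,
    any_reject_se = sqrt(any_r * (1 - any_r) / sim$n_sim),
    n_sim = sim$n_sim
  )
}
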