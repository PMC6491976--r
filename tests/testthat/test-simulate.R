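test_that("simulation is reproducible and respects the noiseless limit", {
  d <- masw_design("000011", m = 2, C = 2, T = 3)
  vc <- vc_from_correlations(1, 0.1)
  sim <- simulation_spec(n_sim = 1, seed = 42, beta_true = 0.5, mu = 1,
                         period_effects = c(0, 0.2, -0.1))
  y1 <- simulate_trial(d, vc, sim)
  y2 <- simulate_trial(d, vc, sim)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(2, 3, 2))

  # near-zero noise: the response equals the fixed-effect surface
  vc0 <- variance_components(sigma_eps2 = 1e-20)
  y0 <- simulate_trial(d, vc0, sim)
  surface <- outer(seq_len(2), seq_len(3),
                   function(i, j) 1 + c(0, 0.2, -0.1)[j] + 0.5 * (d$X[cbind(i, j)] >= 1))
  for (k in 1:2) expect_equal(y0[, , k], surface, tolerance = 1e-8)

  expect_error(simulation_spec(10, 1, 0.5, period_effects = c(1, 0)),
               "pi_1 = 0")
})

test_that("simulated correlations match the model's rho parameters", {
  d <- masw_design(matrix(c(0L, 1L), 1, 2), m = 2, C = NULL, T = NULL,
                   monotone = TRUE)
  vc <- vc_from_correlations(2, 0.3, 0.1, 0.4)
  sim <- simulation_spec(n_sim = 1, seed = 9, beta_true = 0)
  n <- 5000
  set.seed(9)
  draws <- replicate(n, maswdesign:::draw_trial(d, vc, sim))
  # same cluster, same period, distinct subjects -> rho0 * sigma2
  c_within <- cov(draws[1, 1, 1, ], draws[1, 1, 2, ])
  expect_lt(abs(c_within - 0.3 * 2), 3 * 2 / sqrt(n) * 2)
  # same subject, distinct periods -> rho2 * sigma2
  c_subj <- cov(draws[1, 1, 1, ], draws[1, 2, 1, ])
  expect_lt(abs(c_subj - 0.4 * 2), 3 * 2 / sqrt(n) * 2)
  # distinct subjects, distinct periods -> rho1 * sigma2
  c_inter <- cov(draws[1, 1, 1, ], draws[1, 2, 2, ])
  expect_lt(abs(c_inter - 0.1 * 2), 3 * 2 / sqrt(n) * 2)
})

test_that("GLS recovers the truth exactly in the noiseless limit", {
  d <- masw_design("000100110111", m = 2, C = 3, T = 4)
  vc0 <- variance_components(sigma_eps2 = 1e-18)
  sim <- simulation_spec(n_sim = 1, seed = 5, beta_true = 0.7, mu = 0.3,
                         period_effects = c(0, 0.1, 0.2, 0.3))
  y <- simulate_trial(d, vc0, sim)
  # estimate under a nondegenerate working covariance (GLS is exact for
  # any V when the data are noiseless)
  fit <- gls_estimate(y, d, vc_from_correlations(1, 0.1))
  expect_equal(unname(fit$beta_q), 0.7, tolerance = 1e-6)
  expect_equal(unname(fit$beta_hat[1]), 0.3, tolerance = 1e-6)
})

test_that("gls_estimate's Lambda equals compute_information's", {
  inst <- list(design = masw_design("000112011222", m = 3, C = 2, T = 6),
               vc = vc_from_correlations(1, 0.1, 0.05, 0.2))
  sim <- simulation_spec(n_sim = 1, seed = 2, beta_true = c(0.3, 0.2))
  y <- simulate_trial(inst$design, inst$vc, sim)
  fit <- gls_estimate(y, inst$design, inst$vc)
  info <- compute_information(inst$design, inst$vc)
  expect_equal(fit$Lambda, info$Lambda, tolerance = 1e-12)
})

test_that("GLS is unbiased and its sampling covariance matches Lambda_q", {
  d <- masw_design("000112001122011222", m = 2, C = 3, T = 6)
  vc <- vc_from_correlations(1, 0.05)
  truth <- c(0.3, 0.2)
  sim <- simulation_spec(n_sim = 1, seed = 77, beta_true = truth)
  info <- compute_information(d, vc)
  H <- maswdesign:::gls_projector(d, vc, info)
  qidx <- maswdesign:::intervention_coords(d$T, d$D)
  set.seed(77)
  B <- 5000
  est <- matrix(0, B, 2)
  for (b in seq_len(B)) {
    y <- maswdesign:::draw_trial(d, vc, sim)
    est[b, ] <- (H %*% unlist(maswdesign:::flatten_trial(y)))[qidx]
  }
  se <- sqrt(diag(info$Lambda_q) / B)
  expect_lt(max(abs(colMeans(est) - truth) / se), 3)
  emp_cov <- cov(est)
  expect_equal(emp_cov, unname(info$Lambda_q), tolerance = 0.1)
})

test_that("empirical rejection rates are consistent and deterministic", {
  d <- masw_design("000112001122011222", m = 2, C = 3, T = 6)
  vc <- vc_from_correlations(1, 0.05)
  hyp <- hypothesis_spec(q = 2, alpha = 0.05, delta = c(0, 0))
  sim <- simulation_spec(n_sim = 400, seed = 12, beta_true = c(0, 0))
  out <- empirical_power(d, vc, hyp, sim)
  # familywise frequency below the Bonferroni bound (within noise)
  expect_lte(out$any_reject, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  # n_sim = 1 is a deterministic 0/1 record
  one <- empirical_power(d, vc, hyp, simulation_spec(1, 3, c(0, 0)))
  expect_true(all(one$reject %in% c(0, 1)))
  expect_identical(one,
                   empirical_power(d, vc, hyp, simulation_spec(1, 3, c(0, 0))))
})

test_that("power is invariant to the intercept and period nuisances", {
  d <- masw_design("000111001111", m = 2, C = 2, T = 6)
  vc <- vc_from_correlations(1, 0.1)
  hyp <- hypothesis_spec(q = 1, alpha = 0.05, delta = 0.6)
  base <- empirical_power(d, vc, hyp,
                          simulation_spec(300, 8, beta_true = 0.6))
  shifted <- empirical_power(d, vc, hyp,
                             simulation_spec(300, 8, beta_true = 0.6, mu = 50,
                                             period_effects = c(0, 3, -2, 1, 0.5, 9)))
  expect_identical(base$reject, shifted$reject)
})

test_that("tidy export carries the design labels through", {
  d <- masw_design("0112", m = 2, C = 1, T = 4, D = 3)
  vc <- vc_from_correlations(1, 0.1)
  y <- simulate_trial(d, vc, simulation_spec(1, 4, beta_true = c(1, 2)))
  df <- trial_as_data_frame(y, d)
  expect_equal(nrow(df), 8)
  expect_equal(df$arm[df$period == 1], c(0L, 0L))
  expect_equal(df$arm[df$period == 4], c(2L, 2L))
  expect_equal(df$response[df$cluster == 1 & df$period == 2 & df$subject == 1],
               y[1, 2, 1])
})
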