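vc05 <- vc_from_correlations(1, 0.05)

test_that("criterion values follow their definitions", {
  expect_equal(criterion_value(diag(2), "D"), 1)
  expect_equal(criterion_value(diag(2), "A"), 1)
  expect_equal(criterion_value(diag(2), "E"), 1)
  L <- matrix(c(4, 1, 1, 2), 2, 2)
  expect_equal(criterion_value(L, "D"), 7)
  expect_equal(criterion_value(L, "A"), 3)
  expect_equal(criterion_value(L, "E"), 4)
  # scalar case: all three coincide with the single variance
  expect_equal(criterion_value(matrix(0.3), "D"),
               criterion_value(matrix(0.3), "E"))
  expect_error(criterion_value(matrix(c(1, 2, 2, 1), 2, 2), "D"),
               "positive definite")
})

test_that("admissibility scores implement the weighted rescaling", {
  # hand evaluation: costs {100, 200}, criteria {4, 2}, w = 0.5 ties at 0.5
  expect_equal(maswdesign:::rescale_term(c(100, 200)), c(0, 1))
  sc <- 0.5 * maswdesign:::rescale_term(c(100, 200)) +
    0.5 * maswdesign:::rescale_term(c(4, 2))
  expect_equal(sc, c(0.5, 0.5))

  # w = 0 ranking is the raw criterion ranking
  des <- enumerate_designs(3, 3, 2, 2)
  spec <- admissible_spec("A", w = 0)
  sc0 <- admissibility_scores(des, spec, vc05)
  crit <- vapply(des, function(d)
    criterion_value(compute_information(d, vc05), "A"), 0)
  expect_equal(order(sc0), order(crit))
  expect_true(all(sc0 >= 0 & sc0 <= 1))

  # degenerate ranges contribute zero
  expect_equal(admissibility_scores(des[1], spec, vc05), 0)
  expect_error(admissibility_scores(list(), spec, vc05), "at least one")
  expect_warning(admissible_spec("D", w = 1), "w = 1")
})

test_that("exhaustive search minimizes the criterion over the space", {
  sp <- design_space(3, 4, 2, D = 2)
  res <- exhaustive_search(sp, admissible_spec("A"), vc05)
  # brute force over materialized designs
  des <- enumerate_designs(4, 3, 2, 2)
  crit <- vapply(des, function(d)
    criterion_value(compute_information(d, vc05), "A"), 0)
  expect_equal(res$criterion_value, min(crit), tolerance = 1e-12)
  expect_identical(design_string(res$best),
                   design_string(des[[which.min(crit)]]))
  expect_equal(res$n_evaluated, length(des))
  # search result is reproducible (pure minimum over a finite set)
  res2 <- exhaustive_search(sp, admissible_spec("A"), vc05)
  expect_identical(design_string(res2$best), design_string(res$best))
  expect_identical(res2$criterion_value, res$criterion_value)
})

test_that("a space with one identifiable design returns it with score zero", {
  # T = 3 start/end-constrained two-arm sequences are 001 and 011; with
  # C = 2 only the mixed multiset {001, 011} is identifiable
  cs <- constraint_set(start_at_control = TRUE, end_at_top = TRUE)
  sp <- design_space(3, 2, 5, D = 2, constraints = cs)
  expect_equal(space_size(sp), 3)  # pre-screening count
  res <- exhaustive_search(sp, admissible_spec("D", w = 0.5), vc05)
  expect_equal(res$n_evaluated, 1)
  expect_identical(design_string(res$best), "001011")
  expect_equal(res$admissibility_score, 0)
})

test_that("D, A and E searches coincide for two arms", {
  sp <- design_space(4, 5, 2, D = 2)
  strings <- sapply(c("D", "A", "E"), function(cr)
    design_string(exhaustive_search(sp, admissible_spec(cr), vc05)$best))
  expect_length(unique(strings), 1)
})

test_that("the power filter excludes underpowered designs", {
  sp <- design_space(3, 4, 4, D = 2)
  hyp <- hypothesis_spec(q = 1, alpha = 0.05, delta = 1, beta = 0.4)
  res <- exhaustive_search(sp, admissible_spec("D"), vc05, hyp = hyp)
  # recompute the returned design's power independently
  pw <- individual_power(compute_information(res$best, vc05), hyp)
  expect_gte(attr(pw, "min"), 1 - hyp$beta)
  expect_lte(res$n_admissible, res$n_evaluated)

  # an unattainable requirement errors, or relaxes with fallback = TRUE
  hyp_hard <- hypothesis_spec(q = 1, alpha = 0.05, delta = 0.01, beta = 0.01)
  expect_error(
    exhaustive_search(sp, admissible_spec("D"), vc05, hyp = hyp_hard),
    "no admissible design")
  res_fb <- exhaustive_search(sp, admissible_spec("D", w = 0.7), vc05,
                              hyp = hyp_hard, fallback = TRUE)
  res_w0 <- exhaustive_search(sp, admissible_spec("D", w = 0), vc05)
  expect_identical(design_string(res_fb$best), design_string(res_w0$best))
})

test_that("cross-entropy search is deterministic given the seed", {
  spec <- admissible_spec("A")
  s1 <- ce_search(4, 3, 2, 2, spec = spec, vc = vc05, seed = 11,
                  settings = ce_settings(n_pop = 300))
  s2 <- ce_search(4, 3, 2, 2, spec = spec, vc = vc05, seed = 11,
                  settings = ce_settings(n_pop = 300))
  expect_identical(design_string(s1$best), design_string(s2$best))
  expect_identical(s1$criterion_value, s2$criterion_value)
  expect_identical(s1$iterations, s2$iterations)
  expect_error(ce_search(4, 3, 2, 2, spec = spec, vc = vc05), "seed")
})

test_that("cross-entropy search attains the exhaustive optimum on a small space", {
  spec <- admissible_spec("D")
  opt <- exhaustive_search(design_space(3, 4, 2, D = 2), spec, vc05)
  res <- ce_search(4, 3, 2, 2, spec = spec, vc = vc05, seed = 5,
                   settings = ce_settings(n_pop = 300))
  expect_equal(res$criterion_value, opt$criterion_value, tolerance = 1e-10)
})

test_that("sensitivity ratios are >= 1 and exactly 1 where the probe is optimal", {
  grid <- expand.grid(sigma_c2 = c(0.01, 0.2), sigma_eps2 = c(0.5, 2))
  sp <- design_space(3, 5, 2, D = 2)
  # use the optimum at the first grid point as the probe
  vc1 <- variance_components(sigma_c2 = grid$sigma_c2[1],
                             sigma_eps2 = grid$sigma_eps2[1])
  probe <- exhaustive_search(sp, admissible_spec("D"), vc1)$best
  out <- sensitivity_map(probe, grid)
  expect_true(all(out$ratio >= 1 - 1e-12))
  expect_equal(out$ratio[1], 1, tolerance = 1e-12)
})
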