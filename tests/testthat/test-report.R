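vc05 <- vc_from_correlations(1, 0.05)
hyp2 <- hypothesis_spec(q = 2, alpha = 0.05, delta = c(1.5, 0.75), beta = 0.12)

test_that("comparison report annotates percent changes against the reference", {
  ds <- sohip_designs()
  rep1 <- report_designs(ds["sohip_proposed"], vc05, hyp2)
  raw <- attr(rep1, "raw")
  expect_equal(raw["cost", 1], 288)

  # reference versus itself: all percent changes are +-0%
  rep2 <- report_designs(ds[c("sohip_proposed", "sohip_proposed")], vc05, hyp2)
  expect_true(all(grepl("±0%", rep2[c("cost", "det", "maxDiag"), 2])))

  # optimized design: determinant drops by 67.7%, cost-efficient variant
  # (receives-all-arms, w = 0.5) saves 37.5% of observations
  rep3 <- report_designs(ds[c("sohip_proposed", "sohip_optimal_w0",
                              "allarms_d_optimal_w05")], vc05, hyp2)
  expect_match(rep3["det", 2], "-67.7%")
  expect_match(rep3["cost", 3], "-37.5%")

  # displayed percents agree with ones recomputed from the raw values
  raw3 <- attr(rep3, "raw")
  pct <- 100 * (raw3["det", 2] - raw3["det", 1]) / raw3["det", 1]
  expect_equal(round(pct, 1), -67.7)
})

test_that("config-driven evaluation reproduces the reference trial metrics", {
  cfg <- list(
    command = "evaluate",
    design = list(string = "000112000112001122001122011222011222",
                  m = 8, C = 6, T = 6, D = 3),
    variance = list(sigma2 = 1, rho = 0.05),
    hypothesis = list(alpha = 0.05, correction = "bonferroni",
                      delta = c(1.5, 0.75), beta = 0.12)
  )
  out <- run_from_config(cfg)
  expect_equal(out$cost, 288)
  expect_equal(out$maxDiag, 0.05696, tolerance = 1e-4)
  expect_equal(out$power$power[2], 0.8815, tolerance = 1e-4)
})

test_that("config validation catches malformed input", {
  cfg_bad <- list(
    command = "evaluate",
    design = list(string = "000112", m = 8, C = 6, T = 6, D = 3),
    variance = list(sigma2 = 1, rho = 0.05),
    hypothesis = list(alpha = 0.05, delta = c(1.5, 0.75), beta = 0.12)
  )
  expect_error(run_from_config(cfg_bad), "expected C\\*T = 36")

  cfg_nohyp <- list(
    command = "evaluate",
    design = list(string = "0011", m = 2, C = 2, T = 2),
    variance = list(sigma2 = 1, rho = 0.05),
    hypothesis = list(alpha = 0.05)
  )
  expect_error(run_from_config(cfg_nohyp), "delta")

  cfg_twoforms <- list(
    command = "power",
    design = list(string = "0011", m = 2, C = 2, T = 2),
    variance = list(sigma2 = 1, rho = 0.05, sigma_eps2 = 0.95),
    hypothesis = list(alpha = 0.05, delta = 0.5, beta = 0.2)
  )
  expect_error(run_from_config(cfg_twoforms), "exactly one")
})

test_that("seeded config runs write byte-identical reports", {
  cfg <- list(
    command = "search-ce",
    design = list(m = 2, C = 4, T = 3, D = 2),
    variance = list(sigma2 = 1, rho = 0.05),
    search = list(criterion = "A", seed = 7,
                  settings = list(n_pop = 200, max_iter = 30))
  )
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  cfg$output <- list(json = f1)
  r1 <- run_from_config(cfg)
  cfg$output <- list(json = f2)
  r2 <- run_from_config(cfg)
  j1 <- jsonlite::read_json(f1); j2 <- jsonlite::read_json(f2)
  j1$wall_time_s <- j2$wall_time_s <- NULL
  expect_identical(j1, j2)
  expect_identical(r1$best, r2$best)
})

test_that("the command-line front end evaluates a design and rejects bad input", {
  script <- system.file("cli", "masw.R", package = "maswdesign")
  skip_if(script == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  out_json <- tempfile(fileext = ".json")
  status <- system2(
    rscript,
    c(script, "evaluate",
      "--design", "000112000112001122001122011222011222",
      "--m", "8", "--C", "6", "--T", "6", "--D", "3",
      "--sigma2", "1", "--rho", "0.05",
      "--alpha", "0.05", "--delta", "1.5,0.75", "--beta", "0.12",
      "--out", out_json),
    env = paste0("R_LIBS=", libs),
    stdout = TRUE, stderr = TRUE
  )
  expect_true(file.exists(out_json))
  rec <- jsonlite::read_json(out_json)
  expect_equal(rec$cost, 288)

  # malformed design string: nonzero exit, message names the expected length
  err <- tempfile()
  status2 <- system2(
    rscript,
    c(script, "evaluate", "--design", "000112", "--m", "8", "--C", "6",
      "--T", "6", "--D", "3", "--sigma2", "1", "--rho", "0.05",
      "--alpha", "0.05", "--delta", "1.5,0.75", "--beta", "0.12"),
    env = paste0("R_LIBS=", libs),
    stdout = FALSE, stderr = err
  )
  expect_true(status2 != 0)
  expect_match(paste(readLines(err), collapse = " "), "expected C\\*T = 36")
})
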