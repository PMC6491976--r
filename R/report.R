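#' Side-by-side comparison table for named designs
#'
#' Evaluates each design under the same variance components and hypothesis
#' settings and tabulates per-hypothesis powers, cost `m*C*T` and the three
#' optimality criteria, with each non-reference column annotated by its
#' percent change versus the first (reference) design, rounded to one
#' decimal. The raw unrounded values are attached as attribute `"raw"`.
#'
#' @param designs named list of [masw_design()] objects; the first is the
#'   reference.
#' @param vc a [variance_components()] object.
#' @param hyp a [hypothesis_spec()].
#' @return data frame (class `masw_report`) with one formatted column per
#'   design and factor labels as row names; attribute `raw` holds the
#'   numeric matrix.
#' @export
report_designs <- function(designs, vc, hyp) {
  stopifnot(length(designs) >= 1L)
  if (is.null(names(designs)) || any(!nzchar(names(designs)))) {
    names(designs) <- paste0("design", seq_along(designs))
  }
  q <- hyp$q
  rows <- c("C", "T", "m", "X", paste0("P(reject H0", seq_len(q), ")"),
            "cost", "det", "trace/q", "maxDiag")
  raw <- matrix(NA_real_, length(rows), length(designs),
                dimnames = list(rows, names(designs)))
  strings <- character(length(designs))
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    info <- compute_information(d, vc)
    pw <- individual_power(info, hyp)
    strings[k] <- design_string(d)
    raw[, k] <- c(d$C, d$T, d$m, NA,
                  as.numeric(pw), design_cost(d),
                  det(info$Lambda_q), mean(diag(info$Lambda_q)),
                  max(diag(info$Lambda_q)))
  }
  fmt <- matrix("", length(rows), length(designs),
                dimnames = dimnames(raw))
  value_rows <- c(paste0("P(reject H0", seq_len(q), ")"),
                  "cost", "det", "trace/q", "maxDiag")
  for (k in seq_along(designs)) {
    fmt["C", k] <- as.character(raw["C", k])
    fmt["T", k] <- as.character(raw["T", k])
    fmt["m", k] <- as.character(raw["m", k])
    fmt["X", k] <- strings[k]
    for (rr in value_rows) {
      val <- signif(raw[rr, k], 4)
      base <- format(val, digits = 4)
      if (k == 1L) {
        fmt[rr, k] <- base
      } else {
        fmt[rr, k] <- paste0(base, " (",
                             format_percent(raw[rr, k], raw[rr, 1L]), ")")
      }
    }
  }
  out <- as.data.frame(fmt, stringsAsFactors = FALSE)
  attr(out, "raw") <- raw
  attr(out, "designs") <- strings
  class(out) <- c("masw_report", class(out))
  out
}

# percent change vs reference, one decimal; exact/rounded zero prints as +-0%
format_percent <- function(value, ref) {
  pct <- 100 * (value - ref) / ref
  if (round(pct, 1) == 0) "±0%" else sprintf("%+.1f%%", pct)
}

#' @export
print.masw_report <- function(x, ...) {
  print.data.frame(x, right = TRUE)
  invisible(x)
}

# ---- configuration-driven runs ---------------------------------------------

config_vc <- function(cfg) {
  v <- cfg$variance
  if (is.null(v)) stop("config must contain a 'variance' block")
  has_comp <- !is.null(v$sigma_eps2)
  has_cor <- !is.null(v$sigma2)
  if (has_comp && has_cor) stop("supply exactly one variance form, not both")
  if (has_comp) {
    variance_components(
      sigma_c2 = v$sigma_c2 %||% 0, sigma_theta2 = v$sigma_theta2 %||% 0,
      sigma_s2 = v$sigma_s2 %||% 0, sigma_eps2 = v$sigma_eps2)
  } else if (has_cor) {
    rho0 <- v$rho0 %||% v$rho
    if (is.null(rho0)) stop("variance block needs rho0 (or rho)")
    vc_from_correlations(v$sigma2, rho0, v$rho1 %||% rho0, v$rho2 %||% rho0)
  } else {
    stop("variance block must supply sigma_eps2 (components) or sigma2 (correlations)")
  }
}

config_design <- function(cfg) {
  d <- cfg$design
  if (is.null(d)) stop("config must contain a 'design' block")
  if (!is.null(d$file)) {
    read_design(d$file, m = d$m, D = d$D, C = d$C, T = d$T)
  } else if (!is.null(d$string)) {
    masw_design(d$string, m = d$m, D = d$D, C = d$C, T = d$T)
  } else {
    stop("design block needs 'string' or 'file'")
  }
}

# No hidden defaults: alpha, delta and beta must be explicit so a run's
# calibration is always visible in its config.
config_hyp <- function(cfg, q) {
  h <- cfg$hypothesis
  if (is.null(h)) stop("config must contain a 'hypothesis' block")
  for (nm in c("alpha", "delta", "beta")) {
    if (is.null(h[[nm]])) stop("hypothesis block must set '", nm, "' explicitly")
  }
  hypothesis_spec(q = h$q %||% q, alpha = h$alpha,
                  correction = h$correction %||% "bonferroni",
                  delta = as.numeric(h$delta), beta = h$beta,
                  power_type = h$power_type %||% "individual")
}

config_constraints <- function(blk) {
  if (is.null(blk)) return(constraint_set())
  do.call(constraint_set, blk[names(blk) %in% names(formals(constraint_set))])
}

config_space <- function(cfg) {
  s <- cfg$space
  if (is.null(s)) stop("config must contain a 'space' block")
  C_sets <- s$C_sets
  if (is.list(C_sets)) C_sets <- lapply(C_sets, unlist)
  M_sets <- s$M_sets
  if (is.list(M_sets)) M_sets <- lapply(M_sets, unlist)
  design_space(unlist(s$T_set), C_sets, M_sets, D = s$D,
               constraints = config_constraints(s$constraints))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_outputs <- function(result, cfg) {
  out <- cfg$output
  if (is.null(out)) return(invisible(result))
  if (!is.null(out$json)) {
    jsonlite::write_json(result, out$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  if (!is.null(out$csv) && is.data.frame(result$table)) {
    write.csv(result$table, out$csv, row.names = TRUE)
  }
  invisible(result)
}

#' Run a full workflow from a configuration
#'
#' Dispatches on `config$command`:
#' * `"evaluate"` — evaluate one design: criteria, cost and power report;
#' * `"power"` — power report only;
#' * `"search-exhaustive"` — [exhaustive_search()] over a `space` block;
#' * `"search-ce"` — [ce_search()] at fixed `C`, `T`, `m`;
#' * `"simulate"` — [empirical_power()] by Monte-Carlo.
#'
#' The configuration is a plain named list or a path to a YAML file with
#' blocks `design`, `variance` (components *or* correlation form, not
#' both), `hypothesis` (`alpha`, `delta`, `beta` are mandatory — no hidden
#' defaults), `space`, `search` and `output`. Results are returned and,
#' when `output$json`/`output$csv` are set, written to disk. The returned
#' record includes the package version, the seed and the wall time, so a
#' report can be regenerated bit-identically from its logged config.
#'
#' @param config named list or YAML file path.
#' @return list with the command's results (invisibly when written to
#'   disk).
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$command)) stop("config must contain 'command'")
  t0 <- proc.time()[["elapsed"]]
  vc <- config_vc(config)
  result <- switch(
    config$command,
    "evaluate" = {
      design <- config_design(config)
      hyp <- config_hyp(config, q = design$D - 1L)
      info <- compute_information(design, vc)
      list(
        command = "evaluate",
        design = design_string(design),
        m = design$m, C = design$C, T = design$T, D = design$D,
        cost = design_cost(design),
        det = det(info$Lambda_q),
        trace_over_q = mean(diag(info$Lambda_q)),
        maxDiag = max(diag(info$Lambda_q)),
        power = power_report(info, hyp)
      )
    },
    "power" = {
      design <- config_design(config)
      hyp <- config_hyp(config, q = design$D - 1L)
      c(list(command = "power", design = design_string(design)),
        power_report(compute_information(design, vc), hyp))
    },
    "search-exhaustive" = {
      space <- config_space(config)
      srch <- config$search %||% list()
      hyp <- if (!is.null(config$hypothesis)) config_hyp(config, q = space$D - 1L)
      spec <- admissible_spec(srch$criterion %||% "D", w = srch$w %||% 0)
      res <- exhaustive_search(space, spec, vc, hyp = hyp,
                               fallback = isTRUE(srch$fallback))
      list(command = "search-exhaustive",
           criterion = res$criterion, w = res$w,
           best = design_string(res$best),
           m = res$best$m, C = res$best$C, T = res$best$T,
           criterion_value = res$criterion_value, cost = res$cost,
           admissibility_score = res$admissibility_score,
           n_evaluated = res$n_evaluated, n_admissible = res$n_admissible,
           n_ties = length(res$ties),
           power = res$power_report)
    },
    "search-ce" = {
      srch <- config$search
      if (is.null(srch$seed)) stop("search block must set 'seed' for search-ce")
      d <- config$design
      hyp <- if (!is.null(config$hypothesis)) config_hyp(config, q = d$D - 1L)
      spec <- admissible_spec(srch$criterion %||% "D", w = 0)
      setts <- do.call(ce_settings, (srch$settings %||% list()))
      res <- ce_search(C = d$C, T = d$T, m = d$m, D = d$D,
                       constraints = config_constraints(config$space$constraints),
                       spec = spec, vc = vc, hyp = hyp,
                       seed = srch$seed, settings = setts)
      list(command = "search-ce", criterion = res$criterion,
           seed = srch$seed,
           best = design_string(res$best),
           criterion_value = res$criterion_value, cost = res$cost,
           iterations = res$iterations, converged = res$converged,
           n_evaluated = res$n_evaluated,
           power = res$power_report)
    },
    "simulate" = {
      design <- config_design(config)
      hyp <- config_hyp(config, q = design$D - 1L)
      s <- config$simulate
      if (is.null(s$n_sim) || is.null(s$seed)) {
        stop("simulate block must set 'n_sim' and 'seed'")
      }
      sim <- simulation_spec(n_sim = s$n_sim, seed = s$seed,
                             beta_true = s$beta_true %||% hyp$delta,
                             mu = s$mu %||% 0)
      c(list(command = "simulate", design = design_string(design)),
        empirical_power(design, vc, hyp, sim))
    },
    stop("unknown command '", config$command, "'")
  )
  result$package_version <- as.character(utils::packageVersion("maswdesign"))
  result$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
  write_outputs(result, config)
}
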