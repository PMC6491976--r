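#' Optimality criteria for the treatment-effect covariance
#'
#' Scalarizes the `q x q` treatment-effect covariance matrix:
#' * `"D"` — `det(Lambda_q)`, the volume of the confidence ellipsoid;
#' * `"A"` — `tr(Lambda_q) / q`, the average effect-estimator variance;
#' * `"E"` — `max(diag(Lambda_q))`, the most extreme variance.
#'
#' For `q = 1` the three criteria coincide (the single variance).
#'
#' @param Lambda_q symmetric positive-definite matrix (or a
#'   `masw_information` object, whose `Lambda_q` is used).
#' @param criterion `"D"`, `"A"` or `"E"`.
#' @return the criterion value (smaller is better).
#' @export
criterion_value <- function(Lambda_q, criterion = c("D", "A", "E")) {
  criterion <- match.arg(criterion)
  if (inherits(Lambda_q, "masw_information")) Lambda_q <- Lambda_q$Lambda_q
  if (!is.matrix(Lambda_q) || nrow(Lambda_q) != ncol(Lambda_q) ||
      max(abs(Lambda_q - t(Lambda_q))) > 1e-8 * max(1, max(abs(Lambda_q)))) {
    stop("Lambda_q must be a symmetric matrix")
  }
  ok <- tryCatch({ chol(Lambda_q); TRUE }, error = function(e) FALSE)
  if (!ok) stop("Lambda_q must be positive definite")
  switch(criterion,
         D = det(Lambda_q),
         A = mean(diag(Lambda_q)),
         E = max(diag(Lambda_q)))
}

#' Specification of the admissibility objective
#'
#' An admissible design minimizes the weighted sum of the range-rescaled
#' trial cost and the range-rescaled optimality criterion,
#' `w * rescale(cost) + (1 - w) * rescale(criterion)`, where
#' `rescale(x) = (x - min) / (max - min)` over the whole design space,
#' subject to an optional power requirement. Because many designs share the
#' same cost, `w = 1` usually yields massive ties and is flagged with a
#' warning.
#'
#' @param criterion `"D"`, `"A"` or `"E"`.
#' @param w cost weight in `[0, 1]`.
#' @param cost_fn cost function of a design; `NULL` (default) means the
#'   total number of observations `m * C * T`. Custom functions are called
#'   per design and slow large searches.
#' @param power_filter optional [hypothesis_spec()]; designs whose power
#'   (individual or combined per `power_type`) falls below `1 - beta` are
#'   excluded. `NULL` or `beta = 1` disables the filter.
#' @return Object of class `masw_admissible`.
#' @export
admissible_spec <- function(criterion = c("D", "A", "E"), w = 0,
                            cost_fn = NULL, power_filter = NULL) {
  criterion <- match.arg(criterion)
  if (!is.numeric(w) || w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (w == 1) warning("w = 1 ignores the optimality criterion entirely; ",
                      "expect large ties on cost")
  if (!is.null(power_filter)) stopifnot(inherits(power_filter, "masw_hypothesis"))
  structure(list(criterion = criterion, w = w, cost_fn = cost_fn,
                 power_filter = power_filter),
            class = "masw_admissible")
}

# Rescale to [0, 1] over the candidate set; a degenerate range (min = max)
# contributes 0 -- the rescaling is undefined there and any constant is
# rank-neutral.
rescale_term <- function(x) {
  rng <- range(x)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Admissibility scores for a list of designs
#'
#' Applies the weighted rescaled-cost/rescaled-criterion score to an
#' explicit list of designs (ranges taken over that list). With `w = 0` the
#' ranking is identical to the raw criterion ranking.
#'
#' @param designs list of [masw_design()] objects (all identifiable).
#' @param spec an [admissible_spec()].
#' @param vc a [variance_components()] object.
#' @return numeric vector of scores in `[0, 1]`; the minimizer is the
#'   admissible design.
#' @export
admissibility_scores <- function(designs, spec, vc) {
  if (length(designs) == 0L) stop("at least one design is required")
  crit <- vapply(designs, function(d) {
    criterion_value(compute_information(d, vc), spec$criterion)
  }, 0)
  cost <- vapply(designs, design_cost, 0, cost_fn = spec$cost_fn)
  spec$w * rescale_term(cost) + (1 - spec$w) * rescale_term(crit)
}

design_cost <- function(design, cost_fn = NULL) {
  if (is.null(cost_fn)) design$m * design$C * design$T else cost_fn(design)
}

# ---- vectorized stratum evaluation -----------------------------------------

# Evaluate every multiset (rows of idx, indices into seqs) in one (m, C, T)
# stratum: criterion value, diag(Lambda_q) and optionally combined power.
# Non-identifiable designs get NA. Chunked to bound memory.
evaluate_stratum <- function(seqs, idx, m, T, D, vc, criterion,
                             hyp = NULL, chunk = 65536L) {
  S <- nrow(seqs)
  p <- T + D - 1L
  q <- D - 1L
  qidx <- intervention_coords(T, D)
  Mflat <- sequence_information_blocks(seqs, m, T, D, vc)
  n <- nrow(idx)
  C <- ncol(idx)
  crit <- rep(NA_real_, n)
  powmin <- if (!is.null(hyp)) rep(NA_real_, n) else NULL
  powcomb <- if (!is.null(hyp) && hyp$power_type == "combined") rep(NA_real_, n) else NULL
  e <- if (!is.null(hyp)) critical_value(hyp$alpha, hyp$q, hyp$correction)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    counts <- matrix(0, length(rows), S)
    for (j in seq_len(C)) {
      ij <- cbind(seq_along(rows), idx[rows, j])
      counts[ij] <- counts[ij] + 1
    }
    Kflat <- counts %*% Mflat
    for (r in seq_along(rows)) {
      K <- matrix(Kflat[r, ], p, p)
      if (!information_nonsingular(K)) next
      ch <- tryCatch(chol(K), error = function(err) NULL)
      if (is.null(ch)) next
      Lambda <- chol2inv(ch)
      Lq <- Lambda[qidx, qidx, drop = FALSE]
      dq <- diag(Lq)
      if (any(dq <= 0)) next
      g <- rows[r]
      crit[g] <- switch(criterion, D = det(Lq), A = mean(dq), E = max(dq))
      if (!is.null(hyp)) {
        pw <- 1 - pnorm(e - hyp$delta * sqrt(1 / dq))
        powmin[g] <- min(pw)
        if (!is.null(powcomb)) {
          info <- structure(list(Lambda_q = Lq, info = 1 / dq),
                            class = "masw_information")
          powcomb[g] <- combined_power(info, hyp)
        }
      }
    }
  }
  list(crit = crit, powmin = powmin, powcomb = powcomb)
}

#' Exhaustive search for the admissible design
#'
#' Evaluates every design in a finite [design_space()] — caching each
#' distinct sequence's information contribution per `(m, T)` stratum so that
#' a design evaluation is a multiplicity-weighted sum of cached blocks plus
#' one small matrix inversion — and returns the design minimizing the
#' admissibility score of the supplied [admissible_spec()].
#'
#' The power requirement (when `hyp` has `beta < 1`) excludes designs whose
#' individual (or combined) power at `delta` falls below `1 - beta`.
#' Rescaling ranges are taken over all identifiable designs in the space. If
#' no design meets the power requirement, the search either signals an error
#' (`fallback = FALSE`) or, with `fallback = TRUE`, relaxes to `beta = 1`
#' and `w = 0` and simply minimizes the raw criterion.
#'
#' Ties (scores within relative `1e-12` of the minimum) are resolved to the
#' earliest design in the deterministic enumeration order (strata ordered by
#' `T`, `C`, `m`; canonical multisets in lexicographic order) and all tied
#' designs are reported. Results are independent of enumeration order up to
#' this tie rule.
#'
#' @param space a [design_space()].
#' @param spec an [admissible_spec()].
#' @param vc a [variance_components()] object.
#' @param hyp a [hypothesis_spec()] used for the power requirement and the
#'   power report; `NULL` for criterion-only searches.
#' @param fallback logical; relax to `beta = 1, w = 0` when no design meets
#'   the power requirement.
#' @return Object of class `masw_search_result`: `best` design, raw
#'   `criterion_value`, `cost`, `admissibility_score`, `power_report`
#'   (when `hyp` supplied), `n_evaluated` (identifiable designs),
#'   `n_admissible`, `ties`.
#' @examples
#' sp <- design_space(3, 4, 2, D = 2)
#' res <- exhaustive_search(sp, admissible_spec("D"), vc_from_correlations(1, 0.1))
#' res$best
#' @export
exhaustive_search <- function(space, spec, vc, hyp = NULL, fallback = FALSE) {
  stopifnot(inherits(space, "masw_space"), inherits(spec, "masw_admissible"),
            inherits(vc, "masw_vc"))
  if (is.null(hyp) && !is.null(spec$power_filter)) hyp <- spec$power_filter
  use_power <- !is.null(hyp) && hyp$beta < 1
  strata <- space_strata(space)
  if (!is.null(hyp) && any(strata$T + space$D - 1L < hyp$q)) {
    # q never varies with the stratum; this is just a sanity guard
  }
  per <- vector("list", nrow(strata))
  for (r in seq_len(nrow(strata))) {
    T <- strata$T[r]; C <- strata$C[r]; m <- strata$m[r]
    seqs <- enumerate_sequences(T, space$D, space$constraints)
    if (nrow(seqs) == 0L) next
    idx <- multiset_index_matrix(nrow(seqs), C)
    if (space$constraints$equal_allocation) {
      idx <- idx[apply(idx, 1L, is_equal_allocation), , drop = FALSE]
    }
    ev <- evaluate_stratum(seqs, idx, m, T, space$D, vc, spec$criterion,
                           hyp = if (use_power) hyp)
    cost <- if (is.null(spec$cost_fn)) {
      rep(m * C * T, nrow(idx))
    } else {
      vapply(seq_len(nrow(idx)), function(k) {
        spec$cost_fn(suppressWarnings(
          masw_design(seqs[idx[k, ], , drop = FALSE], m = m, D = space$D,
                      monotone = FALSE)))
      }, 0)
    }
    per[[r]] <- list(seqs = seqs, idx = idx, m = m, C = C, T = T,
                     crit = ev$crit, cost = cost,
                     pow = if (use_power) {
                       if (hyp$power_type == "combined") ev$powcomb else ev$powmin
                     })
  }
  per <- Filter(Negate(is.null), per)
  if (length(per) == 0L) stop("design space is empty")
  crit <- unlist(lapply(per, `[[`, "crit"))
  cost <- unlist(lapply(per, `[[`, "cost"))
  ok <- !is.na(crit)
  n_evaluated <- sum(ok)
  if (n_evaluated == 0L) stop("no identifiable design in the space")
  w <- spec$w
  admissible <- ok
  if (use_power) {
    pow <- unlist(lapply(per, `[[`, "pow"))
    admissible <- ok & !is.na(pow) & pow >= 1 - hyp$beta
    if (!any(admissible)) {
      if (!fallback) {
        stop("no admissible design: no design attains power ", 1 - hyp$beta,
             " (set fallback = TRUE to relax to beta = 1, w = 0)")
      }
      admissible <- ok
      w <- 0
    }
  }
  score <- rep(NA_real_, length(crit))
  score[ok] <- w * rescale_term(cost[ok]) + (1 - w) * rescale_term(crit[ok])
  sc <- score
  sc[!admissible] <- Inf
  best_idx <- which.min(sc)
  # ties at relative 1e-12 on the raw criterion and cost (the score itself
  # can be arbitrarily compressed by ill-conditioned designs in the range)
  tie_idx <- which(
    admissible &
      abs(crit - crit[best_idx]) <=
        1e-12 * max(abs(crit[best_idx]), 1e-300) &
      abs(cost - cost[best_idx]) <= 1e-12 * max(abs(cost[best_idx]), 1)
  )
  fetch <- function(g) {
    off <- 0L
    for (blk in per) {
      nblk <- length(blk$crit)
      if (g <= off + nblk) {
        k <- g - off
        return(suppressWarnings(masw_design(
          blk$seqs[blk$idx[k, ], , drop = FALSE],
          m = blk$m, D = space$D, monotone = FALSE)))
      }
      off <- off + nblk
    }
    stop("internal error: design index out of range")
  }
  best <- fetch(best_idx)
  res <- structure(
    list(
      best = best,
      criterion = spec$criterion,
      criterion_value = crit[best_idx],
      cost = cost[best_idx],
      admissibility_score = score[best_idx],
      w = w,
      n_designs = length(crit),
      n_evaluated = n_evaluated,
      n_admissible = sum(admissible),
      ties = lapply(tie_idx, fetch),
      power_report = if (!is.null(hyp)) {
        power_report(compute_information(best, vc), hyp)
      }
    ),
    class = "masw_search_result"
  )
  res
}

#' @export
print.masw_search_result <- function(x, ...) {
  cat(sprintf("%s-optimality search: %d designs evaluated (%d admissible)\n",
              x$criterion, x$n_evaluated, x$n_admissible))
  cat(sprintf("best criterion value = %.6g, cost = %g, score = %.6g%s\n",
              x$criterion_value, x$cost, x$admissibility_score,
              if (length(x$ties) > 1L) sprintf(" (%d ties)", length(x$ties)) else ""))
  print(x$best)
  if (!is.null(x$power_report)) {
    cat(sprintf("min individual power = %.4f, combined = %.4f\n",
                x$power_report$min_individual, x$power_report$combined))
  }
  invisible(x)
}

#' Settings for the cross-entropy search
#'
#' @param n_pop population size per iteration.
#' @param elite_frac fraction of the population retained as elite.
#' @param smoothing weight on the elite empirical frequencies in the
#'   probability update (`1` = no smoothing memory).
#' @param max_iter iteration cap.
#' @param patience stop once the elite criterion value has been unchanged
#'   for this many iterations.
#' @return list of settings.
#' @export
ce_settings <- function(n_pop = 1000L, elite_frac = 0.1, smoothing = 0.7,
                        max_iter = 100L, patience = 5L) {
  stopifnot(n_pop >= 10, elite_frac > 0, elite_frac <= 1,
            smoothing > 0, smoothing <= 1, max_iter >= 1, patience >= 1)
  list(n_pop = as.integer(n_pop), elite_frac = elite_frac,
       smoothing = smoothing, max_iter = as.integer(max_iter),
       patience = as.integer(patience))
}

#' Cross-entropy stochastic search over allocation matrices
#'
#' For fixed `C`, `T`, `m`, optimizes the raw D/A/E criterion (no
#' admissibility rescaling — minima and maxima over the space are unknown to
#' a stochastic search) over the constrained sequence set by the
#' cross-entropy method: each cluster carries a categorical distribution
#' over allowed sequences; each iteration samples `n_pop` allocation
#' matrices, keeps the elite fraction with the smallest criterion values and
#' updates the categorical probabilities toward the elite empirical
#' frequencies with smoothing. Iteration stops when the elite criterion
#' value has not improved for `patience` iterations or at `max_iter`. The
#' same `seed` yields a bit-identical result, and the returned design is the
#' best identifiable design observed anywhere in the sampling history.
#'
#' @param C,T,m,D design dimensions (fixed).
#' @param constraints a [constraint_set()]; row-level constraints restrict
#'   the sequence set (`equal_allocation` is not supported by the sampler).
#' @param spec an [admissible_spec()]; only its `criterion` and
#'   `power_filter` are used.
#' @param vc a [variance_components()] object.
#' @param hyp optional [hypothesis_spec()] for the power filter/report.
#' @param seed integer seed (mandatory — results are reproducible only with
#'   it).
#' @param settings a [ce_settings()] list.
#' @return `masw_search_result` (with `admissibility_score = NA`; the raw
#'   criterion was optimized). Additional fields: `iterations`,
#'   `converged`.
#' @export
ce_search <- function(C, T, m, D, constraints = constraint_set(), spec,
                      vc, hyp = NULL, seed, settings = ce_settings()) {
  stopifnot(inherits(spec, "masw_admissible"), inherits(vc, "masw_vc"))
  if (missing(seed)) stop("seed is mandatory for ce_search")
  if (constraints$equal_allocation) {
    stop("equal_allocation is not supported by the cross-entropy sampler")
  }
  if (is.null(hyp) && !is.null(spec$power_filter)) hyp <- spec$power_filter
  use_power <- !is.null(hyp) && hyp$beta < 1
  set.seed(as.integer(seed))
  seqs <- enumerate_sequences(T, D, constraints)
  S <- nrow(seqs)
  if (S == 0L) stop("constraints leave no allowed sequence")
  p <- T + D - 1L
  qidx <- intervention_coords(T, D)
  Mflat <- sequence_information_blocks(seqs, m, T, D, vc)
  e <- if (use_power) critical_value(hyp$alpha, hyp$q, hyp$correction)
  P <- matrix(1 / S, C, S)
  N <- settings$n_pop
  n_elite <- max(1L, ceiling(settings$elite_frac * N))
  best_val <- Inf
  best_idx <- NULL
  elite_history <- numeric(0)
  n_eval <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    idx <- matrix(0L, N, C)
    for (i in seq_len(C)) {
      idx[, i] <- sample.int(S, N, replace = TRUE, prob = P[i, ])
    }
    counts <- matrix(0, N, S)
    for (j in seq_len(C)) {
      ij <- cbind(seq_len(N), idx[, j])
      counts[ij] <- counts[ij] + 1
    }
    Kflat <- counts %*% Mflat
    val <- rep(Inf, N)
    for (r in seq_len(N)) {
      K <- matrix(Kflat[r, ], p, p)
      if (!information_nonsingular(K)) next
      ch <- tryCatch(chol(K), error = function(err) NULL)
      if (is.null(ch)) next
      Lq <- chol2inv(ch)[qidx, qidx, drop = FALSE]
      dq <- diag(Lq)
      if (any(dq <= 0)) next
      if (use_power) {
        pw <- 1 - pnorm(e - hyp$delta * sqrt(1 / dq))
        pok <- if (hyp$power_type == "combined") {
          info <- structure(list(Lambda_q = Lq, info = 1 / dq),
                            class = "masw_information")
          combined_power(info, hyp) >= 1 - hyp$beta
        } else {
          min(pw) >= 1 - hyp$beta
        }
        if (!pok) next
      }
      val[r] <- switch(spec$criterion, D = det(Lq), A = mean(dq), E = max(dq))
    }
    n_eval <- n_eval + N
    ord <- order(val)
    elite <- ord[seq_len(n_elite)]
    ebest <- val[elite[1L]]
    if (is.finite(ebest) && ebest < best_val - 0) {
      best_val <- ebest
      best_idx <- idx[elite[1L], ]
    }
    # categorical update toward elite frequencies, smoothed
    fin <- elite[is.finite(val[elite])]
    if (length(fin)) {
      for (i in seq_len(C)) {
        freq <- tabulate(idx[fin, i], nbins = S) / length(fin)
        P[i, ] <- settings$smoothing * freq + (1 - settings$smoothing) * P[i, ]
      }
    }
    elite_history <- c(elite_history, ebest)
    if (length(elite_history) > settings$patience) {
      recent <- tail(elite_history, settings$patience + 1L)
      if (all(is.finite(recent)) &&
          max(recent) - min(recent) <= 1e-12 * max(abs(recent), 1e-300)) {
        converged <- TRUE
        break
      }
    }
  }
  if (is.null(best_idx)) stop("cross-entropy search found no identifiable design")
  if (!converged) {
    warning("cross-entropy search stopped at max_iter without convergence; ",
            "returning best design found")
  }
  X <- seqs[sort(best_idx), , drop = FALSE]
  best <- suppressWarnings(masw_design(X, m = m, D = D, monotone = FALSE))
  structure(
    list(
      best = best,
      criterion = spec$criterion,
      criterion_value = best_val,
      cost = design_cost(best, spec$cost_fn),
      admissibility_score = NA_real_,
      w = NA_real_,
      n_designs = NA_real_,
      n_evaluated = n_eval,
      n_admissible = NA_integer_,
      ties = list(best),
      iterations = iter,
      converged = converged,
      power_report = if (!is.null(hyp)) {
        power_report(compute_information(best, vc), hyp)
      }
    ),
    class = "masw_search_result"
  )
}

#' Sensitivity of a candidate design across variance-parameter values
#'
#' For a two-arm cross-sectional reduction (`sigma_theta2 = sigma_s2 = 0`),
#' re-runs the criterion-only exhaustive search (`w = 0`, no power
#' requirement) at each `(sigma_c2, sigma_eps2)` grid point and reports the
#' ratio of the probe design's effect-estimator variance `Lambda_q[1,1]` to
#' the optimum's. The ratio is `>= 1` everywhere and equals 1 exactly where
#' the probe is optimal, so the map shows how much efficiency the probe
#' forfeits when the variance parameters are misspecified.
#'
#' @param probe a two-arm [masw_design()] whose `C`, `T`, `m` define the
#'   search space.
#' @param grid data frame with columns `sigma_c2` and `sigma_eps2`.
#' @param criterion `"D"`, `"A"` or `"E"` (equivalent for two arms).
#' @param constraints a [constraint_set()].
#' @return `grid` with columns `optimal_design` (digit string) and `ratio`
#'   appended.
#' @export
sensitivity_map <- function(probe, grid, criterion = "D",
                            constraints = constraint_set()) {
  stopifnot(inherits(probe, "masw_design"), probe$D == 2L,
            all(c("sigma_c2", "sigma_eps2") %in% names(grid)))
  space <- design_space(probe$T, probe$C, probe$m, D = 2L,
                        constraints = constraints)
  spec <- admissible_spec(criterion, w = 0)
  out <- grid
  out$optimal_design <- character(nrow(grid))
  out$ratio <- NA_real_
  for (r in seq_len(nrow(grid))) {
    vc <- variance_components(sigma_c2 = grid$sigma_c2[r],
                              sigma_eps2 = grid$sigma_eps2[r])
    res <- exhaustive_search(space, spec, vc)
    v_opt <- compute_information(res$best, vc)$Lambda_q[1L, 1L]
    v_probe <- compute_information(probe, vc)$Lambda_q[1L, 1L]
    out$optimal_design[r] <- design_string(res$best)
    out$ratio[r] <- v_probe / v_opt
  }
  out
}
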