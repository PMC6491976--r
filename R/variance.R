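#' Variance components of the linear mixed model
#'
#' The analysis model for response \eqn{k} in cluster \eqn{i}, period \eqn{j}
#' is
#' \deqn{y_{ijk} = \mu + \pi_j + \sum_d \beta_d 1\{X_{ij} \ge d\}
#'   + c_i + \theta_{ij} + s_{ik} + \varepsilon_{ijk},}
#' with independent normal random effects: cluster \eqn{c_i \sim N(0,
#' \sigma_c^2)}, cluster-period interaction \eqn{\theta_{ij} \sim N(0,
#' \sigma_\theta^2)}, subject \eqn{s_{ik} \sim N(0, \sigma_s^2)} (closed
#' cohort; zero for cross-sectional sampling) and residual
#' \eqn{\varepsilon_{ijk} \sim N(0, \sigma_\varepsilon^2)}. All components are
#' assumed known at the design stage; nothing in this package estimates them.
#'
#' The total variance is \eqn{\sigma^2 = \sigma_c^2 + \sigma_\theta^2 +
#' \sigma_s^2 + \sigma_\varepsilon^2} and the implied correlations are
#' * `rho0 = (sigma_c2 + sigma_theta2) / sigma2` — within-period correlation
#'   (two subjects, same cluster and period);
#' * `rho1 = sigma_c2 / sigma2` — interperiod correlation (two subjects, same
#'   cluster, different periods);
#' * `rho2 = (sigma_c2 + sigma_s2) / sigma2` — individual autocorrelation
#'   (same subject, different periods).
#'
#' @param sigma_c2,sigma_theta2,sigma_s2 nonnegative variances.
#' @param sigma_eps2 positive residual variance.
#' @return Object of class `masw_vc`: the four components plus the derived
#'   `sigma2`, `rho0`, `rho1`, `rho2`.
#' @examples
#' variance_components(sigma_c2 = 0.05, sigma_eps2 = 0.95)
#' @seealso [vc_from_correlations()] for the \eqn{(\sigma^2, \rho_0, \rho_1,
#'   \rho_2)} parameterization.
#' @export
variance_components <- function(sigma_c2 = 0, sigma_theta2 = 0, sigma_s2 = 0,
                                sigma_eps2) {
  for (nm in c("sigma_c2", "sigma_theta2", "sigma_s2", "sigma_eps2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(nm, " must be a single number")
    }
  }
  if (sigma_c2 < 0) stop("sigma_c2 >= 0 violated")
  if (sigma_theta2 < 0) stop("sigma_theta2 >= 0 violated")
  if (sigma_s2 < 0) stop("sigma_s2 >= 0 violated")
  if (sigma_eps2 <= 0) stop("sigma_eps2 > 0 violated")
  sigma2 <- sigma_c2 + sigma_theta2 + sigma_s2 + sigma_eps2
  structure(
    list(
      sigma_c2 = sigma_c2, sigma_theta2 = sigma_theta2,
      sigma_s2 = sigma_s2, sigma_eps2 = sigma_eps2,
      sigma2 = sigma2,
      rho0 = (sigma_c2 + sigma_theta2) / sigma2,
      rho1 = sigma_c2 / sigma2,
      rho2 = (sigma_c2 + sigma_s2) / sigma2
    ),
    class = "masw_vc"
  )
}

#' @export
print.masw_vc <- function(x, ...) {
  cat("Variance components (assumed known):\n")
  cat(sprintf("  cluster        sigma_c2     = %g\n", x$sigma_c2))
  cat(sprintf("  cluster-period sigma_theta2 = %g\n", x$sigma_theta2))
  cat(sprintf("  subject        sigma_s2     = %g\n", x$sigma_s2))
  cat(sprintf("  residual       sigma_eps2   = %g\n", x$sigma_eps2))
  cat(sprintf("  total sigma2 = %g; rho0 = %g, rho1 = %g, rho2 = %g\n",
              x$sigma2, x$rho0, x$rho1, x$rho2))
  invisible(x)
}

#' Variance components from total variance and correlations
#'
#' Inverts the defining equations of `rho0`, `rho1`, `rho2` (see
#' [variance_components()]):
#' \eqn{\sigma_c^2 = \rho_1 \sigma^2}, \eqn{\sigma_\theta^2 = (\rho_0 -
#' \rho_1)\sigma^2}, \eqn{\sigma_s^2 = (\rho_2 - \rho_1)\sigma^2},
#' \eqn{\sigma_\varepsilon^2 = (1 - \rho_0 - \rho_2 + \rho_1)\sigma^2}.
#' The map round-trips: the returned object carries the same
#' `(sigma2, rho0, rho1, rho2)`.
#'
#' The common single-`rho` specification of cross-sectional stepped-wedge
#' trials is `rho0 = rho1 = rho2 = rho` (so `sigma_theta2 = sigma_s2 = 0`).
#'
#' @param sigma2 positive total variance.
#' @param rho0,rho1,rho2 correlations in `[0, 1]`; must satisfy
#'   `rho1 <= rho0`, `rho1 <= rho2` and `1 - rho0 - rho2 + rho1 > 0`.
#' @return Object of class `masw_vc`.
#' @examples
#' vc_from_correlations(1, 0.05, 0.05, 0.05)  # single-rho cross-sectional
#' @export
vc_from_correlations <- function(sigma2, rho0, rho1 = rho0, rho2 = rho0) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop("sigma2 > 0 violated")
  for (nm in c("rho0", "rho1", "rho2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("0 <= ", nm, " <= 1 violated")
    }
  }
  if (rho1 > rho0) stop("rho1 <= rho0 violated")
  if (rho1 > rho2) stop("rho1 <= rho2 violated")
  if (1 - rho0 - rho2 + rho1 <= 0) {
    stop("1 - rho0 - rho2 + rho1 > 0 violated (residual variance ",
         "sigma_eps2 must be positive)")
  }
  variance_components(
    sigma_c2 = rho1 * sigma2,
    sigma_theta2 = (rho0 - rho1) * sigma2,
    sigma_s2 = (rho2 - rho1) * sigma2,
    sigma_eps2 = (1 - rho0 - rho2 + rho1) * sigma2
  )
}

#' Cluster mean correlation of a two-arm cross-sectional design
#'
#' Under the Hussey-Hughes reduction (`sigma_theta2 = sigma_s2 = 0`, so
#' `rho = rho0 = rho1 = rho2`), the efficiency of a two-arm stepped-wedge
#' design is indexed by the intracluster correlation of the cluster-period
#' means aggregated over the whole trial,
#' \deqn{E(\rho) = \frac{mT\rho}{1 + (mT - 1)\rho},}
#' which runs from 0 (independence) to 1 (perfect clustering) and is strictly
#' increasing in \eqn{\rho}.
#'
#' @param vc a `masw_vc` with `sigma_theta2 = sigma_s2 = 0`, or a single
#'   number taken directly as `rho`.
#' @param m,T per-cluster-period sample size and number of periods.
#' @return `E(rho)` in `[0, 1]`.
#' @seealso [icc_from_cluster_mean_correlation()] for the exact inverse.
#' @export
cluster_mean_correlation <- function(vc, m, T) {
  rho <- if (inherits(vc, "masw_vc")) {
    if (vc$sigma_theta2 != 0 || vc$sigma_s2 != 0) {
      stop("cluster mean correlation requires sigma_theta2 = sigma_s2 = 0")
    }
    vc$rho0
  } else {
    vc
  }
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  n <- m * T
  n * rho / (1 + (n - 1) * rho)
}

#' Intracluster correlation for a target cluster mean correlation
#'
#' Closed-form inverse of [cluster_mean_correlation()]:
#' \eqn{\rho = E / \{mT - (mT - 1)E\}}. Exact (no iteration), so the forward
#' map reproduces the target to machine precision.
#'
#' @param E_rho target cluster mean correlation in `[0, 1]`.
#' @param m,T per-cluster-period sample size and number of periods.
#' @return the intracluster correlation `rho`.
#' @examples
#' rho <- icc_from_cluster_mean_correlation(0.45, m = 10, T = 6)
#' cluster_mean_correlation(rho, m = 10, T = 6)  # 0.45
#' @export
icc_from_cluster_mean_correlation <- function(E_rho, m, T) {
  if (E_rho < 0 || E_rho > 1) stop("E_rho must lie in [0, 1]")
  n <- m * T
  E_rho / (n - (n - 1) * E_rho)
}
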