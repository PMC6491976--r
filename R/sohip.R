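#' Reference allocation matrices from the SO-HIP setting
#'
#' The SO-HIP study is a cross-sectional three-arm stepped-wedge trial of
#' sensor monitoring in an occupational therapy rehabilitation program for
#' older adults after hip fracture: arm 0 is care as usual, arm 1 adds
#' occupational therapy without sensor monitoring, and arm 2 adds coaching
#' informed by sensor monitoring, so each arm nests the previous one. The
#' planned design has `C = 6` clusters, `T = 6` periods and `m = 8`
#' observations per cluster-period, with effects of interest
#' `delta = (1.5, 0.75)` (in units of the total standard deviation), a
#' Bonferroni-corrected familywise `alpha = 0.05` and intracluster
#' correlation `rho = 0.05`.
#'
#' The bundled file also contains optimized alternatives for this setting —
#' the unrestricted and receives-all-arms optima at cost weights 0 and 0.5
#' — and a hypothetical four-arm extension (`T = 8`) with stochastically
#' optimized D/A/E alternatives.
#'
#' @return Named list of [masw_design()] objects.
#' @examples
#' d <- sohip_designs()$sohip_proposed
#' compute_information(d, vc_from_correlations(1, 0.05))
#' @export
sohip_designs <- function() {
  path <- system.file("extdata", "sohip_designs.csv", package = "maswdesign",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", rep("integer", 4), "character"))
  out <- lapply(seq_len(nrow(tab)), function(r) {
    masw_design(tab$X[r], m = tab$m[r], D = tab$D[r],
                C = tab$C[r], T = tab$T[r])
  })
  names(out) <- tab$name
  out
}
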