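# Fixture battery for the analytic-versus-empirical power cross-check:
# six designs spanning two to four arms, cross-sectional and cohort
# correlation structures, with effects sized to keep powers away from the
# 0/1 boundary. Seeds are fixed per design.
power_battery <- function() {
  list(
    list(design = masw_design("000001011111", m = 3, C = 4, T = 3),
         vc = vc_from_correlations(1, 0.1), delta = 0.7, seed = 101),
    list(design = masw_design("000001011111", m = 3, C = 4, T = 3),
         vc = vc_from_correlations(1, 0.1, 0.05, 0.3), delta = 0.7,
         seed = 102),
    list(design = masw_design("0012001201120122", m = 2, C = 4, T = 4),
         vc = vc_from_correlations(1, 0.05), delta = c(0.9, 0.7),
         seed = 107),
    list(design = masw_design("0012001201120122", m = 2, C = 4, T = 4),
         vc = vc_from_correlations(1, 0.08, 0.03, 0.25), delta = c(0.9, 0.7),
         seed = 104),
    list(design = masw_design("0000100013011230122301233", m = 2, C = 5,
                              T = 5, D = 4),
         vc = vc_from_correlations(1, 0.05), delta = c(1.0, 0.8, 0.8),
         seed = 105),
    list(design = masw_design("000100110111", m = 6, C = 3, T = 4),
         vc = vc_from_correlations(1, 0.15), delta = 0.5, seed = 106)
  )
}
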