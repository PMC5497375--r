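#' ddCt relative expression for qPCR data
#'
#' Classic delta-delta-Ct quantification: per condition the target
#' gene's Ct is normalised to the housekeeping reference
#' (`dCt = Ct_target - Ct_housekeeping`), the sample's dCt is referred
#' to the calibrator condition (`ddCt = dCt_sample - dCt_calibrator`),
#' and the relative expression is `2^(-ddCt)` (1 = no change,
#' 2 = doubled, 0.25 = quartered).  All arguments are vectorised.
#'
#' @param ct_target Ct of the target gene in the sample.
#' @param ct_housekeeping Ct of the housekeeping gene in the sample.
#' @param ct_target_calibrator Ct of the target gene in the calibrator
#'   (e.g. untreated control).
#' @param ct_housekeeping_calibrator Ct of the housekeeping gene in the
#'   calibrator.
#' @return Relative expression fold change(s), positive reals.
#' @export
ddct_relative_expression <- function(ct_target, ct_housekeeping,
                                     ct_target_calibrator,
                                     ct_housekeeping_calibrator) {
  args <- c(ct_target, ct_housekeeping, ct_target_calibrator,
            ct_housekeeping_calibrator)
  if (anyNA(args) || any(!is.finite(args))) {
    stop_pivotnet("Ct values must be finite")
  }
  dct_sample <- ct_target - ct_housekeeping
  dct_calibrator <- ct_target_calibrator - ct_housekeeping_calibrator
  2^(-(dct_sample - dct_calibrator))
}
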