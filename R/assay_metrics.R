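# Closed-form assay helpers kept apart from the proteomics pipeline:
# surface-receptor internalisation, autophagic flux from LC3-II staining,
# and delta-delta-Ct relative expression. All are vectorised.

#' Percent internalised receptor from surface MFI
#'
#' `100 - (mfi_sample / mfi_ice90) * 100`, where `mfi_ice90` is the mean
#' fluorescence intensity of the 90-minutes-on-ice control (no trafficking,
#' all label still at the surface).
#'
#' @param mfi_sample MFI of the chased sample (>= 0).
#' @param mfi_ice90 MFI of the ice control (> 0).
#' @return Percent internalised (100 when the surface signal is fully lost).
#' @export
percent_internalised <- function(mfi_sample, mfi_ice90) {
  if (any(mfi_ice90 <= 0)) stop("mfi_ice90 must be > 0", call. = FALSE)
  if (any(mfi_sample < 0)) stop("mfi_sample must be >= 0", call. = FALSE)
  100 - (mfi_sample / mfi_ice90) * 100
}

#' Autophagic flux from LC3-II staining
#'
#' `(mfi_bafa1 - mfi_vehicle) / mfi_vehicle`: the relative LC3-II accumulation
#' when lysosomal degradation is blocked. Negative flux is legal and returned
#' as-is.
#'
#' @param mfi_bafa1 LC3-II MFI under bafilomycin A1 (>= 0).
#' @param mfi_vehicle LC3-II MFI under vehicle (> 0).
#' @return Flux as a fraction of the vehicle signal.
#' @export
autophagic_flux <- function(mfi_bafa1, mfi_vehicle) {
  if (any(mfi_vehicle <= 0)) stop("mfi_vehicle must be > 0", call. = FALSE)
  if (any(mfi_bafa1 < 0)) stop("mfi_bafa1 must be >= 0", call. = FALSE)
  (mfi_bafa1 - mfi_vehicle) / mfi_vehicle
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)`;
#' returns the fold change `2^(-ddct)` of the target transcript relative to
#' the reference gene and the control condition.
#'
#' @param ct_target_test,ct_ref_test Ct of target/reference in the test
#'   sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target/reference in the control.
#' @return Fold change, 1 meaning no change.
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
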