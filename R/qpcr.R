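#' qPCR measurement record
#'
#' Threshold-cycle (Ct) measurements for a target assay and the single-copy
#' reference gene (ovotransferrin) in one sample. Replicate Ct values are
#' averaged before any ratio is formed.
#'
#' @param sample_id sample name.
#' @param ct_target Ct value(s) of the target amplicon, cycles.
#' @param ct_refgene Ct value(s) of the reference-gene amplicon, cycles.
#' @param assay_id assay (marker) identifier.
#' @return A `qpcr_record`.
#' @export
qpcr_record <- function(sample_id, ct_target, ct_refgene, assay_id = "assay") {
  if (any(!is.finite(ct_target)) || any(ct_target <= 0) ||
      any(!is.finite(ct_refgene)) || any(ct_refgene <= 0))
    stop_bad("Ct values must be positive and finite")
  structure(list(sample_id = sample_id, ct_target = as.numeric(ct_target),
                 ct_refgene = as.numeric(ct_refgene),
                 assay_id = assay_id), class = "qpcr_record")
}

#' Standard-curve parameters for Ct normalization
#'
#' Slopes of the standard-dilution regressions for the target (`S`) and the
#' reference gene (`S_ref`), with the reference-gene Ct summaries used to
#' put all samples on the same effective input amount.
#'
#' @param S slope of the target standard plot (cycles per log-dilution).
#' @param S_ref slope of the reference-gene standard plot (non-zero).
#' @param mean_ct_ref_all mean reference-gene Ct across all samples (N_t').
#' @param mean_ct_ref_sample mean reference-gene Ct in the sample (C_t').
#' @return A `standard_curve`.
#' @export
standard_curve <- function(S, S_ref, mean_ct_ref_all, mean_ct_ref_sample) {
  if (S_ref == 0) stop_bad("reference-gene standard slope must be non-zero")
  structure(list(S = S, S_ref = S_ref, mean_ct_ref_all = mean_ct_ref_all,
                 mean_ct_ref_sample = mean_ct_ref_sample),
            class = "standard_curve")
}

#' Input-amount-normalized Ct
#'
#' Corrects a target Ct for the amount of input DNA using the sample's
#' reference-gene Ct: `ct + (N_t' - C_t') * S / S'`, where `N_t'` is the
#' mean reference-gene Ct over all samples, `C_t'` the sample's mean
#' reference-gene Ct, and `S`, `S'` the standard-plot slopes of target and
#' reference gene. This interpolates on the standard plots to the Ct the
#' target would have shown had every sample contained the mean amount of
#' reference-gene DNA.
#'
#' @param ct target Ct value(s), cycles.
#' @param curve a [standard_curve()].
#' @return Normalized Ct value(s).
#' @examples
#' normalize_ct(25, standard_curve(1.1, 1, 20, 21))  # 23.9
#' @export
normalize_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$S == 0)
    warning("target standard slope is 0: Ct is insensitive to input amount",
            call. = FALSE)
  ct + (curve$mean_ct_ref_all - curve$mean_ct_ref_sample) * curve$S / curve$S_ref
}

#' Relative copy number by the delta-delta-Ct method
#'
#' Standard ddCt with perfect (base-2) amplification efficiency:
#' `ddCt = (Ct_target - Ct_refgene)_test - (Ct_target - Ct_refgene)_ref`,
#' ratio `2^(-ddCt)` relative to the calibrator sample, and estimated copies
#' `2 * ratio` against the diploid calibrator (rounded to the nearest
#' integer; the unrounded value is retained).
#'
#' @param test a [qpcr_record()] for the test sample.
#' @param reference a [qpcr_record()] for the calibrator sample (same assay).
#' @return A `copy_ratio` list: `ddct`, `ratio`, `copies_unrounded`,
#'   `copies`.
#' @export
relative_copy_ratio <- function(test, reference) {
  stopifnot(inherits(test, "qpcr_record"), inherits(reference, "qpcr_record"))
  if (!identical(test$assay_id, reference$assay_id))
    stop_bad("test and reference records come from different assays (%s vs %s)",
             test$assay_id, reference$assay_id)
  dct_test <- mean(test$ct_target) - mean(test$ct_refgene)
  dct_ref <- mean(reference$ct_target) - mean(reference$ct_refgene)
  ddct <- dct_test - dct_ref
  ratio <- 2^(-ddct)
  structure(list(ddct = ddct, ratio = ratio,
                 copies_unrounded = 2 * ratio,
                 copies = as.integer(round(2 * ratio))),
            class = "copy_ratio")
}

#' @export
print.copy_ratio <- function(x, ...) {
  cat(sprintf("ddCt %.3f -> ratio %.3f vs calibrator (~%d copies, unrounded %.2f)\n",
              x$ddct, x$ratio, x$copies, x$copies_unrounded))
  invisible(x)
}

#' Concordance of qPCR copy number with an aCGH call
#'
#' A "gain" call is concordant with more than 2 qPCR copies, a "loss" with
#' fewer than 2, and "none" with exactly 2.
#'
#' @param copies integer qPCR copy estimate(s), >= 0.
#' @param called_class character: "gain", "loss" or "none".
#' @return Character vector "concordant"/"discordant".
#' @export
classify_concordance <- function(copies, called_class) {
  if (any(copies < 0)) stop_bad("copies must be >= 0")
  stopifnot(all(called_class %in% c("gain", "loss", "none")))
  ok <- (called_class == "gain" & copies > 2) |
        (called_class == "loss" & copies < 2) |
        (called_class == "none" & copies == 2)
  ifelse(ok, "concordant", "discordant")
}
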