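# 8-to-12 lead derivation (Einthoven / Goldberger identities).

#' Derive the 12-lead frame from 8 acquired leads
#'
#' The acquisition front end measures leads I, II and the precordial leads
#' V1--V6; the remaining four limb leads are linear combinations:
#' `III = II - I`, `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`.
#' Acquired leads are passed through unchanged.
#'
#' @param leads8 an 8 x n numeric matrix with rows in the order
#'   I, II, V1, V2, V3, V4, V5, V6, or an `ecg_stream`.
#' @return a 12 x n matrix with rows I, II, III, aVR, aVL, aVF, V1--V6.
#' @export
derive_leads <- function(leads8) {
  if (inherits(leads8, "ecg_stream")) leads8 <- leads8$leads8
  if (!is.matrix(leads8) || nrow(leads8) != 8)
    stopf("leads8 must be an 8-row matrix (I, II, V1-V6)")
  I <- leads8[1, ]; II <- leads8[2, ]
  out <- rbind(I = I, II = II,
               III = II - I,
               aVR = -(I + II) / 2,
               aVL = I - II / 2,
               aVF = II - I / 2,
               leads8[3:8, , drop = FALSE])
  rownames(out) <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")
  out
}
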