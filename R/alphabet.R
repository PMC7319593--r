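# Residue alphabets and fixed orderings shared by the encoders.
#
# Two orderings coexist on purpose:
#  * `acr_pssm_columns()` is the column order of a PSI-BLAST ASCII PSSM
#    (A R N D C Q E G H I L K M F P S T W Y V); every PSSM-derived
#    descriptor indexes columns in this order so that a parsed matrix is
#    consumed without reshuffling.
#  * `acr_residues()` is plain alphabetical order, used by the sequence
#    composition baselines (AAC, DPC).
# Both orders are part of the model format: feature vectors are only
# comparable between runs if the orderings never change.

#' Standard amino-acid alphabets
#'
#' `acr_residues()` returns the 20 standard amino-acid one-letter codes in
#' alphabetical order (used by the AAC and DPC sequence descriptors);
#' `acr_pssm_columns()` returns them in PSI-BLAST PSSM column order (used by
#' all PSSM-derived descriptors).
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
#' @examples
#' acr_residues()
#' acr_pssm_columns()
acr_residues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname acr_residues
#' @export
acr_pssm_columns <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Physicochemical residue groups of the reduced (L x 10) PSSM, in the fixed
# group order: FYW, ML, IV, ATS, NH, QED, RK, C, G, P.
rpssm_groups <- function() {
  list(
    c("F", "Y", "W"),
    c("M", "L"),
    c("I", "V"),
    c("A", "T", "S"),
    c("N", "H"),
    c("Q", "E", "D"),
    c("R", "K"),
    "C",
    "G",
    "P"
  )
}

#' Encoder tags
#'
#' `acr_encoders()` lists all six descriptor tags; `acr_evolutionary_encoders()`
#' lists the four PSSM-derived descriptors used by the ensemble model.
#'
#' @return Character vector of encoder tags.
#' @export
acr_encoders <- function() c("AAC", "DPC", "PSSM_COMP", "DPC_PSSM", "PSSM_AC", "RPSSM")

#' @rdname acr_encoders
#' @export
acr_evolutionary_encoders <- function() c("PSSM_COMP", "DPC_PSSM", "PSSM_AC", "RPSSM")

encoder_dimension <- function(encoder, lag = 10L) {
  switch(encoder,
    AAC = 20L,
    DPC = 400L,
    PSSM_COMP = 400L,
    DPC_PSSM = 400L,
    PSSM_AC = 20L * as.integer(lag),
    RPSSM = 110L,
    abort(paste0("unknown encoder tag: ", encoder), class = "acr_input_error")
  )
}
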