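#' Canonical length of the human integrin alpha-V precursor
#'
#' Residue count of the primary translation product of ITGAV (UniProt
#' P06756, signal peptide included). Recorded as a constant so resolution
#' arithmetic works without a network lookup.
#' @export
ITGAV_PROTEIN_LENGTH <- 1048L

#' Tiling-scan resolution in amino acids per guide
#'
#' The average spacing of a tiling library over its target protein:
#' \code{protein_length / n_guides}, optionally rounded.
#'
#' @param protein_length residues of the primary translation product.
#' @param n_guides number of coding-targeting sgRNAs in the library.
#' @param digits rounding (default 1).
#' @return amino acids per sgRNA.
#' @export
tiling_resolution <- function(protein_length, n_guides, digits = 1) {
  if (n_guides <= 0) stop_("n_guides must be positive")
  round(protein_length / n_guides, digits)
}
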