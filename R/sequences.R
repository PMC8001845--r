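# The fixed synthetic sequence world. Real coral FP sequences are ~230 aa
# with a chromophore tripeptide at a conserved alignment position; the
# packaged panel/reference sequences are synthetic stand-ins derived from
# three archetypes (one per color class) so that class membership is an
# ancient, phylogenetically recoverable signal, as it is in real corals:
# GFP/CFP and ChrP archetypes carry QYG, the RFP archetype carries DYG.
# Archetypes were drawn once from a uniform residue model (~25% pairwise
# divergence) and are frozen here; they are fixtures, not data.

FP_LEN <- 230L
CHROMOPHORE_COLS <- 63:65

FP_ARCHETYPES <- c(
  `GFP/CFP` = paste0(
    "YYNLFCRWDKFSQSFFEWVGTVKQCCKLPEELPNQSILRRWPMDLYYWMKDQPPQETESKTW",
    "QYG",
    "QDQCRTYFAVITIGRTYFWYFEFFTAVKYYDQGRDTSWTQAASLQMVWYIWKLNWECQAAFHCPFNRAMTWLNQGGQFNIMRNATRIIFVMGECACRMFSYRKRQRFDHGLPHRDKHRIFVHQLYHMHSHQIACCSTFLYGMVMVLWMECGVLVTGQGCCQNEAF"),
  RFP = paste0(
    "AYNLHCRWDQFSQSFIIWCGTGKQCTKLPIELPKQSILRRWPMDLYYWMKDQPRQENESKTW",
    "DYG",
    "QDQCRFYFAKITIECAKGWCFEFETADYYYDTGRDTSWFQAASLQMVWAFWKLNWECCAECHHKFNRAMTFLAQDGFFWIMENITRGIFVMGECARRMLSYRIIQRMEWGVPHRDKHRIFVHQLYHMHSHQIDCCSTRLYGMQCVLWMHCIVLVTFQGCCPNETF"),
  ChrP = paste0(
    "YYNLFFRWDTFSQSFFEPTGTVKQCCKLPQELPNQSILRRWMMDYAYWMKDLPPQETEWKAW",
    "QYG",
    "QYQCRFYFAVNTIRRIYFPYEEFFTAVFYYDQKSDYSWQQAASLQCVNYRQKLNWHCQAAQHCPFNSAMTWWNQGVLFNKMRNAMRIIFVYGECACRMFAYRKRQRFHHGLPHQDKHNIVVHQICHMHSHWISQQSTFDYGMVMWLTSNDGVPVTGQGCGQNWRF")
)

#' Class archetype protein sequences of the synthetic FP world
#'
#' Three frozen 230-residue synthetic proteins, one per color class, from
#' which all packaged panel/reference sequences and all simulated gene
#' families descend. The chromophore tripeptide occupies residues 63-65
#' (QYG for GFP/CFP and ChrP, DYG for RFP).
#'
#' @return named character vector with entries `GFP/CFP`, `RFP`, `ChrP`
#' @export
fp_archetypes <- function() FP_ARCHETYPES

#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment score under a substitution matrix. A gap of
#' length k costs `gap_open + k * gap_ext` (the BLAST 11/1 convention
#' with the defaults).
#'
#' @param a,b protein sequences (plain strings)
#' @param submat substitution matrix with residue dimnames (default BLOSUM62)
#' @param gap_open,gap_ext gap opening / per-position extension penalties
#' @return numeric alignment score (0 if no positive-scoring alignment)
#' @export
sw_score <- function(a, b, submat = blosum62(), gap_open = 11, gap_ext = 1) {
  .sw_score(a, b, submat, gap_open, gap_ext)
}

#' Global pairwise alignment with traceback
#'
#' Needleman-Wunsch affine-gap global alignment; end gaps are penalized.
#'
#' @inheritParams sw_score
#' @return list with gapped strings `a`, `b` and the `score`
#' @export
nw_align <- function(a, b, submat = blosum62(), gap_open = 11, gap_ext = 1) {
  .nw_align(a, b, submat, gap_open, gap_ext)
}
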