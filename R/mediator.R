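#' Default homology alignments for the Mediator middle module
#'
#' The structure-prediction alignments used to thread middle-module
#' subunits onto their templates, given as contiguous query/template
#' residue ranges: Med4 46-127 onto Med7 (PDB 1YKH chain A) 19-108,
#' Med9 84-149 onto Med21 (1YKH chain B) 56-118, and Med10 3-91 onto
#' Med8 (4H63 chain H) 1-111. The underlying alignments are gapped; the
#' ranges here pair positions from the range starts (see
#' [alignmentFromRanges()]), so they are a starting point to be replaced
#' by full pair lists when available.
#'
#' @return named list of [AlignmentMap-class] objects (`Med4`, `Med9`,
#'   `Med10`).
#' @export
medTable1Alignments <- function() {
  list(
    Med4 = alignmentFromRanges("Med4", "A", "46-127:19-108"),
    Med9 = alignmentFromRanges("Med9", "B", "84-149:56-118"),
    Med10 = alignmentFromRanges("Med10", "H", "3-91:1-111"))
}
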