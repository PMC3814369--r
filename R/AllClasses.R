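#' @import methods
NULL

#' Cross-linker chemistry specification
#'
#' Describes an amine-reactive, isotope-coded cross-linker: its spacer
#' length, the per-residue side-chain allowance used to derive the
#' C-alpha satisfaction cutoff, the monoisotopic mass its intact bridge
#' adds to a pair of peptides, and the light/heavy isotope mass delta.
#'
#' @slot name linker name.
#' @slot spacerLength spacer arm length in Angstrom.
#' @slot sidechainAllowance side-chain allowance in Angstrom per linked
#'   residue (6 for lysine).
#' @slot bridgeMassLight monoisotopic mass (Da) added to the summed
#'   peptide masses by the intact light-form bridge. May be `NA` until the
#'   user supplies it; mass computations then refuse to run.
#' @slot heavyLightDelta mass difference (Da) between the heavy and light
#'   isotopic forms.
#' @slot reactiveTargets one-letter codes of reactive residues.
#' @slot ntermReactive whether the protein N-terminus is reactive.
#' @export
setClass("LinkerSpec",
  representation(
    name = "character",
    spacerLength = "numeric",
    sidechainAllowance = "numeric",
    bridgeMassLight = "numeric",
    heavyLightDelta = "numeric",
    reactiveTargets = "character",
    ntermReactive = "logical"
  )
)

setValidity("LinkerSpec", function(object) {
  msg <- character()
  if (length(object@spacerLength) != 1L || object@spacerLength < 0)
    msg <- c(msg, "spacerLength must be a single non-negative number")
  if (length(object@sidechainAllowance) != 1L || object@sidechainAllowance < 0)
    msg <- c(msg, "sidechainAllowance must be a single non-negative number")
  if (length(object@heavyLightDelta) != 1L ||
      (!is.na(object@heavyLightDelta) && object@heavyLightDelta < 0))
    msg <- c(msg, "heavyLightDelta must be non-negative")
  if (length(object@bridgeMassLight) != 1L)
    msg <- c(msg, "bridgeMassLight must be a single number (possibly NA)")
  if (length(msg)) msg else TRUE
})

#' Single-chain backbone coordinate model
#'
#' Residue-indexed backbone coordinates (N, CA, C, O; CA mandatory) for
#' one polypeptide chain, with optional per-residue provenance recording
#' where each residue's coordinates came from (source structure or
#' threading template).
#'
#' @slot chainId chain identifier.
#' @slot atoms data.frame with columns `resno`, `code` (one-letter
#'   residue code), `elety` (atom name, one of N/CA/C/O), `x`, `y`, `z`.
#' @slot provenance data.frame with columns `resno`, `source`; one row
#'   per residue.
#' @export
setClass("ChainModel",
  representation(
    chainId = "character",
    atoms = "data.frame",
    provenance = "data.frame"
  )
)

setValidity("ChainModel", function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("resno", "code", "elety", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(sprintf("atoms must have columns %s", paste(need, collapse = ", ")))
  if (length(object@chainId) != 1L || is.na(object@chainId) ||
      !nzchar(object@chainId))
    msg <- c(msg, "chainId must be a single non-empty string")
  if (nrow(a)) {
    if (!all(a$elety %in% c("N", "CA", "C", "O")))
      msg <- c(msg, "atom names must be one of N, CA, C, O")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    resno <- unique(a$resno)
    if (is.unsorted(resno, strictly = TRUE))
      msg <- c(msg, "residue numbers must be strictly increasing")
    ca <- a$resno[a$elety == "CA"]
    if (anyDuplicated(ca) || !setequal(ca, resno))
      msg <- c(msg, "every residue must have exactly one CA atom")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-chain assembly model
#'
#' A placed multi-chain complex: a list of [ChainModel] objects with
#' unique chain ids plus free-form metadata (applied transforms, mapping
#' choices, interface metrics).
#'
#' @slot chains list of `ChainModel`.
#' @slot metadata named list.
#' @export
setClass("AssemblyModel",
  representation(chains = "list", metadata = "list")
)

setValidity("AssemblyModel", function(object) {
  if (!all(vapply(object@chains, is, logical(1), class2 = "ChainModel")))
    return("all chains must be ChainModel objects")
  ids <- vapply(object@chains, function(ch) ch@chainId, character(1))
  if (anyDuplicated(ids))
    return(sprintf("duplicated chain id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' Rigid-body transform
#'
#' A proper rotation plus translation, applied to coordinates as
#' `x' = R x + t`. Pairwise distances are preserved.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
    return("rotation must be a 3x3 numeric matrix")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (to 1e-8)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (determinant +1 to 1e-8)")
  TRUE
})

#' Set of lysine-lysine cross-link pairs
#'
#' One row per linkage between two subunit sites. Pair identity is
#' unordered; rows are stored with the two sites in canonical order
#' (lexicographic by subunit name, then residue). `link_class` is
#' `intra` exactly when the two subunits are the same.
#'
#' @slot links data.frame with columns `subunit_a`, `residue_a`,
#'   `subunit_b`, `residue_b`, `spectral_count`, `link_class`.
#' @export
setClass("CrossLinkSet", representation(links = "data.frame"))

setValidity("CrossLinkSet", function(object) {
  df <- object@links
  need <- c("subunit_a", "residue_a", "subunit_b", "residue_b",
            "spectral_count", "link_class")
  if (!all(need %in% names(df)))
    return(sprintf("links must have columns %s", paste(need, collapse = ", ")))
  if (!nrow(df)) return(TRUE)
  msg <- character()
  if (!all(df$spectral_count >= 1))
    msg <- c(msg, "spectral_count must be >= 1")
  intra <- df$subunit_a == df$subunit_b
  if (!all(df$link_class == ifelse(intra, "intra", "inter")))
    msg <- c(msg, "link_class must be intra exactly when subunits are equal")
  if (length(msg)) msg else TRUE
})

#' Residue-residue alignment between a query and a template chain
#'
#' An ordered, strictly co-linear list of aligned residue pairs (both
#' 1-based), the anchor for superposition and backbone threading.
#'
#' @slot query query subunit name.
#' @slot templateChain template chain identifier.
#' @slot pairs two-column integer matrix (`query`, `template`), both
#'   columns strictly increasing.
#' @export
setClass("AlignmentMap",
  representation(query = "character", templateChain = "character",
                 pairs = "matrix")
)

setValidity("AlignmentMap", function(object) {
  p <- object@pairs
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("pairs must be a non-empty two-column matrix")
  if (is.unsorted(p[, 1L], strictly = TRUE) ||
      is.unsorted(p[, 2L], strictly = TRUE))
    return("alignment columns must both be strictly increasing (no crossings)")
  TRUE
})

#' One candidate architecture of a complex
#'
#' A fully built [AssemblyModel] for one enumerated mapping choice
#' (which template chain each modeled chain was superposed on), together
#' with its cross-link satisfaction tallies once scored.
#'
#' @slot id hypothesis identifier.
#' @slot mappingChoice named character vector, component -> template chain.
#' @slot model the assembled model.
#' @slot score named numeric vector (satisfied, violated, unmappable);
#'   `NA` until scored.
#' @export
setClass("ArchitectureHypothesis",
  representation(id = "character", mappingChoice = "character",
                 model = "AssemblyModel", score = "numeric")
)

#' Coverage and cross-link satisfaction report
#'
#' Modeled-residue counts, cross-link tallies and model extent for an
#' assembled architectural model.
#'
#' @slot totalResidues total residues in the supplied subunit sequences.
#' @slot modeledResidues residues with a modeled CA.
#' @slot percentModeled `round(100 * modeled / total)`.
#' @slot crystalCoveredResidues residues covered by crystal structures
#'   alone (`NA` when not supplied).
#' @slot percentCrystal corresponding percentage (`NA` when not supplied).
#' @slot pairsTotal,pairsMapped,pairsSatisfied,pairsViolated,intraCount,interCount
#'   cross-link tallies.
#' @slot modelExtent maximum pairwise CA-CA distance (Angstrom).
#' @export
setClass("CoverageReport",
  representation(
    totalResidues = "integer", modeledResidues = "integer",
    percentModeled = "numeric",
    crystalCoveredResidues = "integer", percentCrystal = "numeric",
    pairsTotal = "integer", pairsMapped = "integer",
    pairsSatisfied = "integer", pairsViolated = "integer",
    intraCount = "integer", interCount = "integer",
    modelExtent = "numeric"
  )
)

setValidity("CoverageReport", function(object) {
  msg <- character()
  if (!is.na(object@modeledResidues) && !is.na(object@totalResidues) &&
      (object@modeledResidues < 0 ||
       object@modeledResidues > object@totalResidues))
    msg <- c(msg, "modeledResidues must lie in [0, totalResidues]")
  p <- c(object@percentModeled, object@percentCrystal)
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 0) || any(p > 100)))
    msg <- c(msg, "percentages must lie in [0, 100]")
  if (!is.na(object@pairsTotal) &&
      object@intraCount + object@interCount != object@pairsTotal)
    msg <- c(msg, "intraCount + interCount must equal pairsTotal")
  if (!is.na(object@pairsMapped) &&
      object@pairsSatisfied + object@pairsViolated != object@pairsMapped)
    msg <- c(msg, "pairsSatisfied + pairsViolated must equal pairsMapped")
  if (length(msg)) msg else TRUE
})
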