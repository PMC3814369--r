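#' Percentage of residues covered, rounded to the nearest integer
#'
#' @param modeled modeled residue count.
#' @param total total residue count.
#' @return `round(100 * modeled / total)`; 0 when `total` is 0.
#' @examples
#' coveragePercent(361, 1075)  # 34
#' coveragePercent(744, 1075)  # 69
#' @export
coveragePercent <- function(modeled, total) {
  if (total == 0) return(0)
  round(100 * modeled / total)
}

#' Residue coverage of a model
#'
#' Counts, per subunit and in total, how many full-length residues have a
#' modeled CA. When a subunit is present in several chain copies, each
#' full-length residue is counted once.
#'
#' @param model an [AssemblyModel-class].
#' @param sequences `AAStringSet` or named character vector of full-length
#'   subunit sequences.
#' @param chainMap named character vector or list, chain id -> subunit
#'   name; `NULL` means chain ids equal subunit names. A model chain that
#'   resolves to no sequence is an error.
#' @param offsets named integer vector by chain id (full-length residue =
#'   model residue + offset).
#' @return list with `modeled`, `total`, `percent`, and `perSubunit`
#'   (data.frame `subunit`, `modeled`, `length`).
#' @export
coverage <- function(model, sequences, chainMap = NULL, offsets = NULL) {
  lens <- sequenceLengths(sequences)
  mapTo <- function(chain) {
    if (is.null(chainMap)) return(chain)
    if (!chain %in% names(chainMap))
      stop(sprintf("model chain '%s' is absent from the chain map", chain))
    as.character(chainMap[[chain]])
  }
  seen <- new.env()
  for (ch in model@chains) {
    su <- mapTo(ch@chainId)
    if (!su %in% names(lens))
      stop(sprintf("no sequence supplied for subunit '%s' (model chain '%s')",
                   su, ch@chainId))
    off <- if (!is.null(offsets) && ch@chainId %in% names(offsets))
      offsets[[ch@chainId]] else 0L
    res <- residueNumbers(ch) + off
    prev <- if (!is.null(seen[[su]])) seen[[su]] else integer(0)
    seen[[su]] <- union(prev, res)
  }
  perSubunit <- data.frame(
    subunit = names(lens),
    modeled = vapply(names(lens), function(su)
      length(if (!is.null(seen[[su]])) seen[[su]] else integer(0)),
      integer(1)),
    length = unname(lens), stringsAsFactors = FALSE)
  rownames(perSubunit) <- NULL
  modeled <- sum(perSubunit$modeled)
  total <- sum(perSubunit$length)
  list(modeled = modeled, total = total,
       percent = coveragePercent(modeled, total), perSubunit = perSubunit)
}

#' Maximum extent of a model
#'
#' The maximum pairwise CA-CA distance over all chains — the model-span
#' statistic used to describe how extended an architecture is. Invariant
#' under rigid transforms and chain permutation.
#'
#' @param model an [AssemblyModel-class] with at least two CA atoms.
#' @return extent in Angstrom.
#' @export
modelExtent <- function(model) {
  ca <- caCoords(model)
  if (nrow(ca) < 2L) stop("model extent needs at least two CA atoms")
  max(stats::dist(ca))
}

#' Build a coverage and cross-link satisfaction report
#'
#' @param mapped data.frame from [mapCrossLinks()].
#' @param coverage coverage fragment from [coverage()] (optional).
#' @param crystalCoverage like `coverage`, computed against
#'   crystal-structure models only (optional).
#' @param extent model extent in Angstrom (optional; see [modelExtent()]).
#' @return a [CoverageReport-class].
#' @export
summarizeMapping <- function(mapped, coverage = NULL,
                             crystalCoverage = NULL, extent = NA_real_) {
  s <- mappingTallies(mapped)
  new("CoverageReport",
      totalResidues = if (is.null(coverage)) NA_integer_
        else as.integer(coverage$total),
      modeledResidues = if (is.null(coverage)) NA_integer_
        else as.integer(coverage$modeled),
      percentModeled = if (is.null(coverage)) NA_real_ else coverage$percent,
      crystalCoveredResidues = if (is.null(crystalCoverage)) NA_integer_
        else as.integer(crystalCoverage$modeled),
      percentCrystal = if (is.null(crystalCoverage)) NA_real_
        else crystalCoverage$percent,
      pairsTotal = as.integer(s[["total"]]),
      pairsMapped = as.integer(s[["mapped"]]),
      pairsSatisfied = as.integer(s[["satisfied"]]),
      pairsViolated = as.integer(s[["violated"]]),
      intraCount = as.integer(sum(mapped$link_class == "intra")),
      interCount = as.integer(sum(mapped$link_class == "inter")),
      modelExtent = as.numeric(extent))
}

#' @export
setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport\n")
  if (!is.na(object@totalResidues))
    cat(sprintf("  modeled residues: %d / %d (%d%%)\n",
                object@modeledResidues, object@totalResidues,
                object@percentModeled))
  if (!is.na(object@crystalCoveredResidues))
    cat(sprintf("  crystal-covered residues: %d (%d%%)\n",
                object@crystalCoveredResidues, object@percentCrystal))
  cat(sprintf("  cross-links: %d total (%d intra, %d inter); %d mapped, %d satisfied, %d violated\n",
              object@pairsTotal, object@intraCount, object@interCount,
              object@pairsMapped, object@pairsSatisfied,
              object@pairsViolated))
  if (!is.na(object@modelExtent))
    cat(sprintf("  model extent: %.1f A\n", object@modelExtent))
})

#' Serialize a coverage report
#'
#' @param report a [CoverageReport-class].
#' @param file output path for JSON; `NULL` returns the list.
#' @return invisibly, the report as a list.
#' @export
writeReport <- function(report, file = NULL) {
  out <- list(
    total_residues = report@totalResidues,
    modeled_residues = report@modeledResidues,
    percent_modeled = report@percentModeled,
    crystal_covered_residues = report@crystalCoveredResidues,
    percent_crystal = report@percentCrystal,
    pairs_total = report@pairsTotal, pairs_mapped = report@pairsMapped,
    pairs_satisfied = report@pairsSatisfied,
    pairs_violated = report@pairsViolated,
    intra_count = report@intraCount, inter_count = report@interCount,
    model_extent = report@modelExtent)
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(out)
}
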