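#' Enumerate alternative architectures of a complex
#'
#' Builds one fully assembled model per mapping choice. A mapping choice
#' assigns each rigid component to the template chain its anchor chain is
#' superposed on; the whole component then moves rigidly. This is how a
#' handful of alternative subunit arrangements — e.g. which of two
#' structurally equivalent template chains a homolog overlays — are
#' enumerated for cross-link-based discrimination.
#'
#' @param components named list of rigid groups ([AssemblyModel-class] or
#'   [ChainModel-class]); each moves as one body.
#' @param headTemplate template structure ([AssemblyModel-class]) whose
#'   chains are the superposition targets.
#' @param alignments list of alignment entries, each a list with
#'   `component`, `anchorChain` (chain of the component used for the
#'   fit), `templateChain`, and `map` (an [AlignmentMap-class]).
#' @param mappingChoices named list; each element a named character
#'   vector `component -> template chain`. Hypotheses are built in
#'   lexicographic id order.
#' @return list of [ArchitectureHypothesis-class], ordered by id.
#' @export
enumerateArchitectures <- function(components, headTemplate, alignments,
                                   mappingChoices) {
  stopifnot(length(mappingChoices) >= 1L)
  components <- lapply(components, function(x)
    if (is(x, "ChainModel")) AssemblyModel(list(x)) else x)
  ids <- names(mappingChoices)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("mappingChoices must be a named list")
  findAlignment <- function(comp, tmplChain) {
    for (e in alignments) {
      if (identical(e$component, comp) &&
          identical(e$templateChain, tmplChain)) return(e)
    }
    stop(sprintf("no alignment available for component '%s' on template chain '%s'",
                 comp, tmplChain))
  }
  out <- lapply(sort(ids), function(id) {
    choice <- mappingChoices[[id]]
    placed <- list()
    transforms <- list()
    for (comp in names(choice)) {
      if (!comp %in% names(components))
        stop(sprintf("mapping choice '%s' names unknown component '%s'",
                     id, comp))
      entry <- findAlignment(comp, choice[[comp]])
      fit <- superposeOnTemplate(
        getChain(components[[comp]], entry$anchorChain),
        getChain(headTemplate, entry$templateChain),
        entry$map)
      placed[[comp]] <- applyTransform(components[[comp]], fit$transform)
      transforms[[comp]] <- fit$transform
    }
    model <- do.call(combineModels, c(unname(placed), list(
      metadata = list(mappingChoice = choice, transforms = transforms))))
    new("ArchitectureHypothesis", id = id, mappingChoice = choice,
        model = model,
        score = c(satisfied = NA_real_, violated = NA_real_,
                  unmappable = NA_real_))
  })
  out
}

#' @export
setMethod("show", "ArchitectureHypothesis", function(object) {
  cat(sprintf("ArchitectureHypothesis '%s': %s\n", object@id,
              paste(names(object@mappingChoice), object@mappingChoice,
                    sep = "->", collapse = ", ")))
  if (!all(is.na(object@score)))
    cat(sprintf("  score: %d satisfied, %d violated, %d unmappable\n",
                object@score[["satisfied"]], object@score[["violated"]],
                object@score[["unmappable"]]))
})

#' Select the architecture best supported by cross-links
#'
#' Scores every hypothesis with [mapCrossLinks()] and selects the one
#' with the fewest violated pairs, breaking ties by the most satisfied
#' pairs. A remaining tie is reported as unresolved (`winner = NA`),
#' never broken silently.
#'
#' @param hypotheses list of [ArchitectureHypothesis-class] from
#'   [enumerateArchitectures()].
#' @param links a [CrossLinkSet-class].
#' @param linker a [LinkerSpec-class].
#' @param chainMap,offsets see [caDistance()].
#' @return list with `winner` (hypothesis id, or `NA` if unresolved),
#'   `unresolved` flag, `scores` (data.frame of per-hypothesis tallies)
#'   and `hypotheses` (score slots filled).
#' @export
selectArchitecture <- function(hypotheses, links, linker, chainMap = NULL,
                               offsets = NULL) {
  if (!length(hypotheses)) stop("no hypotheses to select among")
  scored <- lapply(hypotheses, function(h) {
    mapped <- mapCrossLinks(h@model, links, linker, chainMap = chainMap,
                            offsets = offsets)
    s <- attr(mapped, "summary")
    h@score <- c(satisfied = unname(s[["satisfied"]]),
                 violated = unname(s[["violated"]]),
                 unmappable = unname(s[["unmappable"]]))
    h
  })
  scores <- data.frame(
    id = vapply(scored, function(h) h@id, character(1)),
    satisfied = vapply(scored, function(h) h@score[["satisfied"]], numeric(1)),
    violated = vapply(scored, function(h) h@score[["violated"]], numeric(1)),
    unmappable = vapply(scored, function(h) h@score[["unmappable"]],
                        numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(scores$violated, -scores$satisfied)
  best <- ord[1]
  unresolved <- nrow(scores) > 1L &&
    scores$violated[ord[2]] == scores$violated[best] &&
    scores$satisfied[ord[2]] == scores$satisfied[best]
  list(winner = if (unresolved) NA_character_ else scores$id[best],
       unresolved = unresolved, scores = scores, hypotheses = scored)
}

#' Restraint-guided placement of a flexibly tethered component
#'
#' Samples random rigid placements of a component around an anchor model
#' — rotations uniform over the rotation group (quaternion sampling),
#' translations of the component centroid uniform in the anchor's
#' bounding box padded by the cross-link cutoff — and keeps those that
#' satisfy every distance restraint and leave no inter-model CA pair
#' closer than `clashCutoff`. Deterministic for a fixed seed.
#'
#' @param component the subcomplex to place ([AssemblyModel-class]).
#' @param anchorModel the fixed model it is tethered to.
#' @param restraints a [CrossLinkSet-class]; each pair must reference at
#'   least one residue present in one of the two models (a pair found in
#'   neither is an error).
#' @param linker a [LinkerSpec-class]; restraint cutoff is
#'   [maxCaDistance()].
#' @param nSamples number of random placements to draw (>= 1).
#' @param seed integer seed.
#' @param clashCutoff minimum allowed CA-CA distance between the placed
#'   component and the anchor (Angstrom, default 4).
#' @param chainMap,offsets see [caDistance()]; applied across both models.
#' @return list with `transforms` (accepted [RigidTransform-class]s),
#'   `centroids` (matrix of placed component centroids),
#'   `acceptanceRate`, and `nSamples`.
#' @export
placeFlexible <- function(component, anchorModel, restraints, linker,
                          nSamples = 1000, seed = 1, clashCutoff = 4,
                          chainMap = NULL, offsets = NULL) {
  stopifnot(nSamples >= 1)
  cutoff <- maxCaDistance(linker)
  compCA <- caCoords(component)
  anchCA <- caCoords(anchorModel)
  cm <- if (is.null(chainMap)) {
    ids <- unique(c(chainIds(component), chainIds(anchorModel)))
    stats::setNames(as.list(ids), ids)
  } else lapply(chainMap, as.character)
  resolve <- function(subunit, residue) {
    if (!subunit %in% names(cm))
      stop(sprintf("subunit '%s' is not in the chain map", subunit))
    for (ch in cm[[subunit]]) {
      for (where in c("component", "anchor")) {
        model <- if (where == "component") component else anchorModel
        h <- siteCA(model, ch, residue, offsets)
        if (!is.null(h)) return(list(where = where, coord = h$coord))
      }
    }
    NULL
  }
  df <- linkTable(restraints)
  sites <- list()
  for (i in seq_len(nrow(df))) {
    a <- resolve(df$subunit_a[i], df$residue_a[i])
    b <- resolve(df$subunit_b[i], df$residue_b[i])
    if (is.null(a) && is.null(b))
      stop(sprintf("restraint %s:%d-%s:%d references residues absent from both models",
                   df$subunit_a[i], df$residue_a[i],
                   df$subunit_b[i], df$residue_b[i]))
    if (is.null(a) || is.null(b)) next  # partially unmappable: no constraint
    sites[[length(sites) + 1L]] <- list(a = a, b = b)
  }
  lo <- apply(anchCA, 2, min) - cutoff
  hi <- apply(anchCA, 2, max) + cutoff
  centroid <- colMeans(compCA)
  compCentered <- sweep(compCA, 2, centroid)
  withSeed(seed, {
    accepted <- list()
    centroids <- matrix(numeric(0), 0, 3)
    for (s in seq_len(nSamples)) {
      R <- randomRotation()
      u <- stats::runif(3, lo, hi)
      tr <- RigidTransform(R, u - as.numeric(R %*% centroid))
      ok <- TRUE
      for (st in sites) {
        pa <- st$a$coord; pb <- st$b$coord
        if (st$a$where == "component") pa <- transformCoords(rbind(pa), tr)[1, ]
        if (st$b$where == "component") pb <- transformCoords(rbind(pb), tr)[1, ]
        if (sqrt(sum((pa - pb)^2)) > cutoff + .CUTOFF_EPS) { ok <- FALSE; break }
      }
      if (ok) {
        placedCA <- sweep(compCentered %*% t(R), 2, u, "+")
        if (minCrossDistance(placedCA, anchCA) < clashCutoff) ok <- FALSE
      }
      if (ok) {
        accepted[[length(accepted) + 1L]] <- tr
        centroids <- rbind(centroids, u)
      }
    }
    list(transforms = accepted, centroids = centroids,
         acceptanceRate = length(accepted) / nSamples, nSamples = nSamples)
  })
}
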