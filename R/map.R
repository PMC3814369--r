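# -- mapping cross-links onto structures --------------------------------

# normalize a chain map: named list subunit -> character vector of chain
# ids (several when a subunit is present in more than one copy). NULL
# means identity (subunit names are chain ids).
normalizeChainMap <- function(chainMap, model) {
  if (is.null(chainMap)) {
    ids <- chainIds(model)
    chainMap <- stats::setNames(as.list(ids), ids)
  }
  lapply(chainMap, as.character)
}

# CA position of one site in full-length numbering; returns list(coord,
# chain) for the requested copy, or NULL when not modeled
siteCA <- function(model, chain, residue, offsets) {
  off <- if (!is.null(offsets) && chain %in% names(offsets))
    offsets[[chain]] else 0L
  resno <- residue - off   # full-length residue = model residue + offset
  if (!chain %in% names(model@chains)) return(NULL)
  ca <- caCoords(model@chains[[chain]])
  hit <- match(as.character(resno), rownames(ca))
  if (is.na(hit)) return(NULL)
  list(coord = ca[hit, ], chain = chain)
}

#' C-alpha distance between two cross-linked sites
#'
#' Euclidean distance between the CA atoms of two sites given in
#' full-length subunit numbering. Residue numbers are translated to model
#' numbering via per-chain offsets (full-length = model + offset). When a
#' subunit is present in several copies, the minimum distance over all
#' copy combinations is returned together with the chains used.
#'
#' @param model an [AssemblyModel-class].
#' @param siteA,siteB lists or vectors `(subunit, residue)`.
#' @param chainMap named list, subunit -> chain id(s). `NULL` means chain
#'   ids equal subunit names. A subunit absent from the map is a
#'   configuration error (distinct from an unmappable site).
#' @param offsets named integer vector by chain id; default all zero.
#' @return list with `distance` (Angstrom, or `NA` when either residue is
#'   not modeled), `chain_a`, `chain_b`.
#' @export
caDistance <- function(model, siteA, siteB, chainMap = NULL, offsets = NULL) {
  stopifnot(is(model, "AssemblyModel"))
  chainMap <- normalizeChainMap(chainMap, model)
  getSite <- function(site) {
    su <- as.character(site[[1]]); res <- as.integer(site[[2]])
    if (!su %in% names(chainMap))
      stop(sprintf("subunit '%s' is not in the chain map", su))
    hits <- list()
    for (ch in chainMap[[su]]) {
      h <- siteCA(model, ch, res, offsets)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
    hits
  }
  ha <- getSite(siteA); hb <- getSite(siteB)
  if (!length(ha) || !length(hb))
    return(list(distance = NA_real_, chain_a = NA_character_,
                chain_b = NA_character_))
  best <- list(distance = Inf, chain_a = NA_character_,
               chain_b = NA_character_)
  for (a in ha) for (b in hb) {
    d <- sqrt(sum((a$coord - b$coord)^2))
    if (d < best$distance)
      best <- list(distance = d, chain_a = a$chain, chain_b = b$chain)
  }
  best
}

#' Map cross-link pairs onto a structure
#'
#' Computes the CA-CA distance of every pair and classifies it as
#' `satisfied` (distance <= cutoff; the boundary itself is satisfied),
#' `violated` (strictly above), or `unmappable` (either residue absent
#' from the model). Comparisons use a 1e-6 Angstrom tolerance so exact
#' boundary values are never lost to float noise.
#'
#' @param model an [AssemblyModel-class].
#' @param links a [CrossLinkSet-class] of deduplicated pairs.
#' @param linker a [LinkerSpec-class]; the cutoff is
#'   [maxCaDistance()]`(linker)`.
#' @param chainMap,offsets see [caDistance()].
#' @param cutoff override the cutoff (Angstrom).
#' @return data.frame with one row per pair: the pair columns plus
#'   `distance`, `status`, `chain_a`, `chain_b`; tallies are attached as
#'   attribute `"summary"`.
#' @export
mapCrossLinks <- function(model, links, linker, chainMap = NULL,
                          offsets = NULL, cutoff = maxCaDistance(linker)) {
  df <- if (is(links, "CrossLinkSet")) linkTable(links) else
    linkTable(CrossLinkSet(links))
  n <- nrow(df)
  df$distance <- NA_real_
  df$status <- rep("unmappable", n)
  df$chain_a <- NA_character_
  df$chain_b <- NA_character_
  for (i in seq_len(n)) {
    r <- caDistance(model,
                    list(df$subunit_a[i], df$residue_a[i]),
                    list(df$subunit_b[i], df$residue_b[i]),
                    chainMap = chainMap, offsets = offsets)
    df$distance[i] <- r$distance
    df$chain_a[i] <- r$chain_a
    df$chain_b[i] <- r$chain_b
    if (!is.na(r$distance))
      df$status[i] <- if (r$distance <= cutoff + .CUTOFF_EPS)
        "satisfied" else "violated"
  }
  attr(df, "summary") <- mappingTallies(df)
  df
}

# tallies for a mapped-pair data.frame
mappingTallies <- function(df) {
  c(total = nrow(df),
    mapped = sum(df$status != "unmappable"),
    satisfied = sum(df$status == "satisfied"),
    violated = sum(df$status == "violated"),
    unmappable = sum(df$status == "unmappable"))
}
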