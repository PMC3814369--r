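# -- reactive-site logic ------------------------------------------------
#
# A cross-linked lysine blocks tryptic cleavage, so a peptide whose
# C-terminal residue is the linked site could not have been produced by
# cleavage after that site; such sites are only reachable through
# missed-cleavage peptides (or when the peptide ends at the protein
# C-terminus, where no cleavage was needed).

reactiveSitesInPeptide <- function(sequence, start, end, proteinLength,
                                   linker) {
  aa <- strsplit(sequence, "")[[1]]
  sites <- start - 1L + which(aa %in% linker@reactiveTargets)
  sites <- sites[sites != end | end == proteinLength]
  if (linker@ntermReactive && start == 1L)
    sites <- sort(unique(c(1L, sites)))
  sites
}

#' Neutral mass of a cross-linked peptide pair
#'
#' The summed peptide masses plus the intact bridge mass, plus the
#' heavy/light isotope delta for the heavy form. Both peptides must carry
#' a reactive site (a target residue, or the protein N-terminus when the
#' linker is N-terminus reactive).
#'
#' @param pa,pb peptides: one-row data.frames as returned by [digest()],
#'   or plain sequence strings (then treated as internal peptides).
#' @param linker a [LinkerSpec-class] with `bridgeMassLight` set.
#' @param form `"light"` or `"heavy"`.
#' @param proteinLengths optional named vector of subunit lengths, used
#'   for the C-terminal blocked-cleavage rule.
#' @return neutral monoisotopic mass in Da.
#' @export
crosslinkedMass <- function(pa, pb, linker, form = c("light", "heavy"),
                            proteinLengths = NULL) {
  form <- match.arg(form)
  if (is.na(linker@bridgeMassLight))
    stop("linker bridgeMassLight is unset; supply it from vendor documentation")
  norm <- function(p) {
    if (is.character(p)) {
      data.frame(subunit = NA_character_, start = 2L,
                 end = 1L + nchar(p), sequence = p, mass = peptideMass(p),
                 stringsAsFactors = FALSE)
    } else as.data.frame(p)
  }
  pa <- norm(pa); pb <- norm(pb)
  for (p in list(pa, pb)) {
    plen <- if (!is.null(proteinLengths) && !is.na(p$subunit[1]) &&
                p$subunit[1] %in% names(proteinLengths))
      proteinLengths[[p$subunit[1]]] else Inf
    if (length(reactiveSitesInPeptide(p$sequence[1], p$start[1], p$end[1],
                                      plen, linker)) == 0L)
      stop(sprintf("peptide '%s' carries no reactive site for linker %s",
                   p$sequence[1], linker@name))
  }
  m <- pa$mass[1] + pb$mass[1] + linker@bridgeMassLight
  if (form == "heavy") m <- m + linker@heavyLightDelta
  m
}

#' Find light/heavy isotope doublets in a peak list
#'
#' Reports pairs of peaks with equal charge `z` whose m/z values differ
#' by `delta / z` within `tolPpm` of the lighter member. Each doublet is
#' reported once, lighter member first; the result is independent of the
#' input peak order (up to row indices).
#'
#' @param peaks data.frame with columns `mz`, `charge` (and optionally
#'   `intensity`).
#' @param delta neutral heavy-minus-light mass difference in Da (8.05824
#'   for CBDPS-H8/D8).
#' @param tolPpm matching tolerance in ppm.
#' @return data.frame with columns `light`, `heavy` (row indices into
#'   `peaks`), `charge`, `mz_light`, `mz_heavy`.
#' @export
findDoublets <- function(peaks, delta, tolPpm = 10) {
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks))
    return(data.frame(light = integer(0), heavy = integer(0),
                      charge = integer(0), mz_light = numeric(0),
                      mz_heavy = numeric(0)))
  stopifnot(all(peaks$charge >= 1))
  out <- list()
  for (z in sort(unique(peaks$charge))) {
    idx <- which(peaks$charge == z)
    mz <- peaks$mz[idx]
    o <- order(mz)
    idx <- idx[o]; mz <- mz[o]
    step <- delta / z
    for (i in seq_along(mz)) {
      tol <- tolPpm * 1e-6 * mz[i]
      j <- which(abs(mz - (mz[i] + step)) <= tol)
      j <- j[j != i]
      if (length(j))
        out[[length(out) + 1L]] <- data.frame(
          light = idx[i], heavy = idx[j], charge = z,
          mz_light = mz[i], mz_heavy = mz[j])
    }
  }
  if (!length(out))
    return(data.frame(light = integer(0), heavy = integer(0),
                      charge = integer(0), mz_light = numeric(0),
                      mz_heavy = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$charge, res$mz_light, res$mz_heavy), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match observed precursor masses to cross-linked peptide pairs
#'
#' Exhaustively enumerates unordered peptide pairs (a peptide may pair
#' with a second copy of itself) whose light cross-linked mass matches an
#' observed neutral mass within `tolPpm`, then enumerates every
#' reactive-site pair in the matched peptides. Candidates are returned
#' sorted by absolute ppm error.
#'
#' @param observedMasses numeric vector of observed neutral masses (Da).
#' @param peptides data.frame from [digest()] (possibly row-bound over
#'   several subunits).
#' @param linker a [LinkerSpec-class] with `bridgeMassLight` set.
#' @param tolPpm precursor tolerance in ppm (default 10).
#' @return data.frame of candidates: observed index and mass, both
#'   peptides (subunit, range, sequence, missed cleavages), absolute
#'   linked-site indices `site_a`/`site_b`, theoretical `neutral_mass`
#'   and `ppm_error`.
#' @export
matchPrecursors <- function(observedMasses, peptides, linker, tolPpm = 10) {
  stopifnot(tolPpm > 0)
  if (is.na(linker@bridgeMassLight))
    stop("linker bridgeMassLight is unset; supply it from vendor documentation")
  peptides <- as.data.frame(peptides)
  if (!nrow(peptides) || !length(observedMasses))
    return(emptyCandidates())
  # protein lengths inferred from the digest (peptides tile each subunit)
  plens <- tapply(peptides$end, peptides$subunit, max)
  sites <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    reactiveSitesInPeptide(p$sequence, p$start, p$end,
                           plens[[p$subunit]], linker)
  })
  eligible <- which(lengths(sites) > 0L)
  if (!length(eligible)) return(emptyCandidates())
  em <- peptides$mass[eligible]
  pairMass <- outer(em, em, "+") + linker@bridgeMassLight
  rows <- list()
  for (k in seq_along(observedMasses)) {
    obs <- observedMasses[k]
    ppm <- (pairMass - obs) / obs * 1e6
    hit <- which(abs(ppm) <= tolPpm & upper.tri(ppm, diag = TRUE),
                 arr.ind = TRUE)
    if (!nrow(hit)) next
    for (h in seq_len(nrow(hit))) {
      i <- eligible[hit[h, 1]]; j <- eligible[hit[h, 2]]
      grid <- expand.grid(site_a = sites[[i]], site_b = sites[[j]])
      # self-pairs: keep unordered site combinations only
      if (i == j) grid <- grid[grid$site_a <= grid$site_b, , drop = FALSE]
      if (!nrow(grid)) next
      pa <- peptides[i, ]; pb <- peptides[j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        observed_index = k, observed_mass = obs,
        subunit_a = pa$subunit, start_a = pa$start, end_a = pa$end,
        sequence_a = pa$sequence, missed_a = pa$missed, site_a = grid$site_a,
        subunit_b = pb$subunit, start_b = pb$start, end_b = pb$end,
        sequence_b = pb$sequence, missed_b = pb$missed, site_b = grid$site_b,
        neutral_mass = pairMass[hit[h, 1], hit[h, 2]],
        ppm_error = ppm[hit[h, 1], hit[h, 2]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyCandidates())
  res <- do.call(rbind, rows)
  res <- res[order(abs(res$ppm_error)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

emptyCandidates <- function() {
  data.frame(observed_index = integer(0), observed_mass = numeric(0),
             subunit_a = character(0), start_a = integer(0),
             end_a = integer(0), sequence_a = character(0),
             missed_a = integer(0), site_a = integer(0),
             subunit_b = character(0), start_b = integer(0),
             end_b = integer(0), sequence_b = character(0),
             missed_b = integer(0), site_b = integer(0),
             neutral_mass = numeric(0), ppm_error = numeric(0),
             stringsAsFactors = FALSE)
}

# singly charged b/y ladder for one peptide of a cross-linked pair; ions
# spanning the linked residue are shifted by the partner mass + bridge
fragmentLadder <- function(sequence, linkPos, shift) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) return(numeric(0))
  m <- .RESIDUE_MASS[aa]
  b <- cumsum(m)[seq_len(n - 1L)] + .MASS_PROTON
  # y_i = sum of the last i residue masses, plus water and a proton
  y <- cumsum(rev(m))[seq_len(n - 1L)] + .MASS_WATER + .MASS_PROTON
  bi <- seq_len(n - 1L)
  yi <- seq_len(n - 1L)
  b[bi >= linkPos] <- b[bi >= linkPos] + shift
  y[yi >= n - linkPos + 1L] <- y[yi >= n - linkPos + 1L] + shift
  c(b, y)
}

#' Fragment-ion support for a cross-link candidate
#'
#' Generates the theoretical singly charged b and y ions of both
#' peptides, shifting ions that span the linked residue by the partner
#' peptide's mass plus the bridge mass, and returns the fraction of
#' theoretical ions found in the observed fragment peaks.
#'
#' @param candidate one row of the [matchPrecursors()] result.
#' @param fragmentPeaks numeric vector of observed fragment m/z values.
#' @param linker a [LinkerSpec-class] with `bridgeMassLight` set.
#' @param tolPpm fragment tolerance in ppm (default 20).
#' @return matched fraction in `[0, 1]` (0 for an empty peak list).
#' @export
scoreSpectrumMatch <- function(candidate, fragmentPeaks, linker,
                               tolPpm = 20) {
  candidate <- as.data.frame(candidate)
  stopifnot(nrow(candidate) == 1L)
  if (is.na(linker@bridgeMassLight))
    stop("linker bridgeMassLight is unset")
  massA <- peptideMass(candidate$sequence_a)
  massB <- peptideMass(candidate$sequence_b)
  posA <- max(1L, candidate$site_a - candidate$start_a + 1L)
  posB <- max(1L, candidate$site_b - candidate$start_b + 1L)
  theo <- c(
    fragmentLadder(candidate$sequence_a, posA,
                   massB + linker@bridgeMassLight),
    fragmentLadder(candidate$sequence_b, posB,
                   massA + linker@bridgeMassLight))
  if (!length(theo)) return(0)
  if (!length(fragmentPeaks)) return(0)
  matched <- vapply(theo, function(m) {
    any(abs(fragmentPeaks - m) <= tolPpm * 1e-6 * m)
  }, logical(1))
  sum(matched) / length(theo)
}

#' Collapse spectrum matches to unique cross-link pairs
#'
#' Pair identity is unordered: `(a-site, b-site)` equals
#' `(b-site, a-site)`. `spectral_count` becomes the number of collapsed
#' input rows (weighted by any incoming counts), `link_class` is
#' recomputed, and the output is sorted by the canonical site order.
#'
#' @param links a [CrossLinkSet-class] or compatible data.frame (one row
#'   per spectrum match).
#' @return a deduplicated [CrossLinkSet-class].
#' @examples
#' x <- CrossLinkSet(data.frame(subunit_a = c("A", "B"), residue_a = c(10, 20),
#'                              subunit_b = c("B", "A"), residue_b = c(20, 10)))
#' deduplicateLinks(x)  # one pair, spectral_count 2
#' @export
deduplicateLinks <- function(links) {
  xs <- if (is(links, "CrossLinkSet")) links else CrossLinkSet(links)
  df <- linkTable(xs)
  if (!nrow(df)) return(xs)
  key <- paste(df$subunit_a, df$residue_a, df$subunit_b, df$residue_b,
               sep = "\r")
  counts <- tapply(df$spectral_count, key, sum)
  first <- df[!duplicated(key), , drop = FALSE]
  first$spectral_count <- as.integer(counts[paste(
    first$subunit_a, first$residue_a, first$subunit_b, first$residue_b,
    sep = "\r")])
  first <- first[order(first$subunit_a, first$residue_a,
                       first$subunit_b, first$residue_b), , drop = FALSE]
  first$spectrum_id <- NULL
  rownames(first) <- NULL
  CrossLinkSet(first)
}

#' Turn precursor-match candidates into a cross-link set
#'
#' @param candidates data.frame from [matchPrecursors()].
#' @return a [CrossLinkSet-class] with one row per candidate.
#' @export
candidatesToLinks <- function(candidates) {
  CrossLinkSet(data.frame(
    subunit_a = candidates$subunit_a, residue_a = candidates$site_a,
    subunit_b = candidates$subunit_b, residue_b = candidates$site_b,
    stringsAsFactors = FALSE))
}
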