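# -- synthetic complexes, cross-links and precursor lists ----------------
#
# Toy data with the statistical structure the pipeline assumes: helical
# multi-chain complexes with lysines at known positions, cross-links
# drawn from site pairs within the cutoff plus decoys beyond it, and
# precursor lists carrying light/heavy isotope doublets. Distance
# statistics, not fold realism, are what the pipeline consumes.

#' Ideal alpha-helix CA trace
#'
#' CA positions on an ideal straight alpha helix: 1.5 Angstrom rise and
#' 100 degree twist per residue on a 2.3 Angstrom radius about the axis.
#' Consecutive CA-CA distances come out near the canonical 3.8 Angstrom.
#'
#' @param nRes number of residues (>= 2).
#' @param origin 3-vector, position of the first residue's axis point.
#' @param axis helix axis direction (non-zero; normalized internally).
#' @param chainId chain id.
#' @param sequence optional one-letter sequence of length `nRes`
#'   (defaults to poly-alanine).
#' @param startRes first residue number.
#' @return a [ChainModel-class] with CA atoms only.
#' @export
makeHelix <- function(nRes, origin = c(0, 0, 0), axis = c(0, 0, 1),
                      chainId = "A", sequence = NULL, startRes = 1L) {
  stopifnot(nRes >= 2)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("helix axis must be non-zero")
  a <- axis / nrm
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  i <- seq_len(nRes) - 1L
  theta <- i * 100 * pi / 180
  pos <- outer(i * 1.5, a) + 2.3 * (outer(cos(theta), u) +
                                      outer(sin(theta), v))
  pos <- sweep(pos, 2, origin, "+")
  if (is.null(sequence)) sequence <- strrep("A", nRes)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == nRes)
  ChainModel(chainId, data.frame(
    resno = startRes + i, code = aa, elety = "CA",
    x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE))
}

# random sequence: uniform over the 19 non-lysine residues, lysines
# inserted at the given fraction (controls eligible-site density)
randomSequence <- function(n, lysineFraction) {
  pool <- setdiff(.AA_CODES, "K")
  aa <- sample(pool, n, replace = TRUE)
  isK <- stats::runif(n) < lysineFraction
  aa[isK] <- "K"
  paste(aa, collapse = "")
}

#' Generate a toy multi-chain helical complex
#'
#' Chains are straight ideal helices grouped in two-helix dimers (a toy
#' stand-in for 4-helix-bundle/coiled-coil dimers); dimer `k` is placed
#' by the planted transform `architecture[[k]]`. Sequences are random
#' with lysines at the stated fraction. Output is deterministic for a
#' fixed seed, and the manifest records the ground truth.
#'
#' @param nChains number of chains (even; two per dimer). Default 4.
#' @param residuesPerChain residues per chain. Default 60.
#' @param architecture list of [RigidTransform-class], one per dimer.
#'   Default: first dimer at the origin, second translated 22 Angstrom
#'   along x (adjacent, within cross-linking range).
#' @param lysineFraction probability a position is lysine. Default 0.1.
#' @param seed integer seed.
#' @return list with `model` ([AssemblyModel-class]), `sequences` (named
#'   character vector), and `manifest` (planted transforms, lysine
#'   positions, seed).
#' @export
makeToyComplex <- function(nChains = 4, residuesPerChain = 60,
                           architecture = NULL, lysineFraction = 0.1,
                           seed = 1) {
  stopifnot(nChains >= 2, nChains %% 2 == 0, residuesPerChain >= 2)
  nDimers <- nChains / 2
  if (is.null(architecture)) {
    architecture <- lapply(seq_len(nDimers), function(k)
      RigidTransform(diag(3), c(22 * (k - 1), 0, 0)))
  }
  stopifnot(length(architecture) == nDimers)
  withSeed(seed, {
    ids <- LETTERS[seq_len(nChains)]
    seqs <- stats::setNames(
      vapply(seq_len(nChains), function(i)
        randomSequence(residuesPerChain, lysineFraction), character(1)),
      ids)
    chains <- list()
    for (k in seq_len(nDimers)) {
      for (j in 1:2) {
        idx <- (k - 1) * 2 + j
        base <- makeHelix(residuesPerChain,
                          origin = c(0, (j - 1) * 10, 0),
                          axis = c(0, 0, 1), chainId = ids[idx],
                          sequence = seqs[[idx]])
        chains[[idx]] <- applyTransform(base, architecture[[k]])
      }
    }
    model <- AssemblyModel(chains)
    manifest <- list(
      seed = seed, nChains = nChains,
      residuesPerChain = residuesPerChain,
      lysineFraction = lysineFraction,
      transforms = architecture,
      lysines = lapply(seqs, function(s)
        which(strsplit(s, "")[[1]] == "K")))
    list(model = model, sequences = seqs, manifest = manifest)
  })
}

# all reactive sites of a complex: lysines, plus residue 1 per chain when
# the linker is N-terminus reactive
complexSites <- function(sequences, linker) {
  out <- list()
  for (su in names(sequences)) {
    pos <- which(strsplit(sequences[[su]], "")[[1]] %in%
                   linker@reactiveTargets)
    if (linker@ntermReactive) pos <- sort(unique(c(1L, pos)))
    if (length(pos))
      out[[su]] <- data.frame(subunit = su, residue = pos,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a cross-link set from a model
#'
#' True links are drawn uniformly without replacement from reactive-site
#' pairs whose CA-CA distance in the generating model is at or below the
#' linker cutoff; decoys from pairs strictly beyond it. The generating
#' distance of every sampled pair is recorded.
#'
#' @param model generating [AssemblyModel-class] (chain ids are subunit
#'   names).
#' @param sequences named character vector (or `AAStringSet`).
#' @param linker a [LinkerSpec-class].
#' @param nTrue,nDecoy numbers of true and decoy links to draw.
#' @param seed integer seed.
#' @return list with `links` (a [CrossLinkSet-class]) and `truth`
#'   (data.frame with the generating `distance` and `type` =
#'   true/decoy per pair).
#' @export
simulateCrossLinks <- function(model, sequences, linker, nTrue, nDecoy,
                               seed = 1) {
  sequences <- asSequenceVector(sequences)
  sites <- complexSites(sequences, linker)
  if (is.null(sites) || nrow(sites) < 2L)
    stop("no reactive sites in the supplied sequences")
  coords <- t(vapply(seq_len(nrow(sites)), function(i) {
    h <- siteCA(model, sites$subunit[i], sites$residue[i], offsets = NULL)
    if (is.null(h)) c(NA_real_, NA_real_, NA_real_) else h$coord
  }, numeric(3)))
  ok <- !is.na(coords[, 1])
  sites <- sites[ok, , drop = FALSE]; coords <- coords[ok, , drop = FALSE]
  cmb <- utils::combn(nrow(sites), 2)
  d <- sqrt(rowSums((coords[cmb[1, ], , drop = FALSE] -
                       coords[cmb[2, ], , drop = FALSE])^2))
  cutoff <- maxCaDistance(linker)
  eligTrue <- which(d <= cutoff)
  eligDecoy <- which(d > cutoff)
  if (length(eligTrue) < nTrue || length(eligDecoy) < nDecoy)
    stop(sprintf(
      "not enough eligible pairs: %d within cutoff (need %d), %d beyond (need %d)",
      length(eligTrue), nTrue, length(eligDecoy), nDecoy))
  withSeed(seed, {
    pick <- c(if (nTrue > 0) sample(eligTrue, nTrue),
              if (nDecoy > 0) sample(eligDecoy, nDecoy))
    type <- rep(c("true", "decoy"), c(nTrue, nDecoy))
    df <- data.frame(
      subunit_a = sites$subunit[cmb[1, pick]],
      residue_a = sites$residue[cmb[1, pick]],
      subunit_b = sites$subunit[cmb[2, pick]],
      residue_b = sites$residue[cmb[2, pick]],
      stringsAsFactors = FALSE)
    links <- CrossLinkSet(df, sequences = sequences)
    truth <- cbind(linkTable(links)[, 1:4], distance = d[pick], type = type)
    list(links = links, truth = truth)
  })
}

#' Simulate precursor masses and isotope-doublet peak lists
#'
#' For every simulated link, the covering peptide of each site is located
#' in the in-silico digest (smallest missed-cleavage form whose
#' C-terminus is not the linked lysine, since a cross-linked lysine
#' blocks cleavage), and the light and heavy cross-linked neutral masses
#' are emitted with Gaussian ppm noise. The heavy mass is the noisy light
#' mass plus the exact isotope delta, as the doublet spacing — not the
#' absolute calibration — is what tags linker-containing species.
#' Doublet-consistent m/z rows are emitted at charges 2-4.
#'
#' @param links list from [simulateCrossLinks()], or a
#'   [CrossLinkSet-class].
#' @param sequences named character vector or `AAStringSet`.
#' @param linker a [LinkerSpec-class] with `bridgeMassLight` set.
#' @param enzyme digestion enzyme (see [digest()]).
#' @param maxMissed maximum missed cleavages searched for a covering
#'   peptide.
#' @param noisePpm standard deviation of the mass noise in ppm.
#' @param seed integer seed.
#' @return list with `peaks` (data.frame `mz`, `charge`, `intensity`),
#'   `neutralMasses` (noisy light masses, one per link), `peptides` (the
#'   digest used), and `truth` (link sites with their emitted masses).
#' @export
simulatePrecursors <- function(links, sequences, linker,
                               enzyme = "trypsin", maxMissed = 2,
                               noisePpm = 0, seed = 1) {
  if (is.na(linker@bridgeMassLight))
    stop("linker bridgeMassLight is unset")
  if (is.list(links) && !is(links, "CrossLinkSet")) links <- links$links
  df <- linkTable(links)
  sequences <- asSequenceVector(sequences)
  peptides <- do.call(rbind, lapply(names(sequences), function(su)
    digest(sequences[[su]], enzyme, maxMissed = maxMissed, subunit = su)))
  plens <- stats::setNames(nchar(sequences), names(sequences))
  covering <- function(su, site) {
    p <- peptides[peptides$subunit == su & peptides$start <= site &
                    peptides$end >= site, , drop = FALSE]
    keep <- vapply(seq_len(nrow(p)), function(i)
      site %in% reactiveSitesInPeptide(p$sequence[i], p$start[i], p$end[i],
                                       plens[[su]], linker), logical(1))
    p <- p[keep, , drop = FALSE]
    if (!nrow(p))
      stop(sprintf(
        "site %s:%d is not coverable by any peptide with <= %d missed cleavages",
        su, site, maxMissed))
    p <- p[order(p$missed, p$end - p$start), , drop = FALSE]
    p[1, ]
  }
  withSeed(seed, {
    rows <- list(); peaks <- list()
    for (i in seq_len(nrow(df))) {
      pa <- covering(df$subunit_a[i], df$residue_a[i])
      pb <- covering(df$subunit_b[i], df$residue_b[i])
      light <- crosslinkedMass(pa, pb, linker, "light",
                               proteinLengths = plens)
      light <- light * (1 + stats::rnorm(1, 0, noisePpm) * 1e-6)
      heavy <- light + linker@heavyLightDelta
      rows[[i]] <- data.frame(
        df[i, c("subunit_a", "residue_a", "subunit_b", "residue_b")],
        mass_light = light, mass_heavy = heavy,
        stringsAsFactors = FALSE)
      for (z in 2:4) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          mz = c((light + z * .MASS_PROTON) / z,
                 (heavy + z * .MASS_PROTON) / z),
          charge = z, intensity = 1e5, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    list(peaks = do.call(rbind, peaks), neutralMasses = truth$mass_light,
         peptides = peptides, truth = truth)
  })
}

#' Synthetic stand-in for a published cross-link spectrum table
#'
#' A synthetic table of 55 spectrum matches over six middle-module
#' subunits, constructed to the published totals — it collapses to 40
#' unique lysine-lysine pairs, 19 intra- and 21 inter-subunit — and
#' containing the three site pairs printed in the text (Med7 K35-K103,
#' Med4 K36-Med9 K117, Med10 K62-Med7 K147). The remaining sites are
#' invented; this is a fixture for exercising the pipeline, not the
#' published supplementary data.
#'
#' @return data.frame with columns `subunit_a`, `residue_a`, `subunit_b`,
#'   `residue_b`, `spectrum_id` (55 rows).
#' @export
syntheticCrossLinkTable <- function() {
  intra <- list(
    c("Med7", 35, "Med7", 103),
    c("Med7", 14, "Med7", 22), c("Med7", 91, "Med7", 119),
    c("Med7", 147, "Med7", 160), c("Med4", 36, "Med4", 79),
    c("Med4", 79, "Med4", 141), c("Med4", 141, "Med4", 190),
    c("Med4", 190, "Med4", 255), c("Med9", 12, "Med9", 45),
    c("Med9", 45, "Med9", 117), c("Med9", 117, "Med9", 140),
    c("Med10", 23, "Med10", 62), c("Med10", 62, "Med10", 104),
    c("Med10", 104, "Med10", 133), c("Med21", 6, "Med21", 43),
    c("Med21", 43, "Med21", 79), c("Med21", 79, "Med21", 113),
    c("Med21", 113, "Med21", 135), c("Med7", 103, "Med7", 147))
  inter <- list(
    c("Med4", 36, "Med9", 117),
    c("Med10", 62, "Med7", 147),
    c("Med4", 79, "Med9", 45), c("Med4", 141, "Med9", 12),
    c("Med4", 190, "Med9", 140), c("Med4", 36, "Med7", 160),
    c("Med4", 79, "Med21", 113), c("Med4", 141, "Med21", 135),
    c("Med9", 45, "Med7", 147), c("Med9", 117, "Med21", 113),
    c("Med9", 140, "Med21", 79), c("Med10", 23, "Med7", 119),
    c("Med10", 104, "Med21", 6), c("Med10", 133, "Med21", 43),
    c("Med7", 14, "Med21", 6), c("Med7", 22, "Med21", 43),
    c("Med7", 91, "Med21", 79), c("Med7", 119, "Med21", 113),
    c("Med7", 160, "Med21", 135), c("Med4", 255, "Med7", 14),
    c("Med9", 12, "Med10", 23))
  pairs <- c(intra, inter)
  df <- data.frame(
    subunit_a = vapply(pairs, `[`, character(1), 1),
    residue_a = as.integer(vapply(pairs, `[`, character(1), 2)),
    subunit_b = vapply(pairs, `[`, character(1), 3),
    residue_b = as.integer(vapply(pairs, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  # 15 repeat observations spread over the first pairs, one of them with
  # the two sites written in the reverse order
  extra <- df[c(1:10, 20, 21, 21, 22, 23), ]
  extra[1, ] <- extra[1, c(3, 4, 1, 2)]
  out <- rbind(df, extra)
  out$spectrum_id <- sprintf("spec%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
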