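#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation moving one point
#' set onto another. The reflection branch of the SVD solution is
#' corrected so the returned rotation always has determinant +1, even for
#' mirror-image inputs.
#'
#' @param moving,fixed n x 3 coordinate matrices (n >= 3, equal n, not
#'   all points collinear).
#' @return list with `transform` (a [RigidTransform-class] such that
#'   `applyTransform(moving, transform)` best fits `fixed`) and `rmsd`
#'   (Angstrom, after transformation).
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch(p, p)$rmsd  # 0
#' @export
kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed))
    stop("point sets must have equal length")
  if (nrow(moving) < 3L)
    stop("at least 3 points are required")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm); Q <- sweep(fixed, 2, cf)
  if (max(svd(P)$d[2], svd(Q)$d[2]) < 1e-9)
    stop("points must not be collinear")
  H <- crossprod(P, Q)                  # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cf - as.numeric(R %*% cm)
  tr <- RigidTransform(R, t)
  moved <- transformCoords(moving, tr)
  list(transform = tr,
       rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

#' Superpose a mobile chain on a template via an alignment
#'
#' Runs [kabsch()] over the CA atoms of the aligned residue pairs present
#' in both chains.
#'
#' @param mobile,template [ChainModel-class] objects.
#' @param alignment an [AlignmentMap-class] with query residues in
#'   `mobile` numbering and template residues in `template` numbering.
#' @return list with `transform` (places `mobile` onto `template`),
#'   `rmsd`, and `nPairs` (aligned CA pairs used).
#' @export
superposeOnTemplate <- function(mobile, template, alignment) {
  stopifnot(is(alignment, "AlignmentMap"))
  mca <- caCoords(mobile); tca <- caCoords(template)
  qi <- match(as.character(alignment@pairs[, 1]), rownames(mca))
  ti <- match(as.character(alignment@pairs[, 2]), rownames(tca))
  ok <- !is.na(qi) & !is.na(ti)
  if (sum(ok) < 3L) {
    missing <- alignment@pairs[!ok, , drop = FALSE]
    stop(sprintf(
      "only %d aligned residue pairs have CA in both chains (need >= 3); missing e.g. query %s / template %s",
      sum(ok),
      paste(utils::head(missing[, 1], 3), collapse = ","),
      paste(utils::head(missing[, 2], 3), collapse = ",")))
  }
  fit <- kabsch(mca[qi[ok], , drop = FALSE], tca[ti[ok], , drop = FALSE])
  list(transform = fit$transform, rmsd = fit$rmsd, nPairs = sum(ok))
}

#' Thread a target sequence onto a template backbone
#'
#' Lightweight homology modeling by coordinate transfer: for every
#' aligned residue pair the target residue adopts the template residue's
#' backbone coordinates (N, CA, C, O; whichever the template has) and is
#' renumbered to target numbering. Unaligned target residues are absent
#' from the output. Per-residue provenance records the template chain and
#' residue each position came from. No side chains are built and no loops
#' are closed; the result is architectural, at CA accuracy.
#'
#' @param target sequence (string, or single named element of an
#'   `AAStringSet`).
#' @param template a [ChainModel-class] with backbone atoms for the
#'   aligned residues.
#' @param alignment an [AlignmentMap-class]; query residues in target
#'   full-length numbering.
#' @param chainId chain id of the output model (default: the alignment's
#'   query name).
#' @return a [ChainModel-class] in target numbering.
#' @export
threadBackbone <- function(target, template, alignment, chainId = NULL) {
  stopifnot(is(alignment, "AlignmentMap"))
  name <- alignment@query
  seq <- asSequenceVector(target)
  if (!is.null(names(seq)) && name %in% names(seq)) seq <- seq[[name]]
  else seq <- seq[[1]]
  n <- nchar(seq)
  pr <- alignment@pairs
  if (any(pr[, 1] < 1L | pr[, 1] > n))
    stop(sprintf("alignment query residues outside target range 1-%d", n))
  tmplRes <- residueNumbers(template)
  keep <- pr[, 2] %in% tmplRes
  pr <- pr[keep, , drop = FALSE]
  if (!nrow(pr)) stop("no aligned template residues present in the template model")
  aa <- strsplit(seq, "")[[1]]
  atoms <- list(); prov <- list()
  for (k in seq_len(nrow(pr))) {
    q <- pr[k, 1]; tt <- pr[k, 2]
    ta <- template@atoms[template@atoms$resno == tt, , drop = FALSE]
    ta$resno <- q
    ta$code <- aa[q]
    atoms[[k]] <- ta
    prov[[k]] <- data.frame(
      resno = q,
      source = sprintf("thread:%s:%d", template@chainId, tt),
      stringsAsFactors = FALSE)
  }
  ChainModel(if (is.null(chainId)) name else chainId,
             do.call(rbind, atoms), do.call(rbind, prov))
}

#' Assemble a tetramer from a dimer structure and a dimer model
#'
#' Places a modeled dimer next to a reference dimer by a supplied
#' crystal-packing transform (the rigid motion relating the two dimer
#' copies in the reference crystal), and records the minimum inter-dimer
#' CA distance as an interface sanity metric.
#'
#' @param dimerXtal reference dimer ([AssemblyModel-class]).
#' @param dimerModel dimer to place; chain ids must not collide with the
#'   reference (use [renameChains()] first).
#' @param packingTransform a [RigidTransform-class].
#' @return combined [AssemblyModel-class]; the minimum inter-dimer CA
#'   distance is stored in `metadata$minInterDimerDistance`.
#' @export
buildTetramer <- function(dimerXtal, dimerModel, packingTransform) {
  collide <- intersect(chainIds(dimerXtal), chainIds(dimerModel))
  if (length(collide))
    stop("chain id collision: ", paste(collide, collapse = ", "),
         " (rename chains of one dimer first)")
  placed <- applyTransform(dimerModel, packingTransform)
  a <- caCoords(dimerXtal); b <- caCoords(placed)
  dmin <- minCrossDistance(a, b)
  combineModels(dimerXtal, placed,
                metadata = list(minInterDimerDistance = dmin,
                                packingTransform = packingTransform))
}

# minimum distance between two coordinate sets
minCrossDistance <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(NA_real_)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}
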