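randomPoints <- function(n) matrix(stats::rnorm(n * 3, sd = 5), n, 3)

test_that("kabsch recovers identity and planted rigid motions", {
  set.seed(61)
  p <- randomPoints(10)
  f <- kabsch(p, p)
  expect_equal(f$transform@rotation, diag(3), tolerance = 1e-10)
  expect_equal(f$transform@translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  R <- axisAngleRotation(c(1, -2, 0.5), 1.2)
  t <- c(4, -7, 2)
  q <- sweep(p %*% t(R), 2, t, "+")
  f <- kabsch(p, q)
  expect_equal(f$transform@rotation, R, tolerance = 1e-8)
  expect_equal(f$transform@translation, t, tolerance = 1e-8)
  expect_lt(f$rmsd, 1e-6)
  expect_error(kabsch(p, p[1:5, ]), "equal length")
  expect_error(kabsch(p[1:2, ], p[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch stays proper and optimal on mirror-image inputs", {
  set.seed(62)
  p <- randomPoints(10)
  q <- p %*% diag(c(-1, 1, 1))  # reflection: no proper rotation fits exactly
  f <- kabsch(p, q)
  expect_equal(det(f$transform@rotation), 1, tolerance = 1e-8)
  # probe oracle: no random proper rotation does better
  cp <- sweep(p, 2, colMeans(p)); cq <- sweep(q, 2, colMeans(q))
  for (i in 1:1000) {
    R <- randomRotation()
    probe <- sqrt(mean(rowSums((cp %*% t(R) - cq)^2)))
    expect_gte(probe, f$rmsd - 1e-9)
  }
})

test_that("kabsch beats 1000 random-rotation probes on random instances", {
  set.seed(63)
  for (inst in 1:10) {
    p <- randomPoints(10)
    q <- randomPoints(10)
    f <- kabsch(p, q)
    cp <- sweep(p, 2, colMeans(p)); cq <- sweep(q, 2, colMeans(q))
    probes <- replicate(1000, {
      R <- randomRotation()
      sqrt(mean(rowSums((cp %*% t(R) - cq)^2)))
    })
    expect_gte(min(probes), f$rmsd - 1e-9)
  }
})

test_that("rigid transforms preserve pairwise distances and invert cleanly", {
  set.seed(64)
  h <- makeHelix(20, chainId = "A")
  tr <- RigidTransform(axisAngleRotation(c(0, 1, 1), 0.8), c(3, -2, 9))
  h2 <- applyTransform(h, tr)
  expect_equal(as.numeric(dist(caCoords(h2))), as.numeric(dist(caCoords(h))),
               tolerance = 1e-6)
  # identity and pure translation
  expect_equal(caCoords(applyTransform(h, identityTransform())), caCoords(h))
  sh <- applyTransform(h, RigidTransform(diag(3), c(1, 0, 0)))
  expect_equal(caCoords(sh)[, 1], caCoords(h)[, 1] + 1)
  # compose with inverse returns the original coordinates
  back <- applyTransform(h2, invertTransform(tr))
  expect_equal(caCoords(back), caCoords(h), tolerance = 1e-6)
  comp <- composeTransforms(invertTransform(tr), tr)
  expect_equal(comp@rotation, diag(3), tolerance = 1e-10)
  expect_equal(comp@translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("superposition on a template uses the aligned CA pairs", {
  h <- makeHelix(20, chainId = "A")
  tmpl <- applyTransform(h, RigidTransform(diag(3), c(5, 5, 5)))
  al <- AlignmentMap("A", "A", cbind(1:20, 1:20))
  fit <- superposeOnTemplate(h, tmpl, al)
  expect_equal(fit$transform@rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit$transform@translation, c(5, 5, 5), tolerance = 1e-8)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$nPairs, 20)
  # an alignment over any residue subset of a rigidly moved template
  # yields the same transform
  al2 <- AlignmentMap("A", "A", cbind(1:10, 1:10))
  fit2 <- superposeOnTemplate(h, tmpl, al2)
  expect_equal(fit2$transform@translation, fit$transform@translation,
               tolerance = 1e-8)
  expect_equal(fit2$transform@rotation, fit$transform@rotation,
               tolerance = 1e-8)
  # alignment referencing absent residues only
  al3 <- AlignmentMap("A", "A", cbind(100:110, 100:110))
  expect_error(superposeOnTemplate(h, tmpl, al3), "aligned residue pairs")
})

test_that("backbone threading transfers coordinates and renumbers", {
  tmpl <- makeHelix(30, chainId = "T", startRes = 19L)
  # identity-range threading onto the same numbering
  seqs <- c(Q = strrep("M", 130))
  al <- alignmentFromRanges("Q", "T", "46-127:19-108")
  expect_equal(nrow(al@pairs), 82)
  # template only has residues 19..48; aligned pairs beyond are dropped
  th <- threadBackbone(seqs, tmpl, al)
  expect_equal(residueNumbers(th), 46:75)
  expect_equal(unname(chainSequence(th)), rep("M", 30))
  # transferred coordinates equal the template's
  expect_equal(unname(caCoords(th)), unname(caCoords(tmpl)))
  # provenance records the template chain and residue
  expect_equal(th@provenance$source[1], "thread:T:19")
  # full-template threading: residue count equals alignment length
  tmpl2 <- makeHelix(90, chainId = "T", startRes = 19L)
  th2 <- threadBackbone(seqs, tmpl2, al)
  expect_equal(residueNumbers(th2), 46:127)
  expect_equal(length(th2), 82)
  # threading conserves template internal geometry
  expect_equal(as.numeric(dist(caCoords(th2))),
               as.numeric(dist(caCoords(tmpl2)[1:82, ])), tolerance = 1e-9)
  # gapped alignment: skipped template residue's partner is absent
  gap <- AlignmentMap("Q", "T", cbind(c(1L, 2L, 4L, 5L), c(19L, 20L, 22L, 23L)))
  th3 <- threadBackbone(c(Q = "MMMMM"), tmpl2, gap)
  expect_equal(residueNumbers(th3), c(1L, 2L, 4L, 5L))
  expect_error(threadBackbone(c(Q = "MM"), tmpl2, gap), "outside target")
})

test_that("tetramer assembly applies the packing transform and checks ids", {
  tc <- makeToyComplex(nChains = 2, seed = 71)
  dimer <- tc$model
  tr <- RigidTransform(axisAngleRotation(c(0, 0, 1), pi), c(30, 10, 0))
  moved <- renameChains(dimer, c(A = "C", B = "D"))
  tet <- buildTetramer(dimer, moved, tr)
  expect_setequal(chainIds(tet), c("A", "B", "C", "D"))
  # round trip: rebuilt coordinates equal directly transformed ones
  expect_equal(caCoords(getChain(tet, "C")),
               transformCoords(caCoords(getChain(dimer, "A")), tr),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(is.finite(tet@metadata$minInterDimerDistance))
  # identity packing on disjoint ids superimposes the copies
  tet0 <- buildTetramer(dimer, moved, identityTransform())
  expect_equal(tet0@metadata$minInterDimerDistance, 0)
  expect_error(buildTetramer(dimer, dimer, tr), "collision")
})

test_that("architecture enumeration builds one model per mapping choice", {
  fx <- selectionFixture(81)
  hyps <- enumerateArchitectures(fx$components, fx$template,
                                 fx$alignments, fx$choices)
  expect_length(hyps, 2)
  expect_equal(vapply(hyps, function(h) h@id, character(1)),
               sort(names(fx$choices)))
  # the two hypotheses place the dimer 60 Angstrom apart along x
  m1 <- caCoords(getChain(hyps[[1]]@model, "Med7"))
  m2 <- caCoords(getChain(hyps[[2]]@model, "Med7"))
  expect_equal(abs(unname(m2[, 1] - m1[, 1])), rep(60, nrow(m1)),
               tolerance = 1e-6)
  # the near hypothesis reproduces the generating arrangement
  near <- hyps[[which(vapply(hyps, function(h) h@id, character(1)) ==
                        "Med7C_on_Med22")]]
  for (id in c("Med7", "Med21", "Med10"))
    expect_equal(caCoords(getChain(near@model, id)),
                 caCoords(getChain(fx$truth, id)), tolerance = 1e-6)
})

test_that("single mapping choice and missing alignments are handled", {
  fx <- selectionFixture(82)
  one <- enumerateArchitectures(fx$components, fx$template, fx$alignments,
                                fx$choices["Med7C_on_Med22"])
  expect_length(one, 1)
  badChoice <- list(X = c(dimer = "Med8"))
  expect_error(
    enumerateArchitectures(fx$components, fx$template, fx$alignments,
                           badChoice),
    "no alignment")
})

test_that("cross-links select the planted architecture; ties are surfaced", {
  fx <- selectionFixture(83)
  linker <- cbdpsLinker()
  hyps <- enumerateArchitectures(fx$components, fx$template,
                                 fx$alignments, fx$choices)
  # the single discriminating link printed for the trimer logic
  link <- CrossLinkSet(data.frame(subunit_a = "Med10", residue_a = 62,
                                  subunit_b = "Med7", residue_b = 147))
  sel <- selectArchitecture(hyps, link, linker)
  expect_equal(sel$winner, "Med7C_on_Med22")
  expect_false(sel$unresolved)
  expect_equal(sel$scores$violated[sel$scores$id == "Med7C_on_Med22"], 0)
  expect_equal(sel$scores$violated[sel$scores$id == "Med7C_on_Med11"], 1)
  # single hypothesis: trivially selected
  sel1 <- selectArchitecture(hyps[1], link, linker)
  expect_equal(sel1$winner, hyps[[1]]@id)
  # an undiscriminating link (within the rigid dimer) ties -> unresolved
  tie <- CrossLinkSet(data.frame(subunit_a = "Med7", residue_a = 140,
                                 subunit_b = "Med21", residue_b = 120))
  selTie <- selectArchitecture(hyps, tie, linker)
  expect_true(selTie$unresolved)
  expect_true(is.na(selTie$winner))
  expect_error(selectArchitecture(list(), link, linker), "no hypotheses")
})

test_that("planted architecture is recovered across seeded replicates", {
  wins <- vapply(1:10, function(s) architectureReplicate(s)$winner,
                 character(1))
  expect_true(all(wins == "Med7C_on_Med22"))
})

test_that("flexible placement is seeded, restraint-driven and clash-aware", {
  linker <- cbdpsLinker()
  anchor <- makeToyComplex(nChains = 2, seed = 91)$model
  # a small component generated at a known pose near the anchor
  truePose <- RigidTransform(axisAngleRotation(c(1, 0, 0), 0.4),
                             c(11, 5, 40))
  comp0 <- makeHelix(10, chainId = "X", sequence = strrep("K", 10))
  compTrue <- applyTransform(comp0, truePose)
  trueCentroid <- colMeans(caCoords(compTrue))
  # pick two restraints satisfied at the true pose
  anchCA <- caTable(anchor)
  compCA <- caCoords(compTrue)
  picks <- list()
  for (i in seq_len(nrow(anchCA))) {
    d <- sqrt(colSums((t(compCA) - as.numeric(anchCA[i, c("x", "y", "z")]))^2))
    j <- which(d < 18)
    if (length(j)) picks[[length(picks) + 1L]] <-
        data.frame(subunit_a = "X", residue_a = as.integer(rownames(compCA))[j[1]],
                   subunit_b = anchCA$chain[i], residue_b = anchCA$resno[i])
    if (length(picks) >= 2) break
  }
  restraints <- CrossLinkSet(do.call(rbind, picks))
  comp <- AssemblyModel(list(compTrue))
  res <- placeFlexible(comp, anchor, restraints, linker,
                       nSamples = 3000, seed = 7)
  expect_gt(length(res$transforms), 0)
  dmin <- min(sqrt(rowSums(sweep(res$centroids, 2, trueCentroid)^2)))
  expect_lte(dmin, 15)
  # determinism
  res2 <- placeFlexible(comp, anchor, restraints, linker,
                        nSamples = 3000, seed = 7)
  expect_equal(res2$centroids, res$centroids)
  expect_equal(res2$acceptanceRate, res$acceptanceRate)
  # contradictory restraints: anchors further apart than any placement
  # can bridge -> empty result
  farAnchor <- AssemblyModel(list(
    makeHelix(5, chainId = "A"),
    makeHelix(5, origin = c(200, 0, 0), chainId = "B")))
  contra <- CrossLinkSet(data.frame(
    subunit_a = c("X", "X"), residue_a = c(1, 10),
    subunit_b = c("A", "B"), residue_b = c(1, 1)))
  res3 <- placeFlexible(comp, farAnchor, contra, linker,
                        nSamples = 500, seed = 8)
  expect_length(res3$transforms, 0)
  # restraints absent from both models error
  ghost <- CrossLinkSet(data.frame(subunit_a = "X", residue_a = 99,
                                   subunit_b = "A", residue_b = 99))
  expect_error(placeFlexible(comp, farAnchor, ghost, linker,
                             nSamples = 10, seed = 9), "absent from both")
})
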