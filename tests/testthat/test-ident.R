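linkerFx <- function() cbdpsLinker(bridgeMassLight = 509.09798)

test_that("cross-linked mass is additive and the isotope delta is exact", {
  lk <- linkerFx()
  pa <- digest("AKGG", "trypsin", maxMissed = 1, subunit = "X")
  pa <- pa[pa$sequence == "AKGG", ]
  pb <- digest("GKGR", "trypsin", maxMissed = 1, subunit = "Y")
  pb <- pb[pb$sequence == "GKGR", ]
  light <- crosslinkedMass(pa, pb, lk, "light")
  expect_equal(light, pa$mass + pb$mass + 509.09798, tolerance = 1e-9)
  heavy <- crosslinkedMass(pa, pb, lk, "heavy")
  expect_equal(heavy - light, 8.05824, tolerance = 1e-9)
  # no reactive residue anywhere -> error (plain strings are internal)
  expect_error(crosslinkedMass("AAA", "AAA", lk), "reactive")
  # unset bridge mass refuses to compute
  expect_error(crosslinkedMass(pa, pb, cbdpsLinker()), "bridgeMassLight")
})

test_that("a linked lysine at a tryptic C-terminus is only reactive at the protein end", {
  lk <- linkerFx()
  # peptide ending in K mid-protein: K blocked
  expect_equal(
    XLArch:::reactiveSitesInPeptide("AGK", start = 1L, end = 3L,
                                    proteinLength = 10L, lk),
    1L)  # only the protein N-terminus
  # same peptide at the protein C-terminus: K reactive
  expect_equal(
    XLArch:::reactiveSitesInPeptide("AGK", start = 8L, end = 10L,
                                    proteinLength = 10L, lk),
    10L)
})

test_that("isotope doublets are found per charge within tolerance", {
  expect_equal(nrow(findDoublets(data.frame(mz = numeric(0),
                                            charge = integer(0),
                                            intensity = numeric(0)),
                                 8.05824)), 0)
  pk <- data.frame(mz = c(500.00000, 504.02912), charge = c(2L, 2L),
                   intensity = 1)
  d <- findDoublets(pk, 8.05824, tolPpm = 5)
  expect_equal(nrow(d), 1)
  expect_equal(d$light, 1)
  expect_equal(d$heavy, 2)
  # charge mismatch kills the doublet
  pk$charge[2] <- 1L
  expect_equal(nrow(findDoublets(pk, 8.05824, tolPpm = 5)), 0)
})

test_that("doublet detection is permutation invariant", {
  set.seed(5)
  pk <- data.frame(mz = c(500, 504.02912, 700, 702.68608, 800.123),
                   charge = c(2L, 2L, 3L, 3L, 2L), intensity = 1)
  ref <- findDoublets(pk, 8.05824, tolPpm = 5)
  key <- function(d) sort(paste(d$mz_light, d$mz_heavy, d$charge))
  for (i in 1:5) {
    perm <- sample(nrow(pk))
    expect_equal(key(findDoublets(pk[perm, ], 8.05824, tolPpm = 5)),
                 key(ref))
  }
})

test_that("precursor matching is exact at zero offset and rejects 2x tolerance", {
  lk <- linkerFx()
  peps <- rbind(digest("MKGGAR", "trypsin", 1, subunit = "X"),
                digest("GGKLR", "trypsin", 1, subunit = "Y"))
  pa <- peps[peps$sequence == "MKGGAR", ][1, ]
  pb <- peps[peps$sequence == "GGKLR", ][1, ]
  m <- crosslinkedMass(pa, pb, lk, proteinLengths = c(X = 6L, Y = 5L))
  hit <- matchPrecursors(m, peps, lk, tolPpm = 10)
  expect_gt(nrow(hit), 0)
  expect_equal(min(abs(hit$ppm_error)), 0)
  expect_true(any(hit$site_a == 2 & hit$site_b == 3 |
                    hit$site_a == 3 & hit$site_b == 2))
  off <- m * (1 + 20e-6)  # 2x the 10 ppm tolerance
  expect_equal(nrow(matchPrecursors(off, peps, lk, tolPpm = 10)), 0)
})

test_that("candidates are sorted by absolute ppm error", {
  lk <- linkerFx()
  peps <- digest("MKGGAKR", "trypsin", 2, subunit = "X")
  pa <- peps[1, ]
  m <- 2 * peps$mass[1] + lk@bridgeMassLight
  obs <- c(m * (1 + 4e-6), m)
  hit <- matchPrecursors(obs, peps, lk, tolPpm = 10)
  expect_true(!is.unsorted(abs(hit$ppm_error)))
})

test_that("fragment-ion scoring matches the b/y ladder with link shifts", {
  lk <- linkerFx()
  cand <- data.frame(
    sequence_a = "AG", start_a = 5L, end_a = 6L, site_a = 6L,
    sequence_b = "GK", start_b = 1L, end_b = 2L, site_b = 2L,
    stringsAsFactors = FALSE)
  # b1 of "AG" (link on G at position 2, so b1 unshifted) = A + proton
  expect_equal(scoreSpectrumMatch(cand, 72.04439, lk, tolPpm = 20), 0.25)
  expect_equal(scoreSpectrumMatch(cand, numeric(0), lk), 0)
  # full theoretical ladder scores 1
  theo <- c(XLArch:::fragmentLadder("AG", 2, peptideMass("GK") + 509.09798),
            XLArch:::fragmentLadder("GK", 2, peptideMass("AG") + 509.09798))
  expect_equal(scoreSpectrumMatch(cand, theo, lk), 1)
})

test_that("deduplication collapses unordered pairs and recomputes classes", {
  x <- CrossLinkSet(data.frame(
    subunit_a = c("A", "B"), residue_a = c(10, 20),
    subunit_b = c("B", "A"), residue_b = c(20, 10)))
  d <- deduplicateLinks(x)
  expect_equal(length(d), 1)
  expect_equal(linkTable(d)$spectral_count, 2L)
  expect_equal(linkTable(d)$link_class, "inter")
  empty <- CrossLinkSet(data.frame(subunit_a = character(0),
                                   residue_a = integer(0),
                                   subunit_b = character(0),
                                   residue_b = integer(0)))
  expect_equal(length(deduplicateLinks(empty)), 0)
})

test_that("a 55-spectrum table with the published structure collapses to 40 pairs", {
  tab <- syntheticCrossLinkTable()
  expect_equal(nrow(tab), 55)
  d <- deduplicateLinks(CrossLinkSet(tab))
  tb <- linkTable(d)
  expect_equal(nrow(tb), 40)
  expect_equal(sum(tb$link_class == "intra"), 19)
  expect_equal(sum(tb$link_class == "inter"), 21)
  expect_equal(sum(tb$spectral_count), 55)
  # the three site pairs printed in the text are present
  expect_true(any(tb$subunit_a == "Med7" & tb$residue_a == 35 &
                    tb$subunit_b == "Med7" & tb$residue_b == 103))
  expect_true(any(tb$subunit_a == "Med4" & tb$residue_a == 36 &
                    tb$subunit_b == "Med9" & tb$residue_b == 117))
  expect_true(any(tb$subunit_a == "Med10" & tb$residue_a == 62 &
                    tb$subunit_b == "Med7" & tb$residue_b == 147))
  # order of spectrum rows does not matter
  set.seed(3)
  d2 <- deduplicateLinks(CrossLinkSet(tab[sample(nrow(tab)), ]))
  expect_equal(linkTable(d2), tb)
})

test_that("zero-noise simulated precursors are fully recovered", {
  lk <- linkerFx()
  tc <- makeToyComplex(seed = 21)
  sim <- simulateCrossLinks(tc$model, tc$sequences, lk,
                            nTrue = 8, nDecoy = 0, seed = 22)
  pre <- simulatePrecursors(sim, tc$sequences, lk, noisePpm = 0, seed = 23)
  expect_equal(pre$truth$mass_heavy - pre$truth$mass_light,
               rep(8.05824, nrow(pre$truth)))
  cand <- matchPrecursors(pre$neutralMasses, pre$peptides, lk, tolPpm = 5)
  tt <- linkTable(sim$links)
  for (i in seq_len(nrow(tt))) {
    found <- any(
      (cand$subunit_a == tt$subunit_a[i] & cand$site_a == tt$residue_a[i] &
         cand$subunit_b == tt$subunit_b[i] & cand$site_b == tt$residue_b[i]) |
        (cand$subunit_b == tt$subunit_a[i] & cand$site_b == tt$residue_a[i] &
           cand$subunit_a == tt$subunit_b[i] & cand$site_a == tt$residue_b[i]))
    expect_true(found, info = sprintf("planted link %d not recovered", i))
  }
  # the peak list carries exact doublets at each charge
  db <- findDoublets(pre$peaks, 8.05824, tolPpm = 1)
  expect_gte(nrow(db), nrow(tt) * 3)
})
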