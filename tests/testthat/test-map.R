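test_that("the satisfaction cutoff is spacer plus twice the side-chain allowance", {
  expect_equal(maxCaDistance(cbdpsLinker()), 26)
  expect_equal(maxCaDistance(LinkerSpec("z", 0, 0)), 0)
  expect_equal(maxCaDistance(LinkerSpec("z", 11.4, 6)), 23.4)
})

# two single-CA "chains" at fixed positions
pointModel <- function(...) {
  pts <- list(...)
  AssemblyModel(lapply(names(pts), function(id) {
    ChainModel(id, data.frame(resno = 1L, code = "K", elety = "CA",
                              x = pts[[id]][1], y = pts[[id]][2],
                              z = pts[[id]][3]))
  }))
}

test_that("CA distances use offsets, copies, and flag unmappable sites", {
  m <- pointModel(A = c(0, 0, 0), B = c(3, 4, 0))
  r <- caDistance(m, list("A", 1), list("B", 1))
  expect_equal(r$distance, 5)
  expect_equal(caDistance(m, list("A", 1), list("A", 1))$distance, 0)
  expect_true(is.na(caDistance(m, list("A", 99), list("B", 1))$distance))
  expect_error(caDistance(m, list("Z", 1), list("B", 1)), "chain map")
  # offsets: full-length residue 101 is model residue 1 of chain A
  r <- caDistance(m, list("A", 101), list("B", 1),
                  offsets = c(A = 100L))
  expect_equal(r$distance, 5)
  # two copies of one subunit: minimum distance over copies, copy recorded
  m2 <- pointModel(A = c(0, 0, 0), B = c(3, 4, 0), C = c(30, 0, 0))
  r <- caDistance(m2, list("S", 1), list("T", 1),
                  chainMap = list(S = c("B", "C"), T = "A"))
  expect_equal(r$distance, 5)
  expect_equal(r$chain_a, "B")
})

test_that("the cutoff boundary is satisfied, strict exceedance is violated", {
  lk <- cbdpsLinker()
  m <- pointModel(A = c(0, 0, 0), B = c(26, 0, 0), C = c(26.1, 0, 0),
                  D = c(100, 0, 0))
  x2 <- CrossLinkSet(data.frame(
    subunit_a = c("A", "A", "A"), residue_a = 1,
    subunit_b = c("B", "C", "D"), residue_b = c(1, 1, 7)))
  mapped <- mapCrossLinks(m, x2, lk)
  expect_equal(mapped$status, c("satisfied", "violated", "unmappable"))
  s <- attr(mapped, "summary")
  expect_equal(unname(s[c("total", "mapped", "satisfied", "violated",
                          "unmappable")]), c(3, 2, 1, 1, 1))
})

test_that("mapping agrees with direct coordinate arithmetic on a toy complex", {
  lk <- cbdpsLinker()
  tc <- makeToyComplex(seed = 31)
  sim <- simulateCrossLinks(tc$model, tc$sequences, lk,
                            nTrue = 12, nDecoy = 4, seed = 32)
  mapped <- mapCrossLinks(tc$model, sim$links, lk)
  # independent oracle: recompute each distance from raw coordinates
  for (i in seq_len(nrow(mapped))) {
    ca1 <- caCoords(getChain(tc$model, mapped$subunit_a[i]))
    ca2 <- caCoords(getChain(tc$model, mapped$subunit_b[i]))
    d <- sqrt(sum((ca1[as.character(mapped$residue_a[i]), ] -
                     ca2[as.character(mapped$residue_b[i]), ])^2))
    expect_equal(mapped$distance[i], d, tolerance = 1e-12)
    expect_equal(mapped$status[i], if (d <= 26 + 1e-6) "satisfied"
                 else "violated")
  }
  # planted truth: satisfied count equals true links, violated equals decoys
  s <- attr(mapped, "summary")
  expect_equal(unname(s[["satisfied"]]), 12)
  expect_equal(unname(s[["violated"]]), 4)
})

test_that("satisfied count is monotone in the side-chain allowance", {
  tc <- makeToyComplex(seed = 41)
  lk0 <- cbdpsLinker()
  sim <- simulateCrossLinks(tc$model, tc$sequences, lk0,
                            nTrue = 10, nDecoy = 6, seed = 42)
  prev <- -1
  for (allow in c(0, 2, 4, 6, 10, 20)) {
    lk <- LinkerSpec("v", spacerLength = 14, sidechainAllowance = allow)
    s <- attr(mapCrossLinks(tc$model, sim$links, lk), "summary")
    expect_gte(unname(s[["satisfied"]]), prev)
    prev <- s[["satisfied"]]
  }
})

test_that("per-pair results are invariant to input order", {
  lk <- cbdpsLinker()
  tc <- makeToyComplex(seed = 51)
  sim <- simulateCrossLinks(tc$model, tc$sequences, lk,
                            nTrue = 8, nDecoy = 3, seed = 52)
  mapped <- mapCrossLinks(tc$model, sim$links, lk)
  tb <- linkTable(sim$links)
  set.seed(53)
  perm <- sample(nrow(tb))
  mapped2 <- mapCrossLinks(tc$model, CrossLinkSet(tb[perm, ]), lk)
  key <- function(df) df[order(df$subunit_a, df$residue_a, df$subunit_b,
                               df$residue_b),
                         c("distance", "status")]
  expect_equal(key(mapped2), key(mapped), ignore_attr = TRUE)
})
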