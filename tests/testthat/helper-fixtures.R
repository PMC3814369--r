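# shared fixtures: tiny PDB texts, a Mediator-like selection geometry,
# and the replicate harness for the planted-architecture simulation

toyPdbLines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.970   2.846   0.000  1.00  0.00           C",
    "END")
}

altlocPdbLines <- function() {
  c("ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA  GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END")
}

# random sequence with lysines at a fixed fraction, K forced at `forceK`
helixSequence <- function(n, forceK = integer(0), lysineFraction = 0.1) {
  pool <- setdiff(strsplit("ACDEFGHILMNPQRSTVWY", "")[[1]], character(0))
  aa <- sample(pool, n, replace = TRUE)
  aa[runif(n) < lysineFraction] <- "K"
  aa[forceK] <- "K"
  paste(aa, collapse = "")
}

# Mediator-like two-hypothesis geometry: a mobile Med7C/Med21 dimer that
# can overlay either of two template positions (near/far), and a fixed
# Med10 chain near the "Med22" position. The true arrangement is the
# near one ("Med7C_on_Med22").
selectionFixture <- function(seed = 1) {
  set.seed(seed)
  nres <- 30L
  # lysine-dense toy chains so both near (true) and far (decoy) site
  # pairs exist in the 45-Angstrom-long arrangement
  seqMed7 <- helixSequence(nres, forceK = 147 - 131 + 1,
                           lysineFraction = 0.25)
  seqMed21 <- helixSequence(nres, lysineFraction = 0.25)
  seqMed10 <- helixSequence(nres, forceK = 62 - 50 + 1,
                            lysineFraction = 0.25)
  med7 <- makeHelix(nres, origin = c(0, 0, 0), chainId = "Med7",
                    sequence = seqMed7, startRes = 131L)
  med21 <- makeHelix(nres, origin = c(0, 10, 0), chainId = "Med21",
                     sequence = seqMed21, startRes = 111L)
  med10 <- makeHelix(nres, origin = c(10, 10, 0), chainId = "Med10",
                     sequence = seqMed10, startRes = 50L)
  template <- AssemblyModel(list(
    makeHelix(nres, origin = c(0, 0, 0), chainId = "Med22"),
    makeHelix(nres, origin = c(60, 0, 0), chainId = "Med11"),
    makeHelix(nres, origin = c(10, 10, 0), chainId = "Med8")))
  dimer <- AssemblyModel(list(med7, med21))
  alignments <- list(
    list(component = "dimer", anchorChain = "Med7", templateChain = "Med22",
         map = AlignmentMap("Med7", "Med22", cbind(131:160, 1:30))),
    list(component = "dimer", anchorChain = "Med7", templateChain = "Med11",
         map = AlignmentMap("Med7", "Med11", cbind(131:160, 1:30))),
    list(component = "Med10", anchorChain = "Med10", templateChain = "Med8",
         map = AlignmentMap("Med10", "Med8", cbind(50:79, 1:30))))
  choices <- list(
    Med7C_on_Med22 = c(dimer = "Med22", Med10 = "Med8"),
    Med7C_on_Med11 = c(dimer = "Med11", Med10 = "Med8"))
  truth <- AssemblyModel(list(med7, med21, med10))  # the near arrangement
  list(components = list(dimer = dimer, Med10 = AssemblyModel(list(med10))),
       template = template, alignments = alignments, choices = choices,
       truth = truth,
       sequences = c(Med7 = strrep("A", 160), Med21 = strrep("A", 140),
                     Med10 = strrep("A", 104)))
}

# one replicate of the planted-architecture recovery simulation:
# sample links (true + ~10% decoys) from the true arrangement, enumerate
# both mappings, select by cross-link satisfaction
architectureReplicate <- function(seed, nTrue = 18, nDecoy = 2) {
  fx <- selectionFixture(seed)
  linker <- cbdpsLinker()
  seqs <- c(Med7 = chainSequenceString(getChain(fx$truth, "Med7")),
            Med21 = chainSequenceString(getChain(fx$truth, "Med21")),
            Med10 = chainSequenceString(getChain(fx$truth, "Med10")))
  sim <- simulateCrossLinks(truthModelFullNumbering(fx), seqs, linker,
                            nTrue = nTrue, nDecoy = nDecoy, seed = seed + 1)
  hyps <- enumerateArchitectures(fx$components, fx$template,
                                 fx$alignments, fx$choices)
  sel <- selectArchitecture(hyps, sim$links, linker)
  list(winner = sel$winner, scores = sel$scores, sim = sim)
}

# the fixture chains carry full-length residue numbering already, so the
# truth model can be used directly for link simulation
truthModelFullNumbering <- function(fx) fx$truth

# sequence string padded so that position i of the chain's numbering is
# residue i of the string (simulateCrossLinks works in full-length
# numbering)
chainSequenceString <- function(chain) {
  sq <- chainSequence(chain)
  res <- as.integer(names(sq))
  out <- rep("A", max(res))
  out[res] <- sq
  # positions outside the modeled range must not create reactive sites
  out[setdiff(seq_len(max(res)), res)] <- "A"
  paste(out, collapse = "")
}
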