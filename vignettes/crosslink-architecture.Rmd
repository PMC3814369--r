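---
title: "Cross-link-guided architectural modeling: methods and design"
author: "XLArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-link-guided architectural modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(XLArch)
```

## The problem and the model

Large, flexible protein complexes often resist crystallization as a
whole even when structures of their subcomplexes exist. Chemical
cross-linking with an amine-reactive, isotope-coded reagent followed by
mass spectrometry (XL-MS) yields a list of lysine pairs that were
simultaneously within reach of the linker. Each pair is a weak but
honest distance restraint: if a model places two linked lysines so that
their Cα atoms are further apart than the linker can physically span,
the model is contradicted.

`XLArch` turns this into a pipeline with four stages.

**1. Identification.** Proteins are digested in silico (trypsin: after
K/R except before proline; GluC: after glutamate; or their union), and
cross-linked peptide pairs are matched to observed precursor masses:

$$ m_\text{pair} = m_\text{pep,a} + m_\text{pep,b} + m_\text{bridge}
   \;(+\,\Delta_\text{iso}\ \text{for the heavy form}) $$

with masses from the standard monoisotopic residue table plus one water
per peptide. Isotope-coded linkers produce light/heavy doublets in MS1
separated by $\Delta_\text{iso}/z$; `findDoublets()` exploits exactly
that signature. Candidate support can be checked against MS2 via
singly charged b/y ladders in which ions spanning the linked residue are
shifted by the partner peptide plus bridge mass; the score is the
matched fraction of theoretical ions — deliberately transparent rather
than probabilistic.

A chemical detail with combinatorial consequences: a cross-linked lysine
is no longer a trypsin substrate, so a peptide *ending* in the linked
lysine cannot exist (unless the peptide ends at the protein C-terminus).
Candidate enumeration therefore admits a C-terminal lysine as a link
site only through missed-cleavage peptides.

**2. Distance mapping.** A mapped cross-link is *satisfied* when

$$ d(\mathrm{C}\alpha_i, \mathrm{C}\alpha_j) \le L_\text{spacer}
   + 2\,L_\text{side chain}, $$

14 + 2 × 6 = 26 Å for CBDPS on lysines. We use Cα atoms, not side-chain
nitrogens, because full-length side chains are rarely modeled at the
accuracy this method produces; the two-side-chain allowance absorbs
them. Pairs whose residues are absent from the model are *unmappable*,
a category kept distinct from *violated*.

**3. Assembly.** The numerical core is the Kabsch algorithm:
least-squares optimal proper rotation plus translation, with the
reflection branch of the SVD corrected so the determinant is always +1.
On top of it sit:

- *alignment-anchored superposition*: Kabsch over the Cα pairs of a
  residue–residue alignment. Secondary-structure-matching tools do this
  interactively; anchoring on an explicit alignment makes the operation
  deterministic and auditable.
- *backbone threading*: a homology model at architectural accuracy,
  built by transferring template backbone coordinates through the
  alignment and renumbering to the target. No side chains, no loop
  closure — claims made from these models are about subunit placement,
  not atomic detail, and per-residue provenance records where every
  coordinate came from.
- *rigid-body assembly*: placing a second dimer copy by a
  crystal-packing transform, with the minimum inter-dimer Cα distance
  recorded as an interface sanity metric.
- *architecture enumeration and selection*: when a template offers two
  structurally equivalent chains a homolog could overlay, both
  arrangements are built and scored by cross-link satisfaction. The
  winner has the fewest violations, ties broken by most satisfied
  links; a residual tie is surfaced as unresolved, never broken
  silently, because a silent arbitrary choice would masquerade as
  evidence.
- *restraint-guided placement*: for a subcomplex tethered by only a few
  cross-links, we sample rigid placements (rotations uniform over SO(3)
  by quaternion sampling; centroid translations uniform in the anchor's
  bounding box padded by the cutoff) and keep those satisfying every
  restraint without steric clash. The output is the set of admissible
  poses and the acceptance rate — deliberately *not* a single pose,
  since a handful of 26 Å restraints rarely determines one.

**4. Reporting.** Residue coverage against the full-length sequences
(unique full-length residues with a modeled Cα, copies counted once),
cross-link tallies, and model extent, operationalized as the maximum
pairwise Cα–Cα distance because "length" claims about extended models
have no other natural metric at this resolution. Percentages are
rounded to the nearest integer, matching how such coverage figures are
conventionally reported.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `spacerLength` (CBDPS) | 14 | Å | linker arm geometry |
| `sidechainAllowance` | 6 | Å per residue | lysine side-chain reach |
| `heavyLightDelta` (CBDPS-H8/D8) | 8.05824 | Da | H8/D8 substitution; treated as a configuration constant, not derived |
| `bridgeMassLight` | none — must be supplied | Da | the intact-bridge monoisotopic mass is vendor documentation, not something to guess; mass functions refuse to run without it |
| MS1 tolerance (`tolPpm` of `matchPrecursors`) | 10 | ppm | typical for Orbitrap-class precursor mass accuracy |
| MS2 tolerance (`scoreSpectrumMatch`) | 20 | ppm | fragment ions are measured less accurately than precursors |
| GluC specificity | E only | — | glutamate cleavage is robust; aspartate cleavage is buffer-dependent, so it is opt-in (`glucResidues = c("E","D")`) |
| `clashCutoff` (`placeFlexible`) | 4.0 | Å | below any plausible Cα–Cα contact distance between folded components |
| cutoff comparison tolerance | 1e-6 | Å | a pair at exactly the cutoff is satisfied (the criterion is ≤), and float noise must not flip it |

Residue numbering: cross-link sites live in full-length subunit
coordinates (1-based). Structure files may number differently; a
per-chain integer offset (full-length = model residue + offset)
reconciles them, and the translation is invertible by construction.

## The synthetic-data generator

`makeHelix()` places Cα atoms on an ideal α-helix (1.5 Å rise, 100°
twist, 2.3 Å radius — giving the textbook ~3.8 Å consecutive-Cα
spacing). `makeToyComplex()` builds pairs of parallel helices as toy
dimers, places them by planted rigid transforms (by default two dimers
22 Å apart, adjacent as interacting subcomplexes would be), and draws
random sequences with lysines at a set fraction. The default chain
length (60 residues) and lysine fraction (0.1, slightly above the ~7%
natural frequency) were chosen once so that a toy complex offers enough
reactive-site pairs on both sides of the 26 Å cutoff for sampling;
they are study conditions, not tuning knobs. The manifest records the
planted transforms and lysine positions, so the generator doubles as
the oracle in tests: `simulateCrossLinks()` samples true links from
within the cutoff and decoys from beyond it, and
`simulatePrecursors()` emits light/heavy neutral masses and
doublet-consistent m/z rows at charges 2–4.

One modeling choice in the precursor simulator deserves a note: mass
noise is applied to the light mass and the heavy mass is set to noisy
light + exact delta. The doublet *spacing* is what tags
linker-containing species, and within one spectrum the two isotope
forms share calibration error; independent noise on both would destroy
the spacing in a way real instruments do not.

What the generator does **not** emulate: real fold geometry (helices
are straight, no super-coiling), solvent accessibility (every lysine is
reactable), isotope envelopes, fragment intensities,
retention time, or false identifications beyond planted mass decoys.
Passing tests therefore demonstrate the pipeline's internal
correctness — exact recovery of planted truth at zero noise, correct
satisfied/violated splits by construction — not its robustness to the
pathologies of real spectra, which are out of scope.

## Numerical and design choices

- **Kabsch degeneracies.** Fewer than 3 points or collinear points are
  rejected. Mirror-image inputs return the best *proper* rotation
  (determinant +1), verified in tests against 1,000 random-rotation
  probes per instance.
- **Alignment ranges.** Range shorthand (`"46-127:19-108"`) with
  unequal lengths — which happens when a gapped alignment is
  summarized by its end points — pairs positions from the range starts
  and leaves the longer tail unaligned. Threading a 82-residue query
  range therefore yields exactly 82 modeled residues. Users with the
  true gapped alignment should pass the explicit pair list.
- **Multiple chain copies.** When a subunit occurs twice (two dimer
  copies in a tetramer), a cross-link is satisfied if *any* copy
  explains it: the minimum distance over copies is used and the chosen
  copy recorded.
- **Deduplication identity.** Pairs are unordered; rows are
  canonicalized (lexicographically smaller site first) before
  collapsing, and spectral counts accumulate.
- **PDB dialect.** Fixed-column ATOM records; alternate locations keep
  the first-listed conformer; insertion codes are rejected with a clear
  error (the intended templates have none, and silently renumbering
  inserted residues would corrupt site mapping). Writing rejects
  coordinates that overflow the 8.3 field and residue numbers beyond
  9999. mmCIF and multi-model NMR files are out of scope.
- **Selection tie-breaks.** Explicit and surfaced (`unresolved = TRUE`,
  `winner = NA`); downstream code must decide, not this package.
- **Problem sizes in the shipped tests.** Toy complexes of 4 × 60
  residues, ~20 links per replicate, 100 replicates for the
  architecture-recovery property, 1,000 rotation probes per Kabsch
  instance, 3,000 samples for flexible placement — sizes at which the
  whole suite completes in well under a minute while every property is
  exercised at meaningful scale.

## Limitations

- Identification is a transparent re-implementation of
  precursor/fragment matching, not a replacement for dedicated XL-MS
  search engines: no FDR estimation, no charge deconvolution, no
  dead-end or loop-link species.
- Threading transfers backbone coordinates only; interface claims at
  side-chain resolution are beyond what these models support.
- Cross-link satisfaction uses straight-line Cα distances, not
  solvent-accessible surface paths; buried shortcuts through a model
  are not penalized.
- A cross-link set systematically biased by differential lysine
  reactivity or enrichment efficiency will bias any architecture scored
  on it; the package reports satisfaction tallies and leaves the
  judgment of restraint quality to the analyst.
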