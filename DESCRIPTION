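Package: XLArch
Title: Cross-Link-Guided Architectural Modeling of Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives architectural models of multi-subunit protein
    complexes from lysine-lysine chemical cross-linking mass spectrometry
    (XL-MS). Provides in-silico protease digestion and isotope-doublet
    precursor matching for cross-linked peptides, distance-based mapping
    of cross-links onto structures with a spacer-derived Calpha-Calpha
    cutoff, alignment-anchored backbone threading, rigid-body assembly by
    least-squares superposition, enumeration and cross-link-satisfaction
    scoring of alternative architectures, restraint-guided placement of
    flexibly tethered subcomplexes, coverage reporting, and a synthetic
    helical-complex generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
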