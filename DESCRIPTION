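Package: ceopt
Title: Collision-Energy Optimization for Tryptic and Nontryptic
    Bottom-Up Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive optimal collision-induced dissociation (CID)
    collision energies (CE) for bottom-up proteomics from peptide-spectrum
    match score tables acquired over a CE-offset grid. Aggregates per-run
    search-engine scores into per-(peptide, charge) score series, applies
    engine-specific inclusion filters, fits one- and two-component Gaussian
    models to locate unimodal and bimodal score optima, fits per-charge
    linear optimal-CE(m/z) trend lines per enzyme class, converts settings
    between eV and normalized collision energy (NCE%), computes normalized
    b/y fragment-ion count and intensity curves versus CE shift, and scores
    competing CE methods by peptide hits, protein sequence coverage, and
    peptide-level score winners. A seedable synthetic-experiment generator
    provides ground truth for every stage, covering five enzyme
    specificities (trypsin, Arg-C, Glu-C, Asp-N, chymotrypsin).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
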