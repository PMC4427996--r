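Package: ParalogSites
Title: Clade-Aware Alignment Decomposition and Character-Site Detection for
    Deeply Divergent Paralog Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing protein multiple sequence alignments of
    paralogous families that each split into a rare and a common form, as in
    the seryl- and threonyl-tRNA synthetase (SerRS/ThrRS) paralog pair.
    Implements clade-aware alignment decomposition (concatenating mutually
    exclusive globally well-aligned and clade-specific well-aligned column
    sets, with per-column provenance), relaxed symplesiomorphy and
    synapomorphy character-site detection with physiochemical residue-class
    grouping, a surrogate per-column alignment-quality scorer, and a
    synthetic-alignment generator that contrasts genuine deep divergence
    with long-branch-attraction scenarios using planted character sites
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
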