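Package: serpintools
Title: Annotation, Nomenclature and Expression Analysis of Plant Serpins
Version: 0.1.0
Authors@R:
    person("serpintools", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for annotating plant serpin protein sequences: locates the
    reactive-centre loop (RCL) hinge from the conserved P17 glutamate, assigns
    canonical P positions, derives reactive-centre (P2-P1') based names,
    classifies serpins as inhibitory or non-inhibitory, applies auditable
    landmark-based gene-model curation edits, computes percent-identity
    matrices and neighbour-joining trees with bootstrap support, transforms
    qPCR crossing-point values into relative transcript abundances, and
    predicts PCR amplicons in silico. Ships the rice (Oryza sativa cv.
    Nipponbare) serpin reference tables and a synthetic-data generator with
    planted ground truth so every operation is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
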