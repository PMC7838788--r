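Package: dmsparis
Title: Comparative RNA Secondary-Structure Analysis from DMS-Seq and PARIS Probing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares in-cell RNA structure probing data against a reference
    secondary-structure model of a transcript. Classifies per-nucleotide
    DMS-Seq read counts into structured/unstructured calls by a read-count
    threshold, scores hairpin disruption and novel base-pair losses between
    conditions, filters and compresses PARIS crosslink duplex reads into
    supported duplex groups classified as consistent with or divergent from
    the model, and overlays functional annotations (miRNA seed sites, protein
    sites, RNA modifications, SNPs, somatic mutations) to report accessibility
    changes. Includes a from-scratch Mann-Whitney U test with tie handling and
    a synthetic-data generator with ground-truth perturbations so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
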