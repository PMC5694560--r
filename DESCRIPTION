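Package: qtlmeta
Title: Consensus Genetic Maps, Meta-QTL Analysis and Synteny-Based
    Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates independent quantitative-genetic studies into a
    single framework: merges genetic maps into a consensus map by
    homothetic (piecewise-linear) projection over shared markers after
    removing order-inconsistent markers, projects QTL peaks and
    confidence intervals onto the consensus coordinates, clusters
    co-locating QTLs into meta-QTLs by weighted Gaussian maximum
    likelihood over contiguous partitions with information-criterion
    model selection, anchors an ordered gene list (syntenome) to the
    consensus map to enumerate genes under meta-QTL intervals, and
    scores candidate genes from tabular alignment output by cumulative
    identity (CIP) and cumulative alignment-length (CALP) percentages.
    Includes seeded generators of synthetic maps, QTL studies, gene
    orders and alignment tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
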