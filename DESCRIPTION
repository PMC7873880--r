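Package: pleiolink
Title: Distinguishing Pleiotropy from Linkage in Mixed-Model GWAS by Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for asking whether univariate and two-trait
    multivariate linear mixed-model genome-wide association scans can tell a
    single pleiotropic quantitative trait nucleotide (QTN) apart from two
    linked, non-pleiotropic QTNs. Provides a synthetic SNP-panel generator
    with tunable, distance-dependent linkage-disequilibrium decay emulating
    contrasting maize-like and soybean-like panels; QTN selection under
    independent, linked (direct and indirect LD control) and pleiotropic
    architectures; single-QTN additive trait simulation at specified
    heritabilities; univariate and multivariate mixed-model association scans
    with a VanRaden genomic relationship matrix; Benjamini-Hochberg FDR
    control; and window-based detection-rate, spurious-pleiotropy and error
    rate summaries over replicated scenario grids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
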