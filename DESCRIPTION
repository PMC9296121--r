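Package: svmrd
Title: Patient-Specific Structural-Variant ddPCR Assays for Residual Disease
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for measurable residual disease (MRD) monitoring in acute
    lymphoblastic leukemia using patient-specific structural-variant (SV)
    breakpoint junctions. Parses SV calls (VCF breakends and symbolic records),
    filters and ranks candidate junctions by clonal prevalence, sequence
    uniqueness and overlap with recurrent leukemia loci, reconstructs junction
    sequences, designs breakpoint-spanning droplet digital PCR (ddPCR)
    primer/probe assays under amplicon-size and melting-temperature
    constraints, verifies assay specificity by exact-match in-silico PCR,
    converts droplet counts to copy estimates by Poisson partition statistics,
    classifies positivity, computes copies per ml of liquid biopsy and
    target:reference ratios corrected for target multiplexing, determines
    limits of detection and quantifiability from serial dilution series, and
    simulates every input (genomes with implanted SVs, droplet counts,
    dilution series) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    graphics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
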