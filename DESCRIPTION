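Package: oncopassenger
Title: Copy-Number Dosage Coupling, Methylation Compensation and Survival
    Screening for Onco-Passenger Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study onco-passenger genes, i.e. genes co-amplified or
    co-deleted with driver oncogenes in large chromosomal segments. Maps
    copy-number segmentation to gene-level log-ratios, classifies genes into
    dosage-coupled (CR-high) and dosage-uncoupled (CR-low) groups from the
    bimodal distribution of per-gene CNV-mRNA correlations, quantifies DNA
    methylation compensation of copy-number changes, screens genes by
    univariate Cox proportional-hazards regression, and scores pathways with
    a value-biased random-walk flux statistic. Includes a synthetic
    multi-omic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    jsonlite
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
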