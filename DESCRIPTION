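Package: mmrsig
Title: Somatic Mutational Signatures, LOH and Microsatellite Instability
    for Mismatch-Repair-Deficient Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A somatic-analysis toolkit for paired tumor/germline exomes of
    mismatch-repair (MMR) deficient versus proficient lesions: caller
    intersection and depth/allele-frequency filtering of somatic variants,
    construction of 96-trinucleotide-context catalogs, refitting of catalogs
    against a panel of 30 predefined mutational signatures by cosine-similarity
    maximization, tumor mutational burden, a loss-of-heterozygosity caller over
    paired variant allele frequencies, microsatellite detection and instability
    scoring, MMR second-hit classification, and pooled two-sample group
    comparisons. Includes a synthetic-data generator producing references,
    germline and dual-caller tumor VCFs with known truth, so the whole pipeline
    is testable without sequence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
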