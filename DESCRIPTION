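Package: somaT2T
Title: Somatic Mutation Burden and Epigenome Remodeling on Donor-Specific
    Diploid Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of somatic variation called against a
    donor-specific diploid genome assembly of a paired tumor/normal sample:
    haploid copy-number (hCN) estimation, segmentation and classification
    from coverage ratios; a multi-stage somatic SNV/DNV filter cascade;
    SBS-96/DBS-78 mutational spectra with trinucleotide-frequency
    normalization, predicted mutability, non-negative least-squares
    signature fitting and the aggregate mutation spectrum distance (AMSD)
    permutation test; centromere dip region (CDR) detection from CpG
    methylation in bulk and on single molecules; telomere variant repeat
    (TVR) profiling and detection of somatic telomere restructuring; and
    haplotype-selective chromatin accessibility analysis. A synthetic-data
    module generates every input with the statistical structure the
    analyses assume, so the full pipeline is testable without sequencing
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
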