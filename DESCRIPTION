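Package: histoneRx
Title: Histone PTM Quantification from Derivatized LC-MS/MS and Spike-In
    Normalized ChIP-Rx Domain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary quantitative epigenomics analyses.
    The proteomics arm models histone H3 tail peptides under heavy-isotopic
    reductive dimethylation and N-terminal propionylation, enumerates
    modification isoforms, computes precursor and b/y fragment masses,
    resolves isobaric positional isomers by unique-fragment-ion ratios, and
    turns extracted-ion-chromatogram peak areas into relative PTM abundances
    (normalized to 100 percent per peptide) and log base-1.5 fold-change
    matrices. The genomics arm computes spike-in (Rx) normalization factors
    and normalized binned coverage, interval means and metagene/anchor
    profiles, partitions peak sets into condition-specific and shared
    clusters, assigns peaks to genes over TSS-TES windows, and classifies
    genes by fold change of normalized signal. Ground-truthed synthetic-data
    generators for both arms make every stage testable without external
    downloads.
License: MIT + file LICENSE
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
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
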