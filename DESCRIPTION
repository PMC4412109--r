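Package: chromameth
Type: Package
Title: Simulation and Analysis of Chromatin-Guided De Novo DNA Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of how chromatin features shape de novo
    DNA methylation deposited by an ectopic DNMT3B in a naive (unmethylated)
    genome. Provides a seeded synthetic chromatin landscape generator
    (phased nucleosome arrays with nucleosome-free regions, promoter
    H3K4me3, 3'-ramped H3K36me3, Pol II, an unmethylated spike-in contig,
    and binomial bisulfite read counts with a non-conversion error),
    context-resolved methylation quantification (CpG/CpHpG/CpHpH), spike-in
    non-conversion estimation, anchored and metagene profiling with
    autocorrelation-based periodicity detection, linker-versus-core
    methylation contrasts, decile stratification, Spearman correlation
    matrices, mutant normalization (total-methylation and delta-delta-Ct
    scaling), and a binned log-linear model predicting methylation or
    DNMT3B occupancy from chromatin marks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
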