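# Small landscape for fast unit tests
tinyConfig <- function(...) {
    args <- list(nChromosomes = 1, chromLength = 30000,
                 spikeLength = 10000, nGenes = 10, coverageMean = 10,
                 seed = 1L)
    args <- utils::modifyList(args, list(...))
    do.call(syntheticConfig, args)
}

# Memoized simulations at the reference (default) configuration, shared
# across test files so each (genotype, seed) pair is simulated once.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(genotype = "WT", seed = 1, config = syntheticConfig()) {
    key <- paste(genotype, seed, digest_cfg(config), sep = "_")
    if (is.null(.simCache[[key]]))
        .simCache[[key]] <- simulateExperiment(config, genotype, seed)
    .simCache[[key]]
}

digest_cfg <- function(config) {
    paste(config@nChromosomes, config@chromLength, config@nGenes,
          config@coverageMean, sep = "x")
}

# A deterministic hand-made methylation table
handMethTable <- function() {
    methylationTable(data.frame(
        chrom = c("c1", "c1", "c1", "c1", "c1", "c1"),
        pos = c(0, 4, 8, 12, 16, 20),
        strand = c("+", "+", "-", "+", "-", "+"),
        context = c("CpG", "CpG", "CpHpG", "CpHpG", "CpHpH", "CpHpH"),
        mc = c(4, 2, 1, 0, 0, 2),
        cov = c(10, 10, 10, 5, 10, 10)))
}
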