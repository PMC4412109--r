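#' Build a synthetic-landscape configuration
#'
#' Returns a validated [SyntheticConfig-class]. The defaults define the
#' package's reference landscape: two 200-kb chromosomes plus a 20-kb
#' unmethylated spike-in contig, 150 genes, a 170-bp nucleosome repeat
#' length with 73-bp core half-width and 80-bp NFR half-width, a baseline
#' CpG methylation probability of 0.035 with a 1.5-fold linker preference
#' and a 0.15-amplitude, 10-bp helical modulation inside cores, mark
#' weights w4 = 1.2 (H3K4me3 suppression) and w36 = 0.8 (H3K36me3
#' promotion), a non-CpG baseline of 5e-4, a bisulfite non-conversion rate
#' of 0.0027, and mean coverage 20. Deletion genotypes (set1, set2, dot1)
#' express the induced methyltransferase at 0.6 of the wild-type level.
#'
#' @param nChromosomes,chromLength,spikeLength genome geometry (bp).
#' @param gcFraction,cpgEnrichment base composition controls.
#' @param nGenes,geneLengthMean,geneLengthSd,expressionSdLog gene model.
#' @param nrl,coreHalfwidth,nfrHalfwidth,jitterSd nucleosome model (bp).
#' @param p0,linkerFactor,helicalAmplitude,helicalPeriod,w4,w36,pNonCpG
#'   methylation probability model.
#' @param nonconversion,coverageMean bisulfite read model.
#' @param expressionScale named DNMT3B activity multiplier per genotype.
#' @param seed default random seed.
#' @return a [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(nChromosomes = 1, chromLength = 20000, nGenes = 6)
#' cfg
#' @export
syntheticConfig <- function(nChromosomes = 2,
                            chromLength = 200000,
                            spikeLength = 20000,
                            gcFraction = 0.4,
                            cpgEnrichment = 1.0,
                            nGenes = 150,
                            geneLengthMean = 1400,
                            geneLengthSd = 400,
                            expressionSdLog = 0.5,
                            nrl = 170,
                            coreHalfwidth = 73,
                            nfrHalfwidth = 80,
                            jitterSd = 5,
                            p0 = 0.035,
                            linkerFactor = 1.5,
                            helicalAmplitude = 0.15,
                            helicalPeriod = 10,
                            w4 = 1.2,
                            w36 = 0.8,
                            pNonCpG = 5e-4,
                            nonconversion = 0.0027,
                            coverageMean = 20,
                            expressionScale = c(WT = 1, set1 = 0.6,
                                                set2 = 0.6, dot1 = 0.6),
                            seed = 1L) {
    obj <- try(new("SyntheticConfig",
                   nChromosomes = as.integer(nChromosomes),
                   chromLength = as.integer(chromLength),
                   spikeLength = as.integer(spikeLength),
                   gcFraction = as.numeric(gcFraction),
                   cpgEnrichment = as.numeric(cpgEnrichment),
                   nGenes = as.integer(nGenes),
                   geneLengthMean = as.numeric(geneLengthMean),
                   geneLengthSd = as.numeric(geneLengthSd),
                   expressionSdLog = as.numeric(expressionSdLog),
                   nrl = as.integer(nrl),
                   coreHalfwidth = as.integer(coreHalfwidth),
                   nfrHalfwidth = as.integer(nfrHalfwidth),
                   jitterSd = as.numeric(jitterSd),
                   p0 = as.numeric(p0),
                   linkerFactor = as.numeric(linkerFactor),
                   helicalAmplitude = as.numeric(helicalAmplitude),
                   helicalPeriod = as.numeric(helicalPeriod),
                   w4 = as.numeric(w4),
                   w36 = as.numeric(w36),
                   pNonCpG = as.numeric(pNonCpG),
                   nonconversion = as.numeric(nonconversion),
                   coverageMean = as.numeric(coverageMean),
                   expressionScale = expressionScale,
                   seed = as.integer(seed)),
               silent = TRUE)
    if (inherits(obj, "try-error"))
        .paramError(sub(".*invalid class[^:]*: *", "",
                        conditionMessage(attr(obj, "condition"))))
    obj
}

.checkGenotype <- function(genotype) {
    if (length(genotype) != 1L || !genotype %in% GENOTYPES)
        .paramError(sprintf("genotype must be one of %s",
                            paste(GENOTYPES, collapse = ", ")))
    genotype
}

#' Convert a configuration to / from a plain list
#'
#' Round-trips all SyntheticConfig fields through a named list, e.g. for
#' YAML serialization. Unknown keys are rejected.
#'
#' @param config a [SyntheticConfig-class].
#' @return `configAsList`: a named list; `configFromList`: a
#'   [SyntheticConfig-class].
#' @export
configAsList <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    nms <- slotNames("SyntheticConfig")
    out <- lapply(nms, function(nm) slot(config, nm))
    names(out) <- nms
    out$expressionScale <- as.list(out$expressionScale)
    out
}

#' @rdname configAsList
#' @param x a named list of configuration fields (as from [configAsList]).
#' @export
configFromList <- function(x) {
    nms <- slotNames("SyntheticConfig")
    unknown <- setdiff(names(x), nms)
    if (length(unknown))
        .paramError(sprintf("unknown configuration keys: %s",
                            paste(unknown, collapse = ", ")))
    if ("expressionScale" %in% names(x))
        x$expressionScale <- unlist(x$expressionScale)
    do.call(syntheticConfig, x)
}
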