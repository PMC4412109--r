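#' @import methods
#' @importFrom S4Vectors metadata metadata<-
NULL

GENOTYPES <- c("WT", "set1", "set2", "dot1")

#' Parameters of the synthetic chromatin landscape
#'
#' Holds every tunable of the generator: genome composition, gene geometry,
#' nucleosome phasing, the chromatin-mark weights of the methylation model,
#' and the bisulfite sequencing error model. Defaults describe a compact
#' two-chromosome landscape whose statistical structure mirrors a budding
#' yeast strain ectopically expressing DNMT3B: ~170 bp nucleosome repeat
#' length, NFR-flanked phased arrays, a 50% linker preference, a 10 bp
#' helical modulation within nucleosome cores, and a 0.27% bisulfite
#' non-conversion rate estimated from an unmethylated spike-in contig.
#'
#' @slot nChromosomes number of non-spike-in chromosomes.
#' @slot chromLength length of each chromosome (bp).
#' @slot spikeLength length of the unmethylated spike-in contig (bp, >= 10 kb).
#' @slot gcFraction genome GC content in [0, 1].
#' @slot cpgEnrichment multiplier on the expected CpG dinucleotide frequency
#'   relative to independent base sampling (1 = no enrichment).
#' @slot nGenes number of genes to place.
#' @slot geneLengthMean,geneLengthSd gene length distribution (bp).
#' @slot expressionSdLog sd of log expression (log-normal, meanlog 0).
#' @slot nrl nucleosome repeat length (bp).
#' @slot coreHalfwidth half-width of the nucleosome core around the dyad (bp).
#' @slot nfrHalfwidth half-width of the nucleosome-free regions flanking
#'   gene boundaries (bp).
#' @slot jitterSd sd of intergenic dyad spacing jitter (bp); gene-proximal
#'   arrays are phased without jitter.
#' @slot p0 baseline CpG methylation probability.
#' @slot linkerFactor multiplicative preference for linker over core DNA.
#' @slot helicalAmplitude,helicalPeriod amplitude and period (bp) of the
#'   helical methylation modulation inside nucleosome cores.
#' @slot w4 H3K4me3 suppression weight (exponential model).
#' @slot w36 H3K36me3 promotion weight (exponential model).
#' @slot pNonCpG baseline methylation probability at non-CpG cytosines.
#' @slot nonconversion bisulfite non-conversion error rate.
#' @slot coverageMean mean read coverage per cytosine (Poisson).
#' @slot expressionScale named multiplicative DNMT3B activity per genotype
#'   (WT, set1, set2, dot1); deletion strains express less of the induced
#'   enzyme.
#' @slot seed default random seed.
#' @export
setClass("SyntheticConfig", representation(
    nChromosomes = "integer",
    chromLength = "integer",
    spikeLength = "integer",
    gcFraction = "numeric",
    cpgEnrichment = "numeric",
    nGenes = "integer",
    geneLengthMean = "numeric",
    geneLengthSd = "numeric",
    expressionSdLog = "numeric",
    nrl = "integer",
    coreHalfwidth = "integer",
    nfrHalfwidth = "integer",
    jitterSd = "numeric",
    p0 = "numeric",
    linkerFactor = "numeric",
    helicalAmplitude = "numeric",
    helicalPeriod = "numeric",
    w4 = "numeric",
    w36 = "numeric",
    pNonCpG = "numeric",
    nonconversion = "numeric",
    coverageMean = "numeric",
    expressionScale = "numeric",
    seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
    chk(object@nChromosomes >= 1L, "nChromosomes must be >= 1")
    chk(object@chromLength >= 1000L, "chromLength must be >= 1000 bp")
    chk(object@spikeLength >= 10000L, "spikeLength must be >= 10 kb")
    chk(object@gcFraction >= 0 && object@gcFraction <= 1,
        "gcFraction must lie in [0, 1]")
    chk(object@cpgEnrichment >= 0, "cpgEnrichment must be non-negative")
    chk(object@nGenes >= 0L, "nGenes must be non-negative")
    chk(object@geneLengthMean > 0, "geneLengthMean must be positive")
    chk(object@geneLengthSd >= 0, "geneLengthSd must be non-negative")
    chk(object@nrl > 2L * object@coreHalfwidth,
        "nrl must exceed twice coreHalfwidth")
    chk(object@p0 >= 0 && object@p0 <= 1, "p0 must lie in [0, 1]")
    chk(object@pNonCpG >= 0 && object@pNonCpG <= 1,
        "pNonCpG must lie in [0, 1]")
    chk(object@nonconversion >= 0 && object@nonconversion <= 1,
        "nonconversion must lie in [0, 1]")
    chk(object@linkerFactor > 0, "linkerFactor must be positive")
    chk(object@helicalAmplitude >= 0 && object@helicalAmplitude < 1,
        "helicalAmplitude must lie in [0, 1)")
    chk(object@helicalPeriod > 0, "helicalPeriod must be positive")
    chk(object@coverageMean >= 0, "coverageMean must be non-negative")
    chk(all(GENOTYPES %in% names(object@expressionScale)),
        "expressionScale must name all genotypes (WT, set1, set2, dot1)")
    chk(all(object@expressionScale > 0),
        "expressionScale entries must be positive")
    if (length(msg)) msg else TRUE
})

#' Nucleosome dyad positions and per-base occupancy
#'
#' @slot dyads named list (one element per contig) of sorted 0-based dyad
#'   positions.
#' @slot occupancy named list of per-base occupancy vectors in [0, 1];
#'   element `i` of a vector is position `i - 1`.
#' @export
setClass("NucleosomeModel", representation(
    dyads = "list",
    occupancy = "list"
))

setValidity("NucleosomeModel", function(object) {
    if (!identical(names(object@dyads), names(object@occupancy)))
        return("dyads and occupancy must cover the same contigs")
    for (nm in names(object@dyads)) {
        d <- object@dyads[[nm]]
        if (is.unsorted(d, strictly = TRUE))
            return(sprintf("dyads on %s must be strictly sorted", nm))
        occ <- object@occupancy[[nm]]
        if (any(occ < 0 | occ > 1))
            return(sprintf("occupancy on %s outside [0, 1]", nm))
        if (length(d) && (d[1L] < 0 || d[length(d)] >= length(occ)))
            return(sprintf("dyads on %s out of contig bounds", nm))
    }
    TRUE
})

#' A synthetic (or assembled) chromatin landscape
#'
#' Bundles the covariate universe of the analysis: genome sequence, gene
#' annotation with expression, nucleosome model, and named per-base signal
#' tracks (H3K4me3, H3K36me3, H3K4me1, PolII, DNMT3b).
#'
#' @slot genome a [Biostrings::DNAStringSet] of contigs.
#' @slot spikeIn name of the unmethylated spike-in contig.
#' @slot genes a [GenomicRanges::GRanges] with mcols `gene_id` and
#'   `expression`.
#' @slot nucleosomes a [NucleosomeModel-class].
#' @slot tracks named list of tracks; each track is a named list of per-base
#'   numeric vectors (one per contig), normalized to max 1 genome-wide.
#' @slot genotype one of WT, set1, set2, dot1.
#' @slot config the [SyntheticConfig-class] used to build the landscape.
#' @export
setClass("ChromatinLandscape", representation(
    genome = "DNAStringSet",
    spikeIn = "character",
    genes = "GRanges",
    nucleosomes = "NucleosomeModel",
    tracks = "list",
    genotype = "character",
    config = "SyntheticConfig"
))

setValidity("ChromatinLandscape", function(object) {
    if (!object@spikeIn %in% names(object@genome))
        return("spikeIn contig absent from genome")
    if (sum(names(object@genome) == object@spikeIn) != 1L)
        return("spike-in contig must be present exactly once")
    if (!object@genotype %in% GENOTYPES)
        return(sprintf("genotype must be one of %s",
                       paste(GENOTYPES, collapse = ", ")))
    for (tr in names(object@tracks)) {
        v <- object@tracks[[tr]]
        if (!all(names(v) %in% names(object@genome)))
            return(sprintf("track %s names unknown contigs", tr))
        if (any(unlist(lapply(v, min), use.names = FALSE) < 0))
            return(sprintf("track %s has negative values", tr))
    }
    TRUE
})

#' Per-cytosine bisulfite methylation counts
#'
#' The central quantitative record: one row per cytosine per strand, with
#' methylated (`mc`) and total (`cov`) read counts and the trinucleotide
#' context (CpG, CpHpG, CpHpH; NA where the contig end prevents
#' classification). Positions are 0-based.
#'
#' @slot data a data.frame with columns chrom, pos, strand, context, mc, cov.
#' @slot spikeIn name of the spike-in contig ("" if none).
#' @export
setClass("MethylationTable", representation(
    data = "data.frame",
    spikeIn = "character"
))

setValidity("MethylationTable", function(object) {
    d <- object@data
    need <- c("chrom", "pos", "strand", "context", "mc", "cov")
    if (!all(need %in% names(d)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, names(d)), collapse = ", ")))
    if (nrow(d)) {
        if (any(d$mc < 0) || any(d$cov < 0) || any(d$mc > d$cov))
            return("counts must satisfy 0 <= mc <= cov")
        if (!all(d$strand %in% c("+", "-")))
            return("strand must be '+' or '-'")
        ok <- is.na(d$context) | d$context %in% c("CpG", "CpHpG", "CpHpH")
        if (!all(ok))
            return("context must be CpG, CpHpG, CpHpH or NA")
        if (anyDuplicated(d[c("chrom", "pos", "strand")]))
            return("duplicate (chrom, pos, strand) records")
    }
    TRUE
})

#' Signal averaged around anchor points
#'
#' Mean signal per base-pair offset relative to a set of strand-oriented
#' anchors (TSS, TTS or nucleosome dyads), with the number of contributing
#' observations per offset. Offsets are negative upstream.
#'
#' @slot offset integer offsets (contiguous over the window).
#' @slot mean mean signal per offset (NA where n = 0).
#' @slot n number of observations per offset.
#' @slot nAnchors number of anchors aggregated.
#' @export
setClass("AnchoredProfile", representation(
    offset = "integer",
    mean = "numeric",
    n = "integer",
    nAnchors = "integer"
))

setValidity("AnchoredProfile", function(object) {
    if (length(object@offset) != length(object@mean) ||
        length(object@offset) != length(object@n))
        return("offset, mean and n must have equal length")
    if (length(object@offset) &&
        !identical(object@offset,
                   seq(object@offset[1L], by = 1L,
                       length.out = length(object@offset))))
        return("offsets must be contiguous")
    if (any(object@n < 0L)) return("n must be non-negative")
    if (any(object@n == 0L & !is.na(object@mean)))
        return("mean must be NA where n = 0")
    TRUE
})

#' Gene-scaled metagene profile
#'
#' Mean signal over genes after rescaling each gene body to a common
#' fractional coordinate, with fixed-width flanking bins in real bp.
#' Strand-oriented: the TSS is always on the left. Each gene is weighted
#' equally; `n` counts contributing genes per bin.
#'
#' @slot bins data.frame with columns region (upstream/body/downstream),
#'   bin (1-based within region), mid (bp for flanks, fraction for body),
#'   mean, n.
#' @slot nBodyBins number of gene-body bins.
#' @slot flankBp,flankBinBp flank extent and flank bin width (bp).
#' @slot nGenes genes aggregated; nExcluded genes dropped by length filter.
#' @export
setClass("MetageneProfile", representation(
    bins = "data.frame",
    nBodyBins = "integer",
    flankBp = "integer",
    flankBinBp = "integer",
    nGenes = "integer",
    nExcluded = "integer"
))

#' Ordinary least-squares fit on binned chromatin features
#'
#' @slot response,predictors model column names.
#' @slot coefficients named vector (intercept first).
#' @slot r2,adjR2 coefficient of determination and its adjusted form.
#' @slot pearson Pearson correlation between fitted and observed values.
#' @slot n number of bins used.
#' @slot dropped predictors dropped as constant/aliased (if any).
#' @export
setClass("LinearModelFit", representation(
    response = "character",
    predictors = "character",
    coefficients = "numeric",
    r2 = "numeric",
    adjR2 = "numeric",
    pearson = "numeric",
    n = "integer",
    dropped = "character"
))

setValidity("LinearModelFit", function(object) {
    if (length(object@adjR2) && length(object@r2) &&
        object@adjR2 > object@r2 + 1e-12)
        return("adjusted R-squared cannot exceed R-squared")
    if (object@n <= length(object@predictors) + 1L)
        return("n must exceed number of predictors + 1")
    TRUE
})
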