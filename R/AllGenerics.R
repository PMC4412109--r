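#' @rdname ChromatinLandscape-class
#' @param x a ChromatinLandscape (or, for some accessors, another container).
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname ChromatinLandscape-class
#' @export
setGeneric("spikeIn", function(x) standardGeneric("spikeIn"))

#' @rdname ChromatinLandscape-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname ChromatinLandscape-class
#' @export
setGeneric("nucleosomes", function(x) standardGeneric("nucleosomes"))

#' @rdname NucleosomeModel-class
#' @param x a NucleosomeModel or ChromatinLandscape.
#' @export
setGeneric("dyads", function(x) standardGeneric("dyads"))

#' @rdname NucleosomeModel-class
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname ChromatinLandscape-class
#' @param name track name (e.g. "H3K4me3").
#' @export
setGeneric("markTrack", function(x, name) standardGeneric("markTrack"))

#' @rdname ChromatinLandscape-class
#' @export
setGeneric("trackNames", function(x) standardGeneric("trackNames"))

#' @rdname ChromatinLandscape-class
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname MethylationTable-class
#' @param x a MethylationTable.
#' @export
setGeneric("methData", function(x) standardGeneric("methData"))

setMethod("genomeSeq", "ChromatinLandscape", function(x) x@genome)
setMethod("spikeIn", "ChromatinLandscape", function(x) x@spikeIn)
setMethod("spikeIn", "MethylationTable", function(x) x@spikeIn)
setMethod("genes", "ChromatinLandscape", function(x) x@genes)
setMethod("nucleosomes", "ChromatinLandscape", function(x) x@nucleosomes)
setMethod("dyads", "NucleosomeModel", function(x) x@dyads)
setMethod("dyads", "ChromatinLandscape", function(x) x@nucleosomes@dyads)
setMethod("occupancy", "NucleosomeModel", function(x) x@occupancy)
setMethod("occupancy", "ChromatinLandscape",
          function(x) x@nucleosomes@occupancy)
setMethod("trackNames", "ChromatinLandscape", function(x) names(x@tracks))
setMethod("markTrack", "ChromatinLandscape", function(x, name) {
    if (!name %in% names(x@tracks))
        .inputError(sprintf("no track named '%s' (have: %s)", name,
                            paste(names(x@tracks), collapse = ", ")))
    x@tracks[[name]]
})
setMethod("genotype", "ChromatinLandscape", function(x) x@genotype)
setMethod("methData", "MethylationTable", function(x) x@data)

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:",
        sprintf("%d x %d bp chromosomes + %d bp spike-in",
                object@nChromosomes, object@chromLength, object@spikeLength),
        "\n")
    cat(sprintf("  %d genes | NRL %d bp | core +/-%d bp | NFR +/-%d bp\n",
                object@nGenes, object@nrl, object@coreHalfwidth,
                object@nfrHalfwidth))
    cat(sprintf("  p0 %.4g | linker x%.2f | helical %.2f @ %g bp | w4 %.2f | w36 %.2f\n",
                object@p0, object@linkerFactor, object@helicalAmplitude,
                object@helicalPeriod, object@w4, object@w36))
    cat(sprintf("  coverage %.1f | non-conversion %.4g | seed %d\n",
                object@coverageMean, object@nonconversion, object@seed))
})

setMethod("show", "NucleosomeModel", function(object) {
    cat(sprintf("NucleosomeModel: %d contigs, %d dyads\n",
                length(object@dyads),
                sum(lengths(object@dyads))))
})

setMethod("show", "ChromatinLandscape", function(object) {
    cat(sprintf("ChromatinLandscape (%s): %d contigs (%s bp), spike-in '%s'\n",
                object@genotype, length(object@genome),
                format(sum(width(object@genome)), big.mark = ","),
                object@spikeIn))
    cat(sprintf("  %d genes | %d dyads | tracks: %s\n",
                length(object@genes),
                sum(lengths(object@nucleosomes@dyads)),
                paste(names(object@tracks), collapse = ", ")))
})

setMethod("show", "MethylationTable", function(object) {
    d <- object@data
    cat(sprintf("MethylationTable: %d cytosine records on %d contigs\n",
                nrow(d), length(unique(d$chrom))))
    if (nrow(d)) {
        tab <- table(d$context, useNA = "ifany")
        cat("  contexts:",
            paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    }
    if (nzchar(object@spikeIn))
        cat(sprintf("  spike-in contig: %s\n", object@spikeIn))
})

setMethod("show", "AnchoredProfile", function(object) {
    cat(sprintf("AnchoredProfile: offsets %d..%d over %d anchors (%d/%d offsets observed)\n",
                min(object@offset), max(object@offset), object@nAnchors,
                sum(object@n > 0L), length(object@offset)))
})

setMethod("show", "MetageneProfile", function(object) {
    cat(sprintf("MetageneProfile: %d body bins, %d bp flanks @ %d bp/bin; %d genes (%d excluded)\n",
                object@nBodyBins, object@flankBp, object@flankBinBp,
                object@nGenes, object@nExcluded))
})

setMethod("show", "LinearModelFit", function(object) {
    cat(sprintf("LinearModelFit: %s ~ %s\n", object@response,
                paste(object@predictors, collapse = " + ")))
    cat(sprintf("  n = %d | R2 = %.4f | adj. R2 = %.4f | Pearson(pred, obs) = %.4f\n",
                object@n, object@r2, object@adjR2, object@pearson))
    if (length(object@dropped))
        cat("  dropped (constant/aliased):",
            paste(object@dropped, collapse = ", "), "\n")
})

#' Extract profile values as a data.frame
#'
#' @param x an AnchoredProfile or MetageneProfile.
#' @return a data.frame with one row per offset or bin.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

setMethod("profileTable", "AnchoredProfile", function(x)
    data.frame(offset = x@offset, mean = x@mean, n = x@n))

setMethod("profileTable", "MetageneProfile", function(x) x@bins)
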