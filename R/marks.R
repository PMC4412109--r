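MARK_NAMES <- c("H3K4me3", "H3K36me3", "H3K4me1", "PolII", "DNMT3b")

## K4me3 Gaussian sd: ~95% of mass within +/- 300 bp of the TSS
K4_SD <- 150

#' Build per-base chromatin mark and Pol II tracks
#'
#' For each gene with expression E: H3K4me3 is a Gaussian bump (sd 150 bp)
#' centered on the +1 nucleosome (TSS + nrl/2, strand-oriented; histone
#' marks are carried by nucleosomes, and the promoter NFR is
#' nucleosome-free) scaled by E; H3K36me3 a linear 0 -> E ramp across the gene
#' body toward the TTS; H3K4me1 a mid-gene plateau (flat over the central
#' half of the body with linear shoulders) scaled by E; PolII a flat E over
#' the body. Each track is normalized to max 1 genome-wide and is zero on
#' the spike-in contig. Genotype switches: set1 has no H3K4me3/H3K4me1
#' (Set1 writes H3K4 methylation), set2 no H3K36me3 (Set2 writes H3K36
#' methylation), dot1 is identical to WT (H3K79 methylation does not enter
#' this model). The DNMT3b occupancy track is initialized to zero and
#' filled in by [computeMethylationProbability].
#'
#' @param geneset GRanges of genes with an `expression` mcol.
#' @param genome the DNAStringSet the genes live on.
#' @param config a [SyntheticConfig-class].
#' @param genotype one of WT, set1, set2, dot1.
#' @return named list of tracks; each a named list of per-base vectors.
#' @export
buildMarkTracks <- function(geneset, genome, config, genotype = "WT") {
    .checkGenotype(genotype)
    stopifnot(is(genome, "DNAStringSet"))
    spike <- .spikeName(genome)
    lens <- setNames(width(genome), names(genome))
    zero <- lapply(lens, numeric)
    tracks <- list(H3K4me3 = zero, H3K36me3 = zero, H3K4me1 = zero,
                   PolII = zero, DNMT3b = zero)
    if (length(geneset)) {
        s0 <- .geneStart0(geneset); e0 <- .geneEnd0(geneset)
        str <- as.character(strand(geneset))
        chrom <- as.character(seqnames(geneset))
        expr <- mcols(geneset)$expression
        tss <- .tss0(geneset)
        for (i in seq_along(geneset)) {
            ct <- chrom[i]
            if (ct == spike) next
            L <- lens[[ct]]
            ## H3K4me3 bump over the +1 nucleosome
            cen <- tss[i] + if (str[i] == "+") config@nrl %/% 2L else
                -(config@nrl %/% 2L)
            win <- max(0L, cen - 3L * K4_SD):min(L - 1L, cen + 3L * K4_SD)
            bump <- expr[i] * exp(-0.5 * ((win - cen) / K4_SD)^2)
            tracks$H3K4me3[[ct]][win + 1L] <-
                tracks$H3K4me3[[ct]][win + 1L] + bump
            ## gene-body coordinates, oriented fraction f in (0, 1)
            body <- s0[i]:(e0[i] - 1L)
            f <- (body - s0[i] + 0.5) / (e0[i] - s0[i])
            if (str[i] == "-") f <- 1 - f
            idx <- body + 1L
            tracks$H3K36me3[[ct]][idx] <- tracks$H3K36me3[[ct]][idx] +
                expr[i] * f
            plateau <- pmin(1, pmax(0, pmin((f - 0.15) / 0.15,
                                            (0.95 - f) / 0.15)))
            tracks$H3K4me1[[ct]][idx] <- tracks$H3K4me1[[ct]][idx] +
                expr[i] * plateau
            tracks$PolII[[ct]][idx] <- tracks$PolII[[ct]][idx] + expr[i]
        }
    }
    if (genotype == "set1") {
        tracks$H3K4me3 <- zero
        tracks$H3K4me1 <- zero
    } else if (genotype == "set2") {
        tracks$H3K36me3 <- zero
    }
    for (nm in names(tracks)) {
        if (nzchar(spike)) tracks[[nm]][[spike]] <- numeric(lens[[spike]])
        tracks[[nm]] <- .normalizeTrack(tracks[[nm]])
    }
    tracks
}

.normalizeTrack <- function(track) {
    mx <- max(unlist(lapply(track, function(v)
        if (length(v)) max(v) else 0), use.names = FALSE), 0)
    if (mx > 0) track <- lapply(track, function(v) v / mx)
    track
}
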