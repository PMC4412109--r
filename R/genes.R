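#' Place genes on the non-spike-in contigs
#'
#' Genes are laid down sequentially with random intergenic gaps (>= 500 bp,
#' leaving room for the flanking NFRs), truncated-normal lengths (>= 400
#' bp), random strand, and log-normal expression. Genes never overlap (on
#' either strand) and never touch the spike-in contig. Deterministic for a
#' fixed seed.
#'
#' @param genome a [Biostrings::DNAStringSet] from [generateGenome] (or any
#'   DNAStringSet whose `metadata()$spikeIn` names the spike-in contig).
#' @param config a [SyntheticConfig-class].
#' @param seed random seed.
#' @return a [GenomicRanges::GRanges] with mcols `gene_id` and `expression`.
#' @export
placeGenes <- function(genome, config, seed = config@seed + 1L) {
    stopifnot(is(genome, "DNAStringSet"))
    spike <- .spikeName(genome)
    contigs <- setdiff(names(genome), spike)
    if (!length(contigs))
        .inputError("genome has no non-spike-in contigs")
    set.seed(seed)
    n <- config@nGenes
    if (n == 0L) {
        gr <- GRanges()
        mcols(gr)$gene_id <- character()
        mcols(gr)$expression <- numeric()
        return(gr)
    }
    margin <- 1000L
    minGap <- 500L
    maxGap <- 1200L
    minLen <- 400L
    lens <- setNames(width(genome)[match(contigs, names(genome))], contigs)
    cursor <- setNames(rep(margin, length(contigs)), contigs)

    chromOut <- character(n); startOut <- integer(n); endOut <- integer(n)
    glen <- pmax(minLen, round(rnorm(n, config@geneLengthMean,
                                     config@geneLengthSd)))
    gap <- round(runif(n, minGap, maxGap))
    strandOut <- sample(c("+", "-"), n, replace = TRUE)
    expression <- rlnorm(n, meanlog = 0, sdlog = config@expressionSdLog)

    for (k in seq_len(n)) {
        placed <- FALSE
        ## round-robin over contigs, falling back to any with room
        tryOrder <- contigs[((k - 1L + seq_along(contigs) - 1L) %%
                             length(contigs)) + 1L]
        for (ct in tryOrder) {
            s0 <- cursor[[ct]] + gap[k]
            e0 <- s0 + glen[k]
            if (e0 <= lens[[ct]] - margin) {
                chromOut[k] <- ct; startOut[k] <- s0; endOut[k] <- e0
                cursor[[ct]] <- e0
                placed <- TRUE
                break
            }
        }
        if (!placed)
            .inputError(sprintf(
                "genome too small to place %d genes (failed at gene %d)",
                n, k))
    }
    gr <- GRanges(chromOut, IRanges(start = startOut + 1L, end = endOut),
                  strand = strandOut)
    mcols(gr)$gene_id <- sprintf("gene%04d", seq_len(n))
    mcols(gr)$expression <- expression
    sort(gr, ignore.strand = TRUE)
}

## 0-based positions of strand-oriented gene anchors
.geneStart0 <- function(gr) start(gr) - 1L
.geneEnd0 <- function(gr) end(gr)          # exclusive
.tss0 <- function(gr) {
    ifelse(as.character(strand(gr)) == "+", start(gr) - 1L, end(gr) - 1L)
}
.tts0 <- function(gr) {
    ifelse(as.character(strand(gr)) == "+", end(gr) - 1L, start(gr) - 1L)
}

#' Strand-oriented TSS / TTS anchor table for a gene set
#'
#' @param gr a GRanges of genes.
#' @param which "tss" or "tts".
#' @return a data.frame with columns chrom, pos (0-based), strand, suitable
#'   for [anchoredProfile].
#' @export
geneAnchors <- function(gr, which = c("tss", "tts")) {
    which <- match.arg(which)
    pos <- if (which == "tss") .tss0(gr) else .tts0(gr)
    data.frame(chrom = as.character(seqnames(gr)), pos = pos,
               strand = as.character(strand(gr)),
               stringsAsFactors = FALSE)
}
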