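#' Build phased nucleosome arrays with NFRs and intergenic nucleosomes
#'
#' Each gene receives a nucleosome-free region upstream of its start and
#' downstream of its end (each spanning twice the configured NFR
#' half-width), and a phased dyad array through the gene body: dyads at
#' oriented offsets nrl/2, nrl/2 + nrl, ... from the TSS, without jitter.
#' Intergenic stretches are filled with dyads spaced nrl apart plus
#' Gaussian jitter. Occupancy is 1 within +/- coreHalfwidth of a dyad and 0
#' elsewhere (so ~0 at NFR centers).
#'
#' @param geneset a GRanges of genes from [placeGenes].
#' @param genome the DNAStringSet the genes live on.
#' @param config a [SyntheticConfig-class].
#' @param seed seed for the intergenic jitter.
#' @return a [NucleosomeModel-class].
#' @export
buildNucleosomeLandscape <- function(geneset, genome, config,
                                     seed = config@seed + 2L) {
    stopifnot(is(genome, "DNAStringSet"))
    set.seed(seed)
    nrl <- config@nrl
    half <- nrl %/% 2L
    core <- config@coreHalfwidth
    nfr <- config@nfrHalfwidth
    dyads <- list()
    occ <- list()
    for (ct in names(genome)) {
        L <- width(genome)[match(ct, names(genome))]
        onCt <- geneset[as.character(seqnames(geneset)) == ct]
        ctDyads <- integer()
        blockedStart <- integer(); blockedEnd <- integer()
        if (length(onCt)) {
            s0 <- .geneStart0(onCt); e0 <- .geneEnd0(onCt)
            str <- as.character(strand(onCt))
            for (i in seq_along(onCt)) {
                len <- e0[i] - s0[i]
                offs <- seq.int(half, by = nrl,
                                length.out = max(0L, (len - half - 1L) %/% nrl + 1L))
                offs <- offs[offs < len]
                pos <- if (str[i] == "+") s0[i] + offs else e0[i] - 1L - offs
                ctDyads <- c(ctDyads, pos)
            }
            ## NFR exclusion zones + gene bodies block intergenic dyads
            blockedStart <- c(s0 - 2L * nfr, s0, e0 - 1L)
            blockedEnd <- c(s0, e0, e0 - 1L + 2L * nfr)
        }
        ## intergenic gaps -> jittered arrays
        if (length(blockedStart)) {
            o <- order(blockedStart)
            bs <- pmax(blockedStart[o], 0L); be <- pmin(blockedEnd[o], L)
            ## merge
            ms <- integer(); me <- integer()
            for (i in seq_along(bs)) {
                if (length(ms) && bs[i] <= me[length(me)]) {
                    me[length(me)] <- max(me[length(me)], be[i])
                } else {
                    ms <- c(ms, bs[i]); me <- c(me, be[i])
                }
            }
            gapStart <- c(0L, me); gapEnd <- c(ms, L)
        } else {
            gapStart <- 0L; gapEnd <- L
        }
        for (i in seq_along(gapStart)) {
            gs <- gapStart[i]; ge <- gapEnd[i]
            if (ge - gs < nrl) next
            pos <- gs + half
            while (pos <= ge - half) {
                ctDyads <- c(ctDyads, pos)
                step <- nrl + if (config@jitterSd > 0)
                    as.integer(round(rnorm(1L, 0, config@jitterSd))) else 0L
                pos <- pos + max(step, 2L * core + 1L)
            }
        }
        ctDyads <- sort(unique(ctDyads))
        ctDyads <- ctDyads[ctDyads >= 0L & ctDyads < L]
        v <- numeric(L)
        if (length(ctDyads)) {
            from <- pmax(ctDyads - core, 0L) + 1L
            to <- pmin(ctDyads + core, L - 1L) + 1L
            for (i in seq_along(from)) v[from[i]:to[i]] <- 1
        }
        dyads[[ct]] <- ctDyads
        occ[[ct]] <- v
    }
    new("NucleosomeModel", dyads = dyads, occupancy = occ)
}

## distance from each 0-based position to its nearest dyad (Inf if none)
.distToNearestDyad <- function(pos, dyadVec) {
    if (!length(dyadVec)) return(rep(Inf, length(pos)))
    idx <- findInterval(pos, dyadVec)
    left <- ifelse(idx >= 1L, pos - dyadVec[pmax(idx, 1L)], Inf)
    right <- ifelse(idx < length(dyadVec),
                    dyadVec[pmin(idx + 1L, length(dyadVec))] - pos, Inf)
    pmin(left, right)
}
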