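CONTEXTS <- c("CpG", "CpHpG", "CpHpH")

## Context of every cytosine (both strands) of one contig, vectorized.
## Returns pos (0-based), strand, context (NA when within 2 bp of the
## contig end, where the trinucleotide cannot be read).
.contigContexts <- function(seqChar) {
    s <- strsplit(seqChar, "", fixed = TRUE)[[1L]]
    L <- length(s)
    out <- list()
    iC <- which(s == "C")            # 1-based; + strand cytosines
    if (length(iC)) {
        ctx <- rep(NA_character_, length(iC))
        ok <- iC + 2L <= L
        nxt <- s[pmin(iC + 1L, L)]
        nxt2 <- s[pmin(iC + 2L, L)]
        ctx[ok & nxt == "G"] <- "CpG"
        ctx[ok & nxt != "G" & nxt2 == "G"] <- "CpHpG"
        ctx[ok & nxt != "G" & nxt2 != "G"] <- "CpHpH"
        out$plus <- data.frame(pos = iC - 1L, strand = "+", context = ctx,
                               stringsAsFactors = FALSE)
    }
    iG <- which(s == "G")            # - strand cytosines (G on +)
    if (length(iG)) {
        ctx <- rep(NA_character_, length(iG))
        ok <- iG - 2L >= 1L
        prv <- s[pmax(iG - 1L, 1L)]
        prv2 <- s[pmax(iG - 2L, 1L)]
        ctx[ok & prv == "C"] <- "CpG"
        ctx[ok & prv != "C" & prv2 == "C"] <- "CpHpG"
        ctx[ok & prv != "C" & prv2 != "C"] <- "CpHpH"
        out$minus <- data.frame(pos = iG - 1L, strand = "-", context = ctx,
                                stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(pos = integer(), strand = character(),
                          context = character(), stringsAsFactors = FALSE))
    d <- do.call(rbind, out)
    d[order(d$pos, d$strand), , drop = FALSE]
}

#' Classify the trinucleotide context of a cytosine
#'
#' On the + strand, a cytosine at `pos` is CpG if the next base is G,
#' CpHpG if the base after next is G, and CpHpH otherwise; a '-' strand
#' cytosine (a G in the + sequence) is classified on the reverse
#' complement. Cytosines whose trinucleotide runs past the contig end are
#' flagged `NA` (unclassifiable). Positions are 0-based.
#'
#' @param sequence a character string or DNAString.
#' @param pos 0-based position(s) of the cytosine in + coordinates.
#' @param strand "+" or "-" (recycled).
#' @return character vector of contexts (CpG, CpHpG, CpHpH or NA).
#' @examples
#' classifyContext("ACGT", 1, "+")    # CpG
#' classifyContext("ACAGT", 1, "+")   # CpHpG
#' classifyContext("TTCGAA", 3, "-")  # CpG read on the reverse complement
#' @export
classifyContext <- function(sequence, pos, strand = "+") {
    seqChar <- toupper(as.character(sequence))
    s <- strsplit(seqChar, "", fixed = TRUE)[[1L]]
    L <- length(s)
    n <- max(length(pos), length(strand))
    pos <- rep_len(as.integer(pos), n)
    strand <- rep_len(strand, n)
    if (any(pos < 0L | pos >= L))
        .inputError("position outside the sequence")
    base <- s[pos + 1L]
    wantC <- strand == "+"
    badBase <- (wantC & base != "C") | (!wantC & base != "G")
    if (any(badBase))
        .chromamethError(sprintf(
            "no cytosine on strand %s at position %d (base %s)",
            strand[badBase][1L], pos[badBase][1L], base[badBase][1L]),
            "chromameth_classification_error")
    vapply(seq_len(n), function(i) {
        p <- pos[i] + 1L
        if (strand[i] == "+") {
            if (p + 2L > L) return(NA_character_)
            if (s[p + 1L] == "G") "CpG"
            else if (s[p + 2L] == "G") "CpHpG"
            else "CpHpH"
        } else {
            if (p - 2L < 1L) return(NA_character_)
            if (s[p - 1L] == "C") "CpG"
            else if (s[p - 2L] == "C") "CpHpG"
            else "CpHpH"
        }
    }, character(1L))
}

#' Compute the per-cytosine ground-truth methylation probability
#'
#' Implements the generative chromatin-template model. For a CpG cytosine
#' at position i:
#' \deqn{p(i) = clamp(p0 L(i) H(i) exp(w36 s36(i) - w4 s4(i)) g, 0, 0.95)}
#' where L(i) is the linker factor outside dyad +/- coreHalfwidth (1
#' inside), H(i) = 1 + helicalAmplitude cos(2 pi d(i) / helicalPeriod)
#' inside cores (d = signed distance to the nearest dyad; 1 outside),
#' s4/s36 are the normalized H3K4me3/H3K36me3 tracks, and g the genotype's
#' DNMT3B activity scale. Non-CpG cytosines get pNonCpG * g; every site on
#' the spike-in contig gets exactly 0. The DNMT3b occupancy track is
#' derived as the 147-bp moving average of p over CpG sites, normalized to
#' max 1.
#'
#' @param genome DNAStringSet with spike-in metadata.
#' @param nucleosomes a [NucleosomeModel-class].
#' @param tracks mark tracks from [buildMarkTracks].
#' @param config a [SyntheticConfig-class].
#' @param genotype one of WT, set1, set2, dot1.
#' @param w4,w36 mark weight overrides (default from config).
#' @return list with `truth` (data.frame chrom, pos, strand, context, p;
#'   attribute `spikeIn`) and `dnmt3b` (the derived occupancy track).
#' @export
computeMethylationProbability <- function(genome, nucleosomes, tracks,
                                          config, genotype = "WT",
                                          w4 = config@w4, w36 = config@w36) {
    .checkGenotype(genotype)
    for (nm in c("H3K4me3", "H3K36me3"))
        if (is.null(tracks[[nm]]))
            .inputError(sprintf("missing track '%s'", nm))
    spike <- .spikeName(genome)
    g <- config@expressionScale[[genotype]]
    res <- vector("list", length(genome))
    dn <- list()
    for (ci in seq_along(genome)) {
        ct <- names(genome)[ci]
        L <- width(genome)[ci]
        cyt <- .contigContexts(as.character(genome[[ci]]))
        if (!nrow(cyt)) {
            res[[ci]] <- NULL
            dn[[ct]] <- numeric(L)
            next
        }
        p <- numeric(nrow(cyt))
        if (ct == spike) {
            p[] <- 0
        } else {
            isCpG <- !is.na(cyt$context) & cyt$context == "CpG"
            p[!isCpG] <- min(config@pNonCpG * g, 0.95)
            if (any(isCpG)) {
                pos <- cyt$pos[isCpG]
                dvec <- nucleosomes@dyads[[ct]]
                dist <- .distToNearestDyad(pos, dvec)
                inCore <- dist <= config@coreHalfwidth
                Lfac <- ifelse(inCore, 1, config@linkerFactor)
                Hfac <- ifelse(inCore,
                               1 + config@helicalAmplitude *
                                   cos(2 * pi * dist / config@helicalPeriod),
                               1)
                s4 <- tracks$H3K4me3[[ct]][pos + 1L]
                s36 <- tracks$H3K36me3[[ct]][pos + 1L]
                p[isCpG] <- pmin(pmax(
                    config@p0 * Lfac * Hfac * exp(w36 * s36 - w4 * s4) * g,
                    0), 0.95)
            }
        }
        res[[ci]] <- data.frame(chrom = ct, pos = cyt$pos,
                                strand = cyt$strand, context = cyt$context,
                                p = p, stringsAsFactors = FALSE)
        ## DNMT3b occupancy proportional to smoothed methylation probability
        idx <- cyt$pos + 1L
        agg <- rowsum(p, idx)
        cnt <- rowsum(rep(1, length(idx)), idx)
        v <- numeric(L)
        v[as.integer(rownames(agg))] <- agg[, 1L] / cnt[, 1L]
        sm <- as.numeric(filter(v, rep(1 / 147, 147), sides = 2))
        sm[is.na(sm)] <- 0
        dn[[ct]] <- sm
    }
    truth <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
    rownames(truth) <- NULL
    attr(truth, "spikeIn") <- spike
    list(truth = truth, dnmt3b = .normalizeTrack(dn))
}

#' Simulate bisulfite read counts from a ground-truth methylome
#'
#' Per site: total coverage ~ Poisson(coverageMean); methylated count ~
#' Binomial(cov, q) with q = p + (1 - p) * nonconversion, so even a fully
#' unmethylated site reads methylated at the non-conversion error rate.
#'
#' @param truth ground-truth data.frame from
#'   [computeMethylationProbability] (columns chrom, pos, strand, context,
#'   p; optional `spikeIn` attribute).
#' @param config a [SyntheticConfig-class].
#' @param seed random seed.
#' @param spikeIn spike-in contig name recorded in the result.
#' @return a [MethylationTable-class].
#' @export
simulateCounts <- function(truth, config, seed = config@seed + 3L,
                           spikeIn = attr(truth, "spikeIn")) {
    if (is.null(spikeIn)) spikeIn <- ""
    if (any(truth$p < 0 | truth$p > 1))
        .inputError("ground-truth probabilities must lie in [0, 1]")
    set.seed(seed)
    n <- nrow(truth)
    cov <- rpois(n, config@coverageMean)
    q <- truth$p + (1 - truth$p) * config@nonconversion
    mc <- rbinom(n, cov, q)
    new("MethylationTable",
        data = data.frame(chrom = truth$chrom, pos = truth$pos,
                          strand = truth$strand, context = truth$context,
                          mc = mc, cov = cov, stringsAsFactors = FALSE),
        spikeIn = spikeIn)
}

#' Simulate a complete chromatin + methylome experiment
#'
#' Runs the full generative chain — genome, genes, nucleosomes, mark
#' tracks, ground-truth methylation probabilities, bisulfite counts — for
#' one genotype. Stage seeds are derived deterministically from `seed`
#' (seed, seed+1, ... per stage), so identical (config, genotype, seed)
#' yields identical output at every stage.
#'
#' @param config a [SyntheticConfig-class].
#' @param genotype one of WT, set1, set2, dot1.
#' @param seed base random seed.
#' @return list with `landscape` ([ChromatinLandscape-class], including
#'   the derived DNMT3b track), `truth` (ground-truth data.frame) and
#'   `meth` ([MethylationTable-class]).
#' @examples
#' sim <- simulateExperiment(syntheticConfig(nChromosomes = 1,
#'     chromLength = 30000, spikeLength = 10000, nGenes = 10), seed = 7)
#' sim$landscape
#' @export
simulateExperiment <- function(config = syntheticConfig(),
                               genotype = "WT", seed = config@seed) {
    .checkGenotype(genotype)
    validObject(config)
    genome <- generateGenome(config, seed)
    geneset <- placeGenes(genome, config, seed + 1L)
    nuc <- buildNucleosomeLandscape(geneset, genome, config, seed + 2L)
    tracks <- buildMarkTracks(geneset, genome, config, genotype)
    mp <- computeMethylationProbability(genome, nuc, tracks, config,
                                        genotype)
    tracks$DNMT3b <- mp$dnmt3b
    landscape <- new("ChromatinLandscape", genome = genome,
                     spikeIn = .spikeName(genome), genes = geneset,
                     nucleosomes = nuc, tracks = tracks,
                     genotype = genotype, config = config)
    meth <- simulateCounts(mp$truth, config, seed + 3L)
    list(landscape = landscape, truth = mp$truth, meth = meth)
}
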