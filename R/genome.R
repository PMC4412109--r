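BASES <- c("A", "C", "G", "T")

.baseFreqs <- function(gc) {
    c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

## Transition row used after a C: P(G | C) is boosted by cpgEnrichment
## (capped at 0.9), the remaining mass spread over A/C/T in proportion to
## their background frequencies. With cpgEnrichment = 1 the chain reduces
## to independent sampling from the background frequencies.
.fromCRow <- function(config) {
    q <- .baseFreqs(config@gcFraction)
    pG <- min(config@cpgEnrichment * q[["G"]], 0.9)
    rest <- q[c("A", "C", "T")]
    restSum <- sum(rest)
    if (restSum > 0) rest <- rest * (1 - pG) / restSum
    c(A = rest[["A"]], C = rest[["C"]], G = pG, T = rest[["T"]])
}

.sampleContig <- function(len, config) {
    q <- .baseFreqs(config@gcFraction)
    if (config@cpgEnrichment == 1) {
        return(paste(sample(BASES, len, replace = TRUE, prob = q),
                     collapse = ""))
    }
    cumQ <- cumsum(q)
    cumC <- cumsum(.fromCRow(config))
    u <- runif(len)
    x <- integer(len)
    x[1L] <- findInterval(u[1L], cumQ, rightmost.closed = TRUE) + 1L
    for (i in seq_len(len - 1L) + 1L) {
        cp <- if (x[i - 1L] == 2L) cumC else cumQ
        x[i] <- findInterval(u[i], cp, rightmost.closed = TRUE) + 1L
    }
    x[x > 4L] <- 4L
    paste(BASES[x], collapse = "")
}

#' Generate a synthetic multi-chromosome genome with a spike-in contig
#'
#' Samples chromosome sequences from a first-order model with the
#' configured GC content and CpG enrichment, plus one lambda-like spike-in
#' contig (same composition) that downstream stages treat as fully
#' unmethylated ground truth. Deterministic for a fixed seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param seed random seed (defaults to the config seed).
#' @return a [Biostrings::DNAStringSet]; `metadata(x)$spikeIn` names the
#'   spike-in contig.
#' @examples
#' g <- generateGenome(syntheticConfig(nChromosomes = 1, chromLength = 5000))
#' names(g)
#' @export
generateGenome <- function(config, seed = config@seed) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    set.seed(seed)
    lens <- c(rep(config@chromLength, config@nChromosomes),
              config@spikeLength)
    nms <- c(paste0("chr", as.character(utils::as.roman(
        seq_len(config@nChromosomes)))), "lambda_spike")
    seqs <- vapply(lens, .sampleContig, character(1L), config = config)
    genome <- Biostrings::DNAStringSet(setNames(seqs, nms))
    metadata(genome)$spikeIn <- "lambda_spike"
    genome
}

.spikeName <- function(genome) {
    sp <- metadata(genome)$spikeIn
    if (is.null(sp)) "" else sp
}
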