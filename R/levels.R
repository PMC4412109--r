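.methSubset <- function(x, context = NULL, contigs = NULL,
                        exclude = NULL) {
    d <- methData(x)
    keep <- rep(TRUE, nrow(d))
    if (!is.null(context)) keep <- keep & !is.na(d$context) &
            d$context %in% context
    if (!is.null(contigs)) keep <- keep & d$chrom %in% contigs
    if (!is.null(exclude)) keep <- keep & !(d$chrom %in% exclude)
    d[keep, , drop = FALSE]
}

#' Coverage-weighted methylation level
#'
#' The weighted level of a set of sites is the pooled count ratio
#' sum(mc) / sum(cov); zero-coverage sites contribute nothing. This is the
#' standard WGBS summary and the estimator used wherever the package
#' reports a single methylation number.
#'
#' @param x a [MethylationTable-class].
#' @param context restrict to these contexts (e.g. "CpG"); NULL = all
#'   classifiable contexts (NA-context sites are always excluded).
#' @param contigs restrict to these contigs; NULL = all.
#' @param exclude contig names to drop (e.g. the spike-in).
#' @return a fraction in [0, 1].
#' @examples
#' tab <- methylationTable(data.frame(
#'     chrom = "c", pos = c(0, 5), strand = "+", context = "CpG",
#'     mc = c(2, 3), cov = c(10, 5)))
#' weightedLevel(tab)  # 5/15
#' @export
weightedLevel <- function(x, context = NULL, contigs = NULL,
                          exclude = NULL) {
    d <- .methSubset(x, context, contigs, exclude)
    d <- d[!is.na(d$context), , drop = FALSE]
    tot <- sum(d$cov)
    if (!nrow(d) || tot == 0)
        .inputError("empty site selection: weighted level undefined")
    sum(d$mc) / tot
}

#' Construct a MethylationTable from a data.frame
#'
#' @param data data.frame with columns chrom, pos (0-based), strand,
#'   context, mc, cov.
#' @param spikeIn spike-in contig name ("" if none).
#' @return a [MethylationTable-class].
#' @export
methylationTable <- function(data, spikeIn = "") {
    new("MethylationTable", data = as.data.frame(data), spikeIn = spikeIn)
}

#' Per-context methylation summary
#'
#' Weighted methylation level per trinucleotide context, plus the ratio of
#' the CpG level to the pooled non-CpG level (the dinucleotide-preference
#' statistic). Contexts absent from the table are absent from the result,
#' not zero.
#'
#' @param x a [MethylationTable-class].
#' @param excludeSpike drop the spike-in contig first (default TRUE).
#' @return list with `levels` (data.frame context, level, nSites,
#'   totalCov), `cpgToNonCpG` (ratio, NA if no non-CpG counts), and
#'   `nonCpGLevel` (pooled CpHpG + CpHpH level, NA if absent).
#' @export
perContextSummary <- function(x, excludeSpike = TRUE) {
    excl <- if (excludeSpike && nzchar(spikeIn(x))) spikeIn(x) else NULL
    d <- .methSubset(x, exclude = excl)
    d <- d[!is.na(d$context) & d$cov > 0, , drop = FALSE]
    if (!nrow(d)) .inputError("no classifiable covered sites")
    present <- CONTEXTS[CONTEXTS %in% d$context]
    lev <- vapply(present, function(ctx) {
        dd <- d[d$context == ctx, ]
        c(sum(dd$mc) / sum(dd$cov), nrow(dd), sum(dd$cov))
    }, numeric(3L))
    levels <- data.frame(context = present, level = lev[1L, ],
                         nSites = as.integer(lev[2L, ]),
                         totalCov = lev[3L, ], row.names = NULL)
    non <- d[d$context %in% c("CpHpG", "CpHpH"), , drop = FALSE]
    nonLevel <- if (nrow(non) && sum(non$cov) > 0)
        sum(non$mc) / sum(non$cov) else NA_real_
    cpg <- levels$level[levels$context == "CpG"]
    ratio <- if (length(cpg) && !is.na(nonLevel) && nonLevel > 0)
        cpg / nonLevel else NA_real_
    list(levels = levels, cpgToNonCpG = ratio, nonCpGLevel = nonLevel)
}

#' Estimate the bisulfite non-conversion rate from the spike-in
#'
#' The spike-in contig is unmethylated by construction, so its pooled
#' weighted level (all contexts) estimates the non-conversion error rate.
#'
#' @param x a [MethylationTable-class].
#' @param spikeContig spike-in contig name (defaults to the table's).
#' @return list with `rate`, `nSites`, `totalCov`.
#' @export
estimateNonconversion <- function(x, spikeContig = spikeIn(x)) {
    d <- methData(x)
    if (!nzchar(spikeContig) || !spikeContig %in% d$chrom)
        .inputError(sprintf("spike-in contig '%s' absent from table",
                            spikeContig))
    dd <- d[d$chrom == spikeContig & d$cov > 0, , drop = FALSE]
    if (!nrow(dd))
        .inputError("spike-in contig has no covered sites")
    rate <- sum(dd$mc) / sum(dd$cov)
    if (rate > 0.5)
        warning("spike-in level > 50%: pathological spike-in, ",
                "non-conversion estimate unreliable")
    list(rate = rate, nSites = nrow(dd), totalCov = sum(dd$cov))
}

#' Apply a non-conversion correction to per-site levels
#'
#' Optional correction l' = max(0, (l - e) / (1 - e)) for non-conversion
#' rate e; reported levels elsewhere in the package are uncorrected.
#'
#' @param level numeric vector of levels.
#' @param rate non-conversion rate in [0, 1).
#' @return corrected levels.
#' @export
correctNonconversion <- function(level, rate) {
    if (rate < 0 || rate >= 1) .paramError("rate must lie in [0, 1)")
    pmax(0, (level - rate) / (1 - rate))
}
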