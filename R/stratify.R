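REGION_MODES <- c("whole", "last_third", "promoter")

## promoter = TSS +/- this many bp (clipped to the contig)
PROMOTER_HALFWIDTH <- 300L

## strand-oriented sub-region of each gene as 0-based half-open intervals
.unitRegions <- function(units, regionMode, contigLens) {
    s0 <- .geneStart0(units); e0 <- .geneEnd0(units)
    str <- as.character(strand(units))
    len <- e0 - s0
    if (regionMode == "whole") {
        rs <- s0; re <- e0
    } else if (regionMode == "last_third") {
        third <- len %/% 3L
        rs <- ifelse(str == "+", e0 - third, s0)
        re <- ifelse(str == "+", e0, s0 + third)
    } else if (regionMode == "promoter") {
        tss <- .tss0(units)
        rs <- tss - PROMOTER_HALFWIDTH
        re <- tss + PROMOTER_HALFWIDTH + 1L
    } else {
        .paramError(sprintf("unknown region_mode '%s' (use %s)", regionMode,
                            paste(REGION_MODES, collapse = ", ")))
    }
    ct <- as.character(seqnames(units))
    rs <- pmax(rs, 0L)
    re <- pmin(re, contigLens[ct])
    data.frame(chrom = ct, start = rs, end = re, stringsAsFactors = FALSE)
}

#' Per-gene chromatin and methylation summaries
#'
#' For each unit (gene), the mean of every landscape track over the
#' selected sub-region, the coverage-weighted CpG methylation level over
#' the sub-region (NA if no covered CpG), and the expression value.
#' Region modes: "whole" (full gene body), "last_third" (terminal third,
#' strand-oriented), "promoter" (TSS +/- 300 bp).
#'
#' @param landscape a [ChromatinLandscape-class].
#' @param meth a [MethylationTable-class].
#' @param units GRanges of units (defaults to the landscape's genes).
#' @param regionMode one of "whole", "last_third", "promoter".
#' @return data.frame: unit, expression, one column per track, `occupancy`
#'   and `meth`.
#' @export
summarizeUnits <- function(landscape, meth, units = genes(landscape),
                           regionMode = "whole") {
    if (!regionMode %in% REGION_MODES)
        .paramError(sprintf("unknown region_mode '%s' (use %s)", regionMode,
                            paste(REGION_MODES, collapse = ", ")))
    contigLens <- setNames(width(genomeSeq(landscape)),
                           names(genomeSeq(landscape)))
    reg <- .unitRegions(units, regionMode, contigLens)
    trackList <- c(landscape@tracks, list(occupancy = occupancy(landscape)))
    md <- methData(meth)
    md <- md[!is.na(md$context) & md$context == "CpG" & md$cov > 0, ]
    out <- data.frame(unit = mcols(units)$gene_id,
                      expression = mcols(units)$expression,
                      stringsAsFactors = FALSE)
    for (nm in names(trackList)) {
        out[[nm]] <- vapply(seq_len(nrow(reg)), function(i) {
            v <- trackList[[nm]][[reg$chrom[i]]]
            if (reg$end[i] <= reg$start[i]) return(NA_real_)
            mean(v[(reg$start[i] + 1L):reg$end[i]])
        }, numeric(1L))
    }
    out$meth <- vapply(seq_len(nrow(reg)), function(i) {
        sel <- md$chrom == reg$chrom[i] & md$pos >= reg$start[i] &
            md$pos < reg$end[i]
        if (!any(sel)) return(NA_real_)
        sum(md$mc[sel]) / sum(md$cov[sel])
    }, numeric(1L))
    out
}

#' Assign units to deciles by a sort key
#'
#' Units are sorted ascending by the key (ties broken by unit id, so the
#' assignment is a deterministic function of keys and ids) and split into
#' 10 groups whose sizes differ by at most one; when n is not a multiple
#' of 10 the lower deciles receive the extra unit. Units with a missing
#' key are excluded and counted.
#'
#' @param summary data.frame with a `unit` column (as from
#'   [summarizeUnits]), or any data.frame with `unit` plus the key.
#' @param keyFeature column name to sort by.
#' @return data.frame(unit, key, decile) plus attribute `nMissing`.
#' @export
decileStratify <- function(summary, keyFeature) {
    if (!keyFeature %in% names(summary))
        .inputError(sprintf("key feature '%s' absent", keyFeature))
    key <- summary[[keyFeature]]
    ok <- !is.na(key)
    if (sum(ok) < 10L)
        .inputError("need at least 10 units with a non-missing key")
    d <- summary[ok, c("unit", keyFeature)]
    o <- order(d[[keyFeature]], d$unit)
    d <- d[o, ]
    n <- nrow(d)
    sizes <- rep(n %/% 10L, 10L) + as.integer(seq_len(10L) <= n %% 10L)
    d$decile <- rep(seq_len(10L), sizes)
    names(d)[2L] <- "key"
    rownames(d) <- NULL
    attr(d, "nMissing") <- sum(!ok)
    d
}

#' Apply a profiling operation within each decile
#'
#' @param signal data.frame(chrom, pos, value) signal.
#' @param units GRanges of units (with `gene_id` mcol matching the
#'   assignment's `unit`).
#' @param assignment data.frame from [decileStratify].
#' @param profileFun function(signal, units) -> profile, e.g.
#'   `function(s, u) metageneProfile(s, u)` or a TSS-anchored closure.
#' @return list of 10 profiles (decile 1 = lowest key).
#' @export
profileByDecile <- function(signal, units, assignment, profileFun) {
    if (!all(assignment$unit %in% mcols(units)$gene_id))
        .inputError("assignment names units absent from the unit set")
    lapply(seq_len(10L), function(k) {
        ids <- assignment$unit[assignment$decile == k]
        profileFun(signal, units[mcols(units)$gene_id %in% ids])
    })
}

#' Spearman rank-correlation matrix over unit summaries
#'
#' Pairwise-complete Spearman correlations between the named feature
#' columns, with the per-pair number of complete observations.
#'
#' @param summary data.frame of unit summaries.
#' @param features column names to correlate (>= 2).
#' @return list with `rho` (symmetric matrix, unit diagonal) and `n`
#'   (pairwise complete counts).
#' @export
spearmanMatrix <- function(summary, features) {
    missing <- setdiff(features, names(summary))
    if (length(missing))
        .inputError(sprintf("features absent from summary: %s",
                            paste(missing, collapse = ", ")))
    m <- as.matrix(summary[features])
    if (nrow(m) < 3L) .inputError("need at least 3 units")
    rho <- cor(m, method = "spearman", use = "pairwise.complete.obs")
    ok <- !is.na(m)
    n <- t(ok) %*% ok
    list(rho = rho, n = n)
}

#' Normalize samples by their total methylation
#'
#' Divides each sample's per-site CpG levels by that sample's genome-wide
#' coverage-weighted CpG level (spike-in excluded), yielding relative
#' (dimensionless) levels whose genome-wide weighted mean is 1 — the
#' "normalize by the total amount of DNA methylation" strategy for
#' comparing mutants with different global activity.
#'
#' @param methTables named list of [MethylationTable-class] objects.
#' @return named list of signal data.frames (chrom, pos, value, weight)
#'   with attribute `totalLevel` (the divisor).
#' @export
normalizeTotal <- function(methTables) {
    if (!length(methTables)) .inputError("no samples supplied")
    lapply(methTables, function(x) {
        excl <- if (nzchar(spikeIn(x))) spikeIn(x) else NULL
        total <- weightedLevel(x, context = "CpG", exclude = excl)
        if (total <= 0)
            .chromamethError("sample has zero total methylation",
                             "chromameth_normalization_error")
        sig <- siteSignal(x, context = "CpG", exclude = excl)
        sig$value <- sig$value / total
        attr(sig, "totalLevel") <- total
        sig
    })
}

#' Relative expression by the delta-delta-Ct method
#'
#' fold = 2^-ddCt with ddCt = (CtTargetMut - CtRefMut) -
#' (CtTargetWt - CtRefWt); the reference gene (e.g. TDH1) absorbs input
#' differences between conditions.
#'
#' @param ctTargetWt,ctRefWt,ctTargetMut,ctRefMut qPCR cycle thresholds.
#' @return list with `fold`, `ddct`, `dctWt`, `dctMut`.
#' @export
ddctRelativeExpression <- function(ctTargetWt, ctRefWt, ctTargetMut,
                                   ctRefMut) {
    cts <- c(ctTargetWt, ctRefWt, ctTargetMut, ctRefMut)
    if (any(!is.finite(cts)) || any(cts <= 0))
        .paramError("Ct values must be positive")
    dctWt <- ctTargetWt - ctRefWt
    dctMut <- ctTargetMut - ctRefMut
    ddct <- dctMut - dctWt
    list(fold = 2^(-ddct), ddct = ddct, dctWt = dctWt, dctMut = dctMut)
}

#' Scale per-site levels by a relative expression fold
#'
#' Linearly rescales a methylation signal by 1/fold — the expression-based
#' normalization that puts a mutant with reduced methyltransferase
#' expression on a wild-type-comparable scale.
#'
#' @param signal data.frame(chrom, pos, value, ...) as from [siteSignal],
#'   or a [MethylationTable-class] (converted to its CpG signal).
#' @param fold relative expression fold (> 0).
#' @return the signal with `value` divided by `fold`.
#' @export
scaleByExpression <- function(signal, fold) {
    if (!is.numeric(fold) || length(fold) != 1L || fold <= 0)
        .paramError("fold must be a positive scalar")
    if (is(signal, "MethylationTable"))
        signal <- siteSignal(signal, context = "CpG",
                             exclude = if (nzchar(spikeIn(signal)))
                                 spikeIn(signal) else NULL)
    signal$value <- signal$value / fold
    signal
}

#' Per-bin mutant / wild-type profile ratio
#'
#' @param profileMut,profileWt two [MetageneProfile-class] (or
#'   [AnchoredProfile-class]) objects on identical bin grids.
#' @param floor wild-type bin means below this are flagged (NA ratio), not
#'   divided.
#' @return data.frame of the shared grid with columns ratio and flagged.
#' @export
mutantWtRatio <- function(profileMut, profileWt, floor = 1e-4) {
    tm <- profileTable(profileMut)
    tw <- profileTable(profileWt)
    gridCols <- setdiff(names(tm), c("mean", "n"))
    if (!identical(names(tm), names(tw)) ||
        !identical(tm[gridCols], tw[gridCols]))
        .inputError("profiles are not on identical bin grids")
    flagged <- is.na(tw$mean) | tw$mean < floor
    out <- tm[gridCols]
    out$ratio <- ifelse(flagged, NA_real_, tm$mean / tw$mean)
    out$flagged <- flagged
    out
}
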