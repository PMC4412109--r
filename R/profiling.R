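#' Per-site methylation level signal
#'
#' Converts a methylation table to a per-base signal of per-site levels
#' mc/cov. Sites with zero coverage emit no observation (they are never
#' zero-filled). The coverage is carried as the observation weight for
#' pooled (coverage-weighted) statistics.
#'
#' @param x a [MethylationTable-class].
#' @param context restrict to these contexts (default "CpG"); NULL = all
#'   classifiable contexts.
#' @param exclude contig names to drop (e.g. the spike-in).
#' @return data.frame with columns chrom, pos (0-based), value, weight.
#' @export
siteSignal <- function(x, context = "CpG", exclude = NULL) {
    d <- .methSubset(x, context = context, exclude = exclude)
    d <- d[!is.na(d$context) & d$cov > 0, , drop = FALSE]
    data.frame(chrom = d$chrom, pos = d$pos, value = d$mc / d$cov,
               weight = d$cov, stringsAsFactors = FALSE)
}

#' Per-base signal from a landscape track
#'
#' @param x a [ChromatinLandscape-class].
#' @param name a track name from [trackNames], or "occupancy".
#' @return data.frame with columns chrom, pos (0-based), value, weight (1).
#' @export
trackSignal <- function(x, name) {
    tr <- if (identical(name, "occupancy")) occupancy(x)
          else markTrack(x, name)
    out <- lapply(names(tr), function(ct)
        data.frame(chrom = ct, pos = seq_along(tr[[ct]]) - 1L,
                   value = tr[[ct]], weight = 1,
                   stringsAsFactors = FALSE))
    do.call(rbind, out)
}

.checkSignal <- function(signal) {
    if (!all(c("chrom", "pos", "value") %in% names(signal)))
        .inputError("signal needs columns chrom, pos, value")
    if (is.null(signal$weight)) signal$weight <- 1
    signal
}

#' Average a signal around strand-oriented anchor points
#'
#' For each anchor, observations within `window` bp are assigned the
#' strand-oriented offset (downstream positive); the profile is the
#' unweighted mean over all observations per offset, with exact
#' bookkeeping of the number of observations. Offsets with no observation
#' are NA, never zero.
#'
#' @param signal data.frame(chrom, pos, value) as from [siteSignal].
#' @param anchors data.frame(chrom, pos, strand) of anchor points
#'   (0-based), e.g. from [geneAnchors].
#' @param window half-window in bp.
#' @return an [AnchoredProfile-class].
#' @export
anchoredProfile <- function(signal, anchors, window) {
    if (window <= 0) .paramError("window must be positive")
    if (is.null(anchors) || !nrow(anchors))
        .inputError("no anchors supplied")
    signal <- .checkSignal(signal)
    width <- 2L * as.integer(window) + 1L
    sums <- numeric(width)
    ns <- integer(width)
    for (ct in unique(anchors$chrom)) {
        sct <- signal[signal$chrom == ct, , drop = FALSE]
        if (!nrow(sct)) next
        o <- order(sct$pos)
        spos <- sct$pos[o]; sval <- sct$value[o]
        a <- anchors[anchors$chrom == ct, , drop = FALSE]
        lo <- findInterval(a$pos - window - 0.5, spos) + 1L
        hi <- findInterval(a$pos + window + 0.5, spos)
        cnt <- hi - lo + 1L
        keep <- cnt > 0L
        if (!any(keep)) next
        idx <- sequence(cnt[keep], from = lo[keep])
        anch <- rep(which(keep), cnt[keep])
        off <- spos[idx] - a$pos[anch]
        flip <- a$strand[anch] == "-"
        off[flip] <- -off[flip]
        key <- off + as.integer(window) + 1L
        rs <- rowsum(sval[idx], key)
        ks <- as.integer(rownames(rs))
        sums[ks] <- sums[ks] + rs[, 1L]
        ns <- ns + tabulate(key, nbins = width)
    }
    means <- ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_)
    new("AnchoredProfile",
        offset = seq.int(-as.integer(window), as.integer(window)),
        mean = as.numeric(means), n = as.integer(ns),
        nAnchors = nrow(anchors))
}

#' Gene-scaled metagene profile
#'
#' Each gene body is rescaled to `nBodyBins` fractional bins; flanks are
#' binned in fixed `flankBinBp` steps out to `flankBp`. The profile is
#' strand-oriented (TSS on the left) and averages genes with equal weight:
#' per bin, the mean over per-gene bin means. Genes shorter than
#' `minGeneLength` are excluded and counted.
#'
#' @param signal data.frame(chrom, pos, value) as from [siteSignal].
#' @param geneset GRanges of genes.
#' @param nBodyBins number of gene-body bins.
#' @param flankBp,flankBinBp flank extent and flank bin width (bp).
#' @param minGeneLength minimum gene length (bp) to include.
#' @return a [MetageneProfile-class].
#' @export
metageneProfile <- function(signal, geneset, nBodyBins = 60L,
                            flankBp = 1000L, flankBinBp = 25L,
                            minGeneLength = 300L) {
    signal <- .checkSignal(signal)
    if (flankBp %% flankBinBp != 0)
        .paramError("flankBp must be a multiple of flankBinBp")
    lens <- end(geneset) - start(geneset) + 1L
    keep <- lens >= max(minGeneLength, nBodyBins + 1L)
    nExcluded <- sum(!keep)
    geneset <- geneset[keep]
    if (!length(geneset))
        .inputError("no genes pass the length filter")
    nUp <- as.integer(flankBp / flankBinBp)
    nBins <- 2L * nUp + nBodyBins
    sums <- numeric(nBins)
    ns <- integer(nBins)
    bychrom <- split(seq_len(nrow(signal)), signal$chrom)
    s0 <- .geneStart0(geneset); e0 <- .geneEnd0(geneset)
    str <- as.character(strand(geneset))
    chrom <- as.character(seqnames(geneset))
    for (i in seq_along(geneset)) {
        ii <- bychrom[[chrom[i]]]
        if (is.null(ii)) next
        pos <- signal$pos[ii]; val <- signal$value[ii]
        len <- e0[i] - s0[i]
        inWin <- pos >= s0[i] - flankBp & pos < e0[i] + flankBp
        if (!any(inWin)) next
        pos <- pos[inWin]; val <- val[inWin]
        d <- if (str[i] == "+") pos - s0[i] else (e0[i] - 1L) - pos
        bin <- integer(length(d))
        up <- d < 0L
        bin[up] <- nUp + 1L + (d[up] %/% flankBinBp)       # 1..nUp
        body <- d >= 0L & d < len
        bin[body] <- nUp + pmin(nBodyBins,
                                ceiling((d[body] + 0.5) / len * nBodyBins))
        down <- d >= len
        bin[down] <- nUp + nBodyBins + 1L + ((d[down] - len) %/% flankBinBp)
        ok <- bin >= 1L & bin <= nBins
        if (!any(ok)) next
        gm <- rowsum(val[ok], bin[ok])
        gc <- rowsum(rep(1, sum(ok)), bin[ok])
        ks <- as.integer(rownames(gm))
        sums[ks] <- sums[ks] + gm[, 1L] / gc[, 1L]
        ns[ks] <- ns[ks] + 1L
    }
    region <- rep(c("upstream", "body", "downstream"),
                  c(nUp, nBodyBins, nUp))
    binIdx <- c(seq_len(nUp), seq_len(nBodyBins), seq_len(nUp))
    mid <- c(-flankBp + (seq_len(nUp) - 0.5) * flankBinBp,
             (seq_len(nBodyBins) - 0.5) / nBodyBins,
             (seq_len(nUp) - 0.5) * flankBinBp)
    bins <- data.frame(region = region, bin = binIdx, mid = mid,
                       mean = ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_),
                       n = ns, stringsAsFactors = FALSE)
    new("MetageneProfile", bins = bins, nBodyBins = as.integer(nBodyBins),
        flankBp = as.integer(flankBp), flankBinBp = as.integer(flankBinBp),
        nGenes = length(geneset), nExcluded = as.integer(nExcluded))
}

#' Dyad-anchored meta-nucleosome profile
#'
#' An [anchoredProfile] with nucleosome dyads as strandless anchors: each
#' dyad contributes in both orientations, so the profile is symmetric in
#' expectation.
#'
#' @param signal data.frame(chrom, pos, value) as from [siteSignal].
#' @param dyads named list of sorted 0-based dyad positions per contig
#'   (as from [dyads]).
#' @param window half-window in bp.
#' @return an [AnchoredProfile-class].
#' @export
metaNucleosome <- function(signal, dyads, window = 200L) {
    if (!sum(lengths(dyads)))
        .inputError("no dyads supplied")
    anchors <- do.call(rbind, lapply(names(dyads), function(ct) {
        if (!length(dyads[[ct]])) return(NULL)
        data.frame(chrom = ct, pos = rep(dyads[[ct]], 2L),
                   strand = rep(c("+", "-"), each = length(dyads[[ct]])),
                   stringsAsFactors = FALSE)
    }))
    prof <- anchoredProfile(signal, anchors, window)
    prof@nAnchors <- sum(lengths(dyads))
    prof
}

#' Estimate the dominant period of a spatial profile
#'
#' Detrends the profile by subtracting a centered moving average of width
#' `maxPeriod`, computes the autocorrelation function, and locates the lag
#' of the highest autocorrelation within [minPeriod, maxPeriod] (smallest
#' lag on exact ties). Because a signal of period P is equally correlated
#' at every multiple of P, the estimator then prefers the fundamental: if
#' an integer divisor of the best lag (within the search range) has an
#' autocorrelation of at least `(1 - harmonicTol)` times the best value,
#' the smallest such divisor is returned. A true period at the larger lag
#' is never displaced this way, since its sub-multiples are
#' anti-correlated. The autocorrelation value at the returned lag is the
#' score. Missing interior values are linearly interpolated (and counted);
#' leading/trailing missing values are trimmed.
#'
#' @param x an [AnchoredProfile-class], or a numeric series sampled at
#'   1 bp spacing.
#' @param minPeriod,maxPeriod search range (bp).
#' @param harmonicTol relative tolerance for the fundamental-vs-harmonic
#'   disambiguation.
#' @return list with `period`, `score`, `searchRange`, `nInterpolated`.
#' @export
estimatePeriodicity <- function(x, minPeriod, maxPeriod,
                                harmonicTol = 0.25) {
    if (minPeriod < 1 || maxPeriod <= minPeriod)
        .paramError("need 1 <= minPeriod < maxPeriod")
    v <- if (is(x, "AnchoredProfile")) x@mean else as.numeric(x)
    ## trim leading/trailing NA, interpolate interior NA
    okIdx <- which(!is.na(v))
    if (!length(okIdx)) .inputError("profile has no observed values")
    v <- v[okIdx[1L]:okIdx[length(okIdx)]]
    nInterp <- sum(is.na(v))
    if (nInterp > 0) {
        xs <- seq_along(v)
        v <- approx(xs[!is.na(v)], v[!is.na(v)], xout = xs)$y
    }
    if (length(v) < 3L * maxPeriod)
        .inputError(sprintf(
            "profile span %d < 3 * maxPeriod (%d): too short", length(v),
            3L * maxPeriod))
    w <- as.integer(maxPeriod)
    trend <- as.numeric(filter(v, rep(1 / w, w), sides = 2))
    d <- v - trend
    d <- d[!is.na(d)]
    ac <- as.numeric(acf(d, lag.max = as.integer(maxPeriod),
                         plot = FALSE, demean = TRUE)$acf)[-1L]
    rng <- seq.int(as.integer(minPeriod), as.integer(maxPeriod))
    vals <- ac[rng]
    best <- which.max(vals)   # first max = smallest lag on ties
    lag <- rng[best]
    ## prefer the fundamental over a harmonic: an in-range divisor with
    ## comparable autocorrelation wins
    divs <- rng[lag %% rng == 0 & rng < lag]
    divs <- divs[ac[divs] >= (1 - harmonicTol) * vals[best]]
    if (length(divs)) {
        lag <- min(divs)
        best <- match(lag, rng)
    }
    list(period = rng[best], score = vals[best],
         searchRange = c(as.integer(minPeriod), as.integer(maxPeriod)),
         nInterpolated = nInterp)
}

#' Linker-versus-core methylation contrast
#'
#' Splits observations by distance to the nearest nucleosome dyad: core if
#' within `coreHalfwidth` bp, linker otherwise. Returns the percent
#' increase 100 * (L - C) / C of the weighted mean signal in linker DNA
#' over core DNA (weights default to the signal's `weight` column, i.e.
#' coverage for methylation signals, making the strata pooled counts).
#' With `maxDist` set to half the nucleosome repeat length the contrast
#' becomes the meta-nucleosome version: only sites within a phased-array
#' neighborhood of a dyad are sampled, so the linker stratum is the DNA
#' between adjacent nucleosomes and both strata share the same regional
#' composition (NFRs and other nucleosome-depleted stretches, which sit
#' farther from any dyad, are excluded). With the default `maxDist = Inf`
#' the strata are a genome-wide partition.
#'
#' @param signal data.frame(chrom, pos, value, weight) as from
#'   [siteSignal].
#' @param dyads named list of sorted 0-based dyad positions per contig.
#' @param coreHalfwidth core half-width (bp).
#' @param maxDist maximum distance to the nearest dyad for a site to be
#'   sampled at all.
#' @return list with `increasePercent`, `linker`, `core`, `nLinker`,
#'   `nCore`.
#' @export
linkerCoreIncrease <- function(signal, dyads, coreHalfwidth = 73L,
                               maxDist = Inf) {
    signal <- .checkSignal(signal)
    dist <- rep(Inf, nrow(signal))
    for (ct in unique(signal$chrom)) {
        ii <- signal$chrom == ct
        dist[ii] <- .distToNearestDyad(signal$pos[ii], dyads[[ct]])
    }
    keep <- dist <= maxDist
    signal <- signal[keep, , drop = FALSE]
    dist <- dist[keep]
    inCore <- dist <= coreHalfwidth
    if (!any(inCore) || all(inCore) || !nrow(signal))
        .inputError("both linker and core strata must be non-empty")
    wm <- function(sel) sum(signal$value[sel] * signal$weight[sel]) /
        sum(signal$weight[sel])
    core <- wm(inCore)
    linker <- wm(!inCore)
    if (core == 0) .inputError("core stratum has zero mean signal")
    list(increasePercent = 100 * (linker - core) / core,
         linker = linker, core = core,
         nLinker = sum(!inCore), nCore = sum(inCore))
}
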