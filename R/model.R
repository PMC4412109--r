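#' Bin the genome and log-transform feature averages
#'
#' Divides every non-spike-in contig into fixed-width bins (partial
#' end bins dropped), averages each landscape track (and nucleosome
#' occupancy) over the bin, computes the coverage-weighted CpG methylation
#' level per bin (NA where the bin has no covered CpG), and log-transforms
#' every value as log(x + pseudocount) (natural log). The DNMT3b track
#' average doubles as the second modelled response.
#'
#' @param landscape a [ChromatinLandscape-class].
#' @param meth a [MethylationTable-class].
#' @param binWidth bin width in bp (200 by default).
#' @param pseudocount added before the log.
#' @return data.frame: chrom, start, end (0-based half-open), nCpG, then
#'   one log-feature column per track plus `occupancy` and `meth`.
#'   Attribute `nNoMeth` counts bins without methylation observations.
#' @export
binFeatures <- function(landscape, meth, binWidth = 200L,
                        pseudocount = 1e-3) {
    if (binWidth <= 0) .paramError("binWidth must be positive")
    genome <- genomeSeq(landscape)
    contigs <- setdiff(names(genome), spikeIn(landscape))
    trackList <- c(landscape@tracks, list(occupancy = occupancy(landscape)))
    md <- methData(meth)
    md <- md[!is.na(md$context) & md$context == "CpG" & md$cov > 0 &
             md$chrom %in% contigs, ]
    rows <- list()
    for (ct in contigs) {
        L <- width(genome)[match(ct, names(genome))]
        nBins <- L %/% binWidth
        if (!nBins) next
        starts <- (seq_len(nBins) - 1L) * binWidth
        d <- data.frame(chrom = ct, start = starts,
                        end = starts + binWidth,
                        stringsAsFactors = FALSE)
        for (nm in names(trackList)) {
            v <- trackList[[nm]][[ct]][seq_len(nBins * binWidth)]
            d[[nm]] <- colMeans(matrix(v, nrow = binWidth))
        }
        mct <- md[md$chrom == ct, ]
        bin <- mct$pos %/% binWidth + 1L
        keep <- bin <= nBins
        mcSum <- rowsum(mct$mc[keep], bin[keep])
        covSum <- rowsum(mct$cov[keep], bin[keep])
        nSite <- rowsum(rep(1L, sum(keep)), bin[keep])
        d$meth <- NA_real_
        d$nCpG <- 0L
        ks <- as.integer(rownames(mcSum))
        d$meth[ks] <- mcSum[, 1L] / covSum[, 1L]
        d$nCpG[ks] <- nSite[, 1L]
        rows[[ct]] <- d
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    featCols <- c(names(trackList), "meth")
    for (nm in featCols) out[[nm]] <- log(out[[nm]] + pseudocount)
    attr(out, "nNoMeth") <- sum(is.na(out$meth))
    attr(out, "pseudocount") <- pseudocount
    out
}

.fitOls <- function(table, predictors, response) {
    cols <- c(response, predictors)
    missing <- setdiff(cols, names(table))
    if (length(missing))
        .inputError(sprintf("columns absent from table: %s",
                            paste(missing, collapse = ", ")))
    d <- table[cols]
    d <- d[complete.cases(d), , drop = FALSE]
    dropped <- character()
    keep <- predictors
    for (p in predictors) {
        if (length(unique(d[[p]])) <= 1L) {
            keep <- setdiff(keep, p)
            dropped <- c(dropped, p)
        }
    }
    if (length(dropped))
        warning("dropping constant predictor(s): ",
                paste(dropped, collapse = ", "))
    if (nrow(d) <= length(keep) + 1L)
        .inputError("too few complete rows for the requested predictors")
    fml <- stats::reformulate(if (length(keep)) keep else "1",
                              response = response)
    fit <- lm(fml, data = d)
    alias <- names(coef(fit))[is.na(coef(fit))]
    if (length(alias)) {
        warning("rank-deficient fit; dropping aliased predictor(s): ",
                paste(alias, collapse = ", "))
        keep <- setdiff(keep, alias)
        dropped <- c(dropped, alias)
        fit <- lm(stats::reformulate(if (length(keep)) keep else "1",
                                     response = response), data = d)
    }
    sm <- summary(fit)
    pred <- as.numeric(stats::fitted(fit))
    obs <- as.numeric(d[[response]])
    pearson <- if (stats::sd(pred) > 0) as.numeric(cor(pred, obs))
               else NA_real_
    new("LinearModelFit", response = response, predictors = keep,
        coefficients = coef(fit), r2 = sm$r.squared,
        adjR2 = sm$adj.r.squared, pearson = pearson,
        n = nrow(d), dropped = dropped)
}

#' Fit an OLS model of a response on binned chromatin features
#'
#' Ordinary least squares on complete cases, reporting the adjusted
#' R-squared, adj R2 = 1 - (1 - R2)(n - 1)/(n - p - 1), and the Pearson
#' correlation between fitted and observed values. Constant or aliased
#' predictors are dropped with a warning.
#'
#' @param table a [binFeatures] data.frame (or any data.frame of
#'   numeric columns).
#' @param predictors predictor column names.
#' @param response response column name (e.g. "meth" or "DNMT3b").
#' @return a [LinearModelFit-class].
#' @export
fitLinearModel <- function(table, predictors, response = "meth") {
    .fitOls(table, predictors, response)
}

#' Compare predictor sets on an identical bin subset
#'
#' Fits each predictor set on the complete cases across the union of all
#' predictors (and the response), so the adjusted R-squared values are
#' directly comparable.
#'
#' @param table a [binFeatures] data.frame.
#' @param response response column name.
#' @param predictorSets named list of character vectors.
#' @return data.frame: set, nPredictors, r2, adjR2, pearson, n; ordered by
#'   decreasing adjusted R-squared. Attribute `fits` holds the
#'   [LinearModelFit-class] objects.
#' @export
comparePredictorSets <- function(table, response, predictorSets) {
    if (!length(predictorSets)) .inputError("no predictor sets supplied")
    if (is.null(names(predictorSets)))
        names(predictorSets) <- vapply(predictorSets, paste,
                                       character(1L), collapse = "+")
    allPred <- unique(unlist(predictorSets))
    cols <- c(response, allPred)
    missing <- setdiff(cols, names(table))
    if (length(missing))
        .inputError(sprintf("columns absent from table: %s",
                            paste(missing, collapse = ", ")))
    d <- table[cols]
    d <- d[complete.cases(d), , drop = FALSE]
    fits <- lapply(predictorSets, function(ps) .fitOls(d, ps, response))
    out <- data.frame(
        set = names(predictorSets),
        nPredictors = lengths(predictorSets),
        r2 = vapply(fits, slot, numeric(1L), "r2"),
        adjR2 = vapply(fits, slot, numeric(1L), "adjR2"),
        pearson = vapply(fits, slot, numeric(1L), "pearson"),
        n = vapply(fits, slot, integer(1L), "n"),
        row.names = NULL, stringsAsFactors = FALSE)
    out <- out[order(-out$adjR2), ]
    rownames(out) <- NULL
    attr(out, "fits") <- fits
    out
}
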