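#' Read a genome FASTA
#'
#' Sequences are uppercased; the number of masked (lowercase) bases is
#' reported via a message. The spike-in contig is identified by name.
#'
#' @param path FASTA file.
#' @param spikeIn spike-in contig name; defaults to "lambda_spike" when a
#'   contig of that name is present.
#' @return a [Biostrings::DNAStringSet] with `metadata()$spikeIn` set.
#' @export
readFastaGenome <- function(path, spikeIn = NULL) {
    if (!file.exists(path)) .inputError(sprintf("file not found: %s", path))
    if (file.size(path) == 0) {
        warning("empty FASTA file: ", path)
        g <- Biostrings::DNAStringSet()
        metadata(g)$spikeIn <- ""
        return(g)
    }
    g <- tryCatch(readDNAStringSet(path),
                  error = function(e) .parseError(
                      sprintf("malformed FASTA '%s': %s", path,
                              conditionMessage(e))))
    ## DNAStringSet normalizes case on parse; count masked bases from the
    ## raw text
    lines <- readLines(path)
    seqLines <- lines[!startsWith(lines, ">")]
    nMasked <- sum(vapply(seqLines, function(x)
        sum(strsplit(x, "", fixed = TRUE)[[1]] %in% letters),
        integer(1L), USE.NAMES = FALSE))
    if (nMasked > 0)
        message(nMasked, " masked (lowercase) bases uppercased")
    out <- Biostrings::DNAStringSet(setNames(toupper(as.character(g)),
                                             names(g)))
    if (is.null(spikeIn))
        spikeIn <- if ("lambda_spike" %in% names(out)) "lambda_spike" else ""
    metadata(out)$spikeIn <- spikeIn
    out
}

#' @rdname readFastaGenome
#' @param genome a DNAStringSet.
#' @export
writeFastaGenome <- function(genome, path) {
    writeXStringSet(genome, path)
    invisible(path)
}

#' Read / write gene annotations as BED6
#'
#' Genes are stored 0-based half-open with the gene id in the name field
#' and expression scaled into the score field as round(1000 * expression)
#' (so expression round-trips to 3 decimal digits of precision).
#'
#' @param path BED file.
#' @param genome optional DNAStringSet; intervals beyond contig bounds are
#'   rejected.
#' @return `readGenesBed`: a GRanges with mcols gene_id, expression.
#' @export
readGenesBed <- function(path, genome = NULL) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) .parseError(
                       sprintf("malformed BED '%s': %s", path,
                               conditionMessage(e))))
    if (any(width(gr) < 1L))
        .parseError(sprintf("interval with end <= start in '%s' (e.g. %s:%d)",
                            path, as.character(seqnames(gr))[width(gr) < 1L][1L],
                            start(gr)[width(gr) < 1L][1L] - 1L))
    if (!is.null(genome)) {
        lens <- setNames(width(genome), names(genome))
        bad <- !(as.character(seqnames(gr)) %in% names(lens)) |
            end(gr) > lens[as.character(seqnames(gr))]
        if (any(bad))
            .parseError(sprintf(
                "interval out of contig bounds in '%s': %s:%d-%d", path,
                as.character(seqnames(gr))[bad][1L],
                start(gr)[bad][1L] - 1L, end(gr)[bad][1L]))
    }
    mcols(gr)$gene_id <- mcols(gr)$name
    mcols(gr)$expression <- mcols(gr)$score / 1000
    mcols(gr)$name <- NULL
    mcols(gr)$score <- NULL
    gr
}

#' @rdname readGenesBed
#' @param genes GRanges with mcols gene_id and expression.
#' @export
writeGenesBed <- function(genes, path) {
    gr <- genes
    mcols(gr) <- NULL
    mcols(gr)$name <- mcols(genes)$gene_id
    mcols(gr)$score <- round(1000 * mcols(genes)$expression)
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read / write nucleosome dyad positions as BED
#'
#' Dyads are single-base BED intervals.
#'
#' @param path BED file.
#' @return `readDyadsBed`: named list of sorted 0-based positions.
#' @export
readDyadsBed <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) .parseError(
                       sprintf("malformed BED '%s': %s", path,
                               conditionMessage(e))))
    pos <- start(gr) - 1L
    out <- split(pos, as.character(seqnames(gr)))
    lapply(out, function(v) sort(unique(v)))
}

#' @rdname readDyadsBed
#' @param dyads named list of 0-based dyad positions per contig.
#' @export
writeDyadsBed <- function(dyads, path) {
    chrom <- rep(names(dyads), lengths(dyads))
    pos <- unlist(dyads, use.names = FALSE)
    gr <- GRanges(chrom, IRanges(start = pos + 1L, width = 1L))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read / write a per-base track as bedGraph
#'
#' Per-base vectors are run-length compressed on write and expanded on
#' read. Coordinates are 0-based half-open; intervals with end <= start or
#' beyond contig bounds are rejected.
#'
#' @param path bedGraph file.
#' @param contigLens named contig lengths (required for expansion).
#' @return `readTrackBedGraph`: named list of per-base numeric vectors.
#' @export
readTrackBedGraph <- function(path, contigLens) {
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                   error = function(e) .parseError(
                       sprintf("malformed bedGraph '%s': %s", path,
                               conditionMessage(e))))
    if (any(width(gr) < 1L)) {
        i <- which(width(gr) < 1L)[1L]
        .parseError(sprintf("interval with end <= start in '%s': %s:%d",
                            path, as.character(seqnames(gr))[i],
                            start(gr)[i] - 1L))
    }
    out <- lapply(names(contigLens), function(ct) numeric(contigLens[[ct]]))
    names(out) <- names(contigLens)
    ct <- as.character(seqnames(gr))
    bad <- !(ct %in% names(contigLens)) | end(gr) > contigLens[ct]
    if (any(bad)) {
        i <- which(bad)[1L]
        .parseError(sprintf("interval out of contig bounds in '%s': %s:%d-%d",
                            path, ct[i], start(gr)[i] - 1L, end(gr)[i]))
    }
    for (i in seq_along(gr))
        out[[ct[i]]][start(gr)[i]:end(gr)[i]] <- mcols(gr)$score[i]
    out
}

#' @rdname readTrackBedGraph
#' @param track named list of per-base numeric vectors.
#' @export
writeTrackBedGraph <- function(track, path) {
    chrom <- character(); starts <- integer(); ends <- integer()
    vals <- numeric()
    for (ct in names(track)) {
        r <- rle(track[[ct]])
        e <- cumsum(r$lengths)
        s <- e - r$lengths + 1L
        keep <- r$values != 0
        chrom <- c(chrom, rep(ct, sum(keep)))
        starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
        vals <- c(vals, r$values[keep])
    }
    if (!length(chrom)) {
        writeLines(character(), path)
        return(invisible(path))
    }
    gr <- GRanges(chrom, IRanges(start = starts, end = ends), score = vals)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read / write the per-cytosine methylation TSV
#'
#' Tab-separated with header `chrom pos strand context mc cov`; positions
#' 0-based; contexts spelled CpG/CpHpG/CpHpH (NA where unclassifiable).
#' Count violations (mc > cov, negatives) are rejected with the offending
#' row number.
#'
#' @param path TSV file.
#' @param spikeIn spike-in contig name recorded in the table (default:
#'   "lambda_spike" if present in the file).
#' @return `readMethTsv`: a [MethylationTable-class].
#' @export
readMethTsv <- function(path, spikeIn = NULL) {
    if (!file.exists(path)) .inputError(sprintf("file not found: %s", path))
    d <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("chrom", "strand",
                                                           "context")),
                           data.table = FALSE, na.strings = "NA")
    need <- c("chrom", "pos", "strand", "context", "mc", "cov")
    if (!all(need %in% names(d)))
        .parseError(sprintf("'%s' lacks columns: %s", path,
                            paste(setdiff(need, names(d)), collapse = ", ")))
    bad <- which(d$mc > d$cov | d$mc < 0 | d$cov < 0)
    if (length(bad))
        .parseError(sprintf("count violation (mc > cov or negative) in '%s' at row %d",
                            path, bad[1L]))
    if (is.null(spikeIn))
        spikeIn <- if ("lambda_spike" %in% d$chrom) "lambda_spike" else ""
    methylationTable(d, spikeIn = spikeIn)
}

#' @rdname readMethTsv
#' @param meth a [MethylationTable-class].
#' @export
writeMethTsv <- function(meth, path) {
    data.table::fwrite(methData(meth), path, sep = "\t", quote = FALSE,
                       na = "NA")
    invisible(path)
}

#' Read / write a SyntheticConfig as YAML
#'
#' Round-trips all fields losslessly; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return `readConfigYaml`: a [SyntheticConfig-class].
#' @export
readConfigYaml <- function(path) {
    if (!file.exists(path)) .inputError(sprintf("file not found: %s", path))
    configFromList(yaml::read_yaml(path))
}

#' @rdname readConfigYaml
#' @param config a [SyntheticConfig-class].
#' @export
writeConfigYaml <- function(config, path) {
    yaml::write_yaml(configAsList(config), path)
    invisible(path)
}
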