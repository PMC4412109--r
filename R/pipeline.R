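PIPELINE_STAGES <- c("simulate", "call", "profile", "stratify", "model")

.pipelinePaths <- function(outdir) {
    nms <- c(genome = "genome.fa", genes = "genes.bed", dyads = "dyads.bed",
             occupancy = "occupancy.bedGraph", meth = "methylation.tsv",
             config = "config.yaml", manifest = "manifest.json")
    setNames(file.path(outdir, nms), names(nms))
}

.trackPath <- function(outdir, nm) file.path(outdir,
                                             paste0("track_", nm, ".bedGraph"))

.requireFile <- function(path, stage) {
    if (!file.exists(path))
        .inputError(sprintf(
            "stage '%s' needs missing input file: %s", stage, path))
    path
}

.loadState <- function(outdir, stage) {
    p <- .pipelinePaths(outdir)
    genome <- readFastaGenome(.requireFile(p[["genome"]], stage))
    config <- readConfigYaml(.requireFile(p[["config"]], stage))
    manifest <- jsonlite::read_json(.requireFile(p[["manifest"]], stage))
    genotype <- manifest$genotype
    geneset <- readGenesBed(.requireFile(p[["genes"]], stage), genome)
    dyRead <- readDyadsBed(.requireFile(p[["dyads"]], stage))
    contigLens <- setNames(width(genome), names(genome))
    dy <- setNames(vector("list", length(contigLens)), names(contigLens))
    for (nm in names(contigLens))
        dy[[nm]] <- if (nm %in% names(dyRead)) dyRead[[nm]] else integer()
    occ <- readTrackBedGraph(.requireFile(p[["occupancy"]], stage),
                             contigLens)
    tracks <- lapply(MARK_NAMES, function(nm)
        readTrackBedGraph(.requireFile(.trackPath(outdir, nm), stage),
                          contigLens))
    names(tracks) <- MARK_NAMES
    meth <- readMethTsv(.requireFile(p[["meth"]], stage))
    landscape <- new("ChromatinLandscape", genome = genome,
                     spikeIn = .spikeName(genome), genes = geneset,
                     nucleosomes = new("NucleosomeModel", dyads = dy,
                                       occupancy = occ),
                     tracks = tracks, genotype = genotype, config = config)
    list(landscape = landscape, meth = meth)
}

.writeTsv <- function(d, path) {
    data.table::fwrite(as.data.frame(d), path, sep = "\t", quote = FALSE,
                       na = "NA")
    path
}

#' Run the simulation / analysis pipeline end to end
#'
#' Executes, in order, any suffix-closed subset of the stages
#' simulate -> call -> profile -> stratify -> model, writing all outputs
#' under `outdir` and finishing with a manifest (package version, config
#' snapshot, genotype, seed, MD5 checksum per output file, timestamp).
#' When "simulate" is not among the stages, earlier outputs are reloaded
#' from `outdir`; a missing input raises an error naming the file. Given
#' the same config, genotype and seed, all data files are byte-identical
#' across runs.
#'
#' @param config a [SyntheticConfig-class].
#' @param outdir output directory (created if needed).
#' @param genotype one of WT, set1, set2, dot1.
#' @param seed base random seed.
#' @param stages character subset of
#'   `c("simulate", "call", "profile", "stratify", "model")`.
#' @return the manifest, invisibly (a named list).
#' @export
runPipeline <- function(config = syntheticConfig(), outdir,
                        genotype = "WT", seed = config@seed,
                        stages = PIPELINE_STAGES) {
    .checkGenotype(genotype)
    stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- .pipelinePaths(outdir)
    state <- NULL

    if ("simulate" %in% stages) {
        sim <- simulateExperiment(config, genotype, seed)
        state <- list(landscape = sim$landscape, meth = sim$meth)
        writeFastaGenome(genomeSeq(sim$landscape), p[["genome"]])
        writeGenesBed(genes(sim$landscape), p[["genes"]])
        writeDyadsBed(dyads(sim$landscape), p[["dyads"]])
        writeTrackBedGraph(occupancy(sim$landscape), p[["occupancy"]])
        for (nm in trackNames(sim$landscape))
            writeTrackBedGraph(markTrack(sim$landscape, nm),
                               .trackPath(outdir, nm))
        writeMethTsv(sim$meth, p[["meth"]])
        writeConfigYaml(config, p[["config"]])
        .writeManifest(outdir, config, genotype, seed)
    }

    for (stage in setdiff(stages, "simulate")) {
        if (is.null(state)) state <- .loadState(outdir, stage)
        landscape <- state$landscape
        meth <- state$meth
        switch(stage,
        call = {
            ctx <- perContextSummary(meth)
            .writeTsv(ctx$levels, file.path(outdir, "context_summary.tsv"))
            nc <- estimateNonconversion(meth)
            jsonlite::write_json(
                list(rate = nc$rate, nSites = nc$nSites,
                     totalCov = nc$totalCov,
                     cpgToNonCpG = ctx$cpgToNonCpG),
                file.path(outdir, "nonconversion.json"),
                auto_unbox = TRUE, digits = NA)
        },
        profile = {
            sig <- siteSignal(meth, context = "CpG",
                              exclude = spikeIn(landscape))
            tss <- anchoredProfile(sig, geneAnchors(genes(landscape), "tss"),
                                   window = 1000L)
            tts <- anchoredProfile(sig, geneAnchors(genes(landscape), "tts"),
                                   window = 1000L)
            mg <- metageneProfile(sig, genes(landscape))
            mn <- metaNucleosome(sig, dyads(landscape), window = 200L)
            .writeTsv(profileTable(tss), file.path(outdir, "profile_tss.tsv"))
            .writeTsv(profileTable(tts), file.path(outdir, "profile_tts.tsv"))
            .writeTsv(profileTable(mg),
                      file.path(outdir, "profile_metagene.tsv"))
            .writeTsv(profileTable(mn),
                      file.path(outdir, "profile_nucleosome.tsv"))
        },
        stratify = {
            su <- summarizeUnits(landscape, meth)
            .writeTsv(su, file.path(outdir, "gene_summary.tsv"))
            dec <- decileStratify(su, "expression")
            .writeTsv(dec, file.path(outdir, "deciles_expression.tsv"))
            sm <- spearmanMatrix(su, c("meth", "H3K4me3", "H3K36me3",
                                       "H3K4me1", "PolII", "DNMT3b"))
            .writeTsv(cbind(feature = rownames(sm$rho),
                            as.data.frame(sm$rho)),
                      file.path(outdir, "spearman_genes.tsv"))
        },
        model = {
            bf <- binFeatures(landscape, meth)
            .writeTsv(bf, file.path(outdir, "binned_features.tsv"))
            full <- c("H3K4me3", "H3K36me3", "H3K4me1", "PolII",
                      "occupancy")
            cmpTab <- withCallingHandlers(
                comparePredictorSets(bf, "meth", list(
                    full = full, marks = c("H3K4me3", "H3K36me3"))),
                warning = function(w) {
                    message("model stage: ", conditionMessage(w))
                    invokeRestart("muffleWarning")
                })
            .writeTsv(cmpTab, file.path(outdir, "model_comparison.tsv"))
            fits <- attr(cmpTab, "fits")
            jsonlite::write_json(
                lapply(fits, function(f) list(
                    response = f@response, predictors = f@predictors,
                    coefficients = as.list(f@coefficients),
                    r2 = f@r2, adjR2 = f@adjR2, pearson = f@pearson,
                    n = f@n, dropped = f@dropped)),
                file.path(outdir, "model_fits.json"),
                auto_unbox = TRUE, digits = NA)
        })
    }
    invisible(.writeManifest(outdir, state$landscape@config,
                             state$landscape@genotype, seed))
}

.writeManifest <- function(outdir, config, genotype, seed) {
    files <- setdiff(list.files(outdir), "manifest.json")
    sums <- tools::md5sum(file.path(outdir, files))
    manifest <- list(
        tool = "chromameth",
        version = as.character(utils::packageVersion("chromameth")),
        genotype = genotype,
        seed = seed,
        config = configAsList(config),
        checksums = as.list(setNames(unname(sums), files)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}
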