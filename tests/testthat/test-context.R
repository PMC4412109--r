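test_that("context classification follows the trinucleotide rules", {
    expect_equal(classifyContext("ACGT", 1, "+"), "CpG")
    expect_equal(classifyContext("ACAGT", 1, "+"), "CpHpG")
    expect_equal(classifyContext("ACATT", 1, "+"), "CpHpH")
    ## '-' strand read on the reverse complement: TTCGAA -> G at 3 pairs
    ## with C, preceded (5'->3' on minus) by complement of C = G => CpG
    expect_equal(classifyContext("TTCGAA", 3, "-"), "CpG")
    expect_equal(classifyContext("CAGTT", 2, "-"), "CpHpG")
    ## not a cytosine on the requested strand
    expect_error(classifyContext("ACGT", 0, "+"),
                 class = "chromameth_classification_error")
    ## too close to the contig end to classify
    expect_true(is.na(classifyContext("AACG", 2, "+")))
    expect_true(is.na(classifyContext("GCAA", 0, "-")))
})

test_that("whole-genome context assignment agrees with scalar classification", {
    cfg <- tinyConfig()
    sim <- simulateExperiment(cfg, "WT", seed = 2)
    d <- methData(sim$meth)
    d <- d[d$chrom == "chrI", ]
    s <- as.character(genomeSeq(sim$landscape)[["chrI"]])
    pick <- d[seq(1, nrow(d), by = 503), ]
    for (i in seq_len(nrow(pick))) {
        expect_identical(pick$context[i],
                         classifyContext(s, pick$pos[i], pick$strand[i]))
    }
})

test_that("weighted level pools counts and refuses empty selections", {
    tab <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 5), strand = "+", context = "CpG",
        mc = c(2, 3), cov = c(10, 5)))
    expect_equal(weightedLevel(tab), 5 / 15)
    allZero <- methylationTable(data.frame(
        chrom = "c", pos = 0:4, strand = "+", context = "CpG",
        mc = 0, cov = 10))
    expect_equal(weightedLevel(allZero), 0)
    allFull <- methylationTable(data.frame(
        chrom = "c", pos = 0:4, strand = "+", context = "CpG",
        mc = 7, cov = 7))
    expect_equal(weightedLevel(allFull), 1)
    expect_error(weightedLevel(tab, context = "CpHpH"),
                 class = "chromameth_input_error")
})

test_that("weighted level is invariant under splitting a site's counts", {
    tab <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 3, 7), strand = "+", context = "CpG",
        mc = c(4, 6, 1), cov = c(10, 12, 9)))
    split <- methylationTable(data.frame(
        chrom = c("c", "c", "c", "c"), pos = c(0, 1, 3, 7),
        strand = c("+", "-", "+", "+"), context = "CpG",
        mc = c(3, 1, 6, 1), cov = c(5, 5, 12, 9)))
    expect_equal(weightedLevel(split), weightedLevel(tab))
})

test_that("per-context summary matches hand arithmetic", {
    s <- perContextSummary(handMethTable())
    lv <- setNames(s$levels$level, s$levels$context)
    expect_equal(lv[["CpG"]], 6 / 20)
    expect_equal(lv[["CpHpG"]], 1 / 15)
    expect_equal(lv[["CpHpH"]], 2 / 20)
    expect_equal(s$nonCpGLevel, 3 / 35)
    expect_equal(s$cpgToNonCpG, (6 / 20) / (3 / 35))
    ## pooled level is the coverage-weighted convex combination
    pooled <- weightedLevel(handMethTable())
    w <- s$levels$totalCov / sum(s$levels$totalCov)
    expect_equal(pooled, sum(w * s$levels$level))
    expect_true(all(s$levels$level >= 0 & s$levels$level <= 1))
})

test_that("contexts absent from the table are absent from the summary", {
    onlyCpG <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 2, 4), strand = "+", context = "CpG",
        mc = 1, cov = 4))
    s <- perContextSummary(onlyCpG)
    expect_identical(s$levels$context, "CpG")
    expect_true(is.na(s$cpgToNonCpG))
})

test_that("non-conversion estimation uses the pooled spike-in level", {
    spikeTab <- function(mc, cov) methylationTable(data.frame(
        chrom = "lambda_spike", pos = seq_along(mc) - 1, strand = "+",
        context = "CpG", mc = mc, cov = cov), spikeIn = "lambda_spike")
    expect_equal(estimateNonconversion(spikeTab(c(0, 0), c(9, 11)))$rate, 0)
    expect_warning(
        r <- estimateNonconversion(spikeTab(c(5, 7), c(5, 7)))$rate,
        "pathological")
    expect_equal(r, 1)
    noSpike <- methylationTable(data.frame(
        chrom = "c", pos = 0, strand = "+", context = "CpG", mc = 0,
        cov = 1))
    expect_error(estimateNonconversion(noSpike, "lambda_spike"),
                 class = "chromameth_input_error")
})

test_that("simulated spike-in recovers the configured non-conversion rate", {
    cfg <- tinyConfig(spikeLength = 40000, coverageMean = 15)
    sim <- simulateExperiment(cfg, "WT", seed = 8)
    est <- estimateNonconversion(sim$meth)
    expect_gte(est$totalCov, 1e5)
    sd <- sqrt(cfg@nonconversion * (1 - cfg@nonconversion) / est$totalCov)
    expect_lt(abs(est$rate - cfg@nonconversion), 3 * sd)
    ## with nonconversion 0 the spike-in is perfectly unmethylated
    sim0 <- simulateExperiment(tinyConfig(nonconversion = 0), "WT",
                               seed = 8)
    expect_equal(estimateNonconversion(sim0$meth)$rate, 0)
})
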