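test_that("unit summaries average tracks over the requested sub-region", {
    cfg <- tinyConfig()
    sim <- cachedSim("WT", 1, cfg)
    ls <- sim$landscape
    ## constant synthetic track: every unit summary equals the constant
    lsConst <- ls
    lsConst@tracks$PolII <- lapply(occupancy(ls), function(v)
        rep(0.7, length(v)))
    su <- summarizeUnits(lsConst, sim$meth)
    expect_true(all(abs(su$PolII - 0.7) < 1e-12))
    ## last-third mode on the 0 -> 1 H3K36me3 ramp: mean over [2/3, 1] of
    ## f is 5/6, scaled by the gene's normalized expression
    suLast <- summarizeUnits(ls, sim$meth, regionMode = "last_third")
    expect_equal(max(unlist(ls@tracks$H3K36me3)), 1)
    ramp <- suLast$H3K36me3 / (suLast$expression / max(su$expression))
    expect_equal(ramp, rep(5 / 6, nrow(suLast)), tolerance = 0.01)
    expect_error(summarizeUnits(ls, sim$meth, regionMode = "middle"),
                 class = "chromameth_parameter_error")
})

test_that("units without covered CpG sites get missing methylation", {
    cfg <- tinyConfig()
    sim <- cachedSim("WT", 1, cfg)
    empty <- methylationTable(methData(sim$meth)[0, ],
                              spikeIn = spikeIn(sim$meth))
    su <- summarizeUnits(sim$landscape, empty)
    expect_true(all(is.na(su$meth)))
})

test_that("decile assignment is balanced, ascending and deterministic", {
    su <- data.frame(unit = sprintf("u%03d", 1:100), key = (1:100)^2 / 50)
    d <- decileStratify(su, "key")
    expect_equal(as.integer(table(d$decile)), rep(10L, 10))
    expect_true(all(diff(d$key) >= 0))
    ## ties broken by unit id, sizes still balanced
    suTie <- data.frame(unit = sprintf("u%03d", 1:25), key = 1)
    dt <- decileStratify(suTie, "key")
    expect_equal(as.integer(table(dt$decile)),
                 c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L))
    expect_equal(dt$unit, sort(suTie$unit))
    ## brute-force balanced partition oracle for several n
    for (n in c(10, 13, 25, 31, 99)) {
        su2 <- data.frame(unit = sprintf("u%03d", 1:n), key = rev(1:n))
        d2 <- decileStratify(su2, "key")
        sizes <- as.integer(table(factor(d2$decile, levels = 1:10)))
        oracle <- rep(n %/% 10L, 10L) + as.integer(seq_len(10L) <= n %% 10L)
        expect_equal(sizes, oracle)
        expect_lte(max(sizes) - min(sizes), 1L)
    }
    expect_error(decileStratify(su[1:5, ], "key"),
                 class = "chromameth_input_error")
    suNA <- su
    suNA$key[1:4] <- NA
    expect_equal(attr(decileStratify(suNA, "key"), "nMissing"), 4L)
})

test_that("spearman matrix equals the rank-then-Pearson oracle", {
    su <- data.frame(unit = letters[1:5],
                     a = c(3, 1, 4, 1.5, 9),
                     b = c(2.6, 5.3, 5.8, 9.7, 9.3),
                     c = c(10, 2, 33, 4, 5))
    sm <- spearmanMatrix(su, c("a", "b", "c"))
    for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
        oracle <- cor(rank(su[[i]]), rank(su[[j]]))
        expect_equal(sm$rho[i, j], oracle, info = paste(i, j))
    }
    expect_equal(unname(diag(sm$rho)), rep(1, 3))
    ## rank invariance under a monotone transform
    su$a3 <- su$a^3
    sm2 <- spearmanMatrix(su, c("a", "a3"))
    expect_equal(sm2$rho["a", "a3"], 1)
    expect_error(spearmanMatrix(su, c("a", "zz")),
                 class = "chromameth_input_error")
})

test_that("spearman matrix matches the oracle on random small instances", {
    set.seed(55)
    for (rep in 1:5) {
        n <- sample(5:20, 1)
        su <- data.frame(unit = seq_len(n), x = rnorm(n), y = rnorm(n))
        su$y[sample(n, 2)] <- NA
        sm <- spearmanMatrix(su, c("x", "y"))
        cc <- !is.na(su$y)
        oracle <- cor(rank(su$x[cc]), rank(su$y[cc]))
        expect_equal(sm$rho["x", "y"], oracle)
        expect_equal(sm$n["x", "y"], sum(cc))
    }
})

test_that("total-methylation normalization yields unit-mean relative levels", {
    tab <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 5, 9), strand = "+", context = "CpG",
        mc = c(1, 2, 3), cov = c(10, 10, 10)))
    norm <- normalizeTotal(list(s = tab))$s
    expect_equal(attr(norm, "totalLevel"), 6 / 30)
    expect_equal(norm$value, c(0.1, 0.2, 0.3) / 0.2)
    expect_equal(sum(norm$value * norm$weight) / sum(norm$weight), 1)
    ## two samples differing by a global factor normalize identically
    tab2 <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 5, 9), strand = "+", context = "CpG",
        mc = c(2, 4, 6), cov = c(20, 20, 20)))
    norm2 <- normalizeTotal(list(a = tab, b = tab2))
    expect_equal(norm2$a$value, norm2$b$value)
    zero <- methylationTable(data.frame(
        chrom = "c", pos = 0:10, strand = "+", context = "CpG", mc = 0,
        cov = 5))
    expect_error(normalizeTotal(list(z = zero)),
                 class = "chromameth_normalization_error")
})

test_that("delta-delta-Ct folds follow the closed form", {
    expect_equal(ddctRelativeExpression(20, 15, 21, 16)$fold, 1)
    expect_equal(ddctRelativeExpression(20, 15, 21, 15)$fold, 0.5)
    r <- ddctRelativeExpression(20, 15, 22, 15)
    expect_equal(r$ddct, 2)
    expect_equal(r$fold, 0.25)
    expect_error(ddctRelativeExpression(-1, 15, 20, 15),
                 class = "chromameth_parameter_error")
})

test_that("expression scaling rescales levels linearly", {
    sig <- data.frame(chrom = "c", pos = 1:3, value = c(0.1, 0.2, 0.3))
    expect_equal(scaleByExpression(sig, 1)$value, sig$value)
    expect_equal(scaleByExpression(sig, 0.5)$value, sig$value * 2)
    expect_error(scaleByExpression(sig, 0),
                 class = "chromameth_parameter_error")
})

test_that("normalizeTotal and scaleByExpression commute up to a constant", {
    tab <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 5, 9), strand = "+", context = "CpG",
        mc = c(1, 2, 3), cov = c(10, 10, 10)))
    normThenScale <- scaleByExpression(normalizeTotal(list(s = tab))$s,
                                       0.5)$value
    scaleThenNorm <- scaleByExpression(siteSignal(tab), 0.5)$value /
        weightedLevel(tab)
    expect_equal(normThenScale, scaleThenNorm)
})

test_that("mutant/wt ratio requires identical grids and flags low bins", {
    gs <- GenomicRanges::GRanges("c", IRanges::IRanges(2001, 3200), "+")
    S4Vectors::mcols(gs)$gene_id <- "g1"
    S4Vectors::mcols(gs)$expression <- 1
    sig <- data.frame(chrom = "c", pos = 1000:4200, value = 0.4)
    mg <- metageneProfile(sig, gs)
    r <- mutantWtRatio(mg, mg)
    expect_true(all(r$ratio[!r$flagged] == 1))
    sigLow <- sig; sigLow$value <- 1e-6
    mgLow <- metageneProfile(sigLow, gs)
    rLow <- mutantWtRatio(mg, mgLow)
    expect_true(all(rLow$flagged[!is.na(profileTable(mgLow)$mean)]))
    mgOther <- metageneProfile(sig, gs, nBodyBins = 30)
    expect_error(mutantWtRatio(mg, mgOther),
                 class = "chromameth_input_error")
})
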