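test_that("site signal emits per-site levels and skips uncovered sites", {
    tab <- methylationTable(data.frame(
        chrom = "c", pos = c(0, 4, 9), strand = "+", context = "CpG",
        mc = c(1, 0, 3), cov = c(4, 0, 6)))
    sig <- siteSignal(tab)
    expect_equal(sig$pos, c(0, 9))
    expect_equal(sig$value, c(0.25, 0.5))
    expect_equal(sig$weight, c(4, 6))
    ## weighted recombination of (level, cov) equals the pooled level
    expect_equal(sum(sig$value * sig$weight) / sum(sig$weight),
                 weightedLevel(tab))
})

test_that("anchored profiles average per offset with exact bookkeeping", {
    sig <- data.frame(chrom = "c", pos = 0:99, value = 0.5)
    anchors <- data.frame(chrom = "c", pos = c(30, 60), strand = "+")
    p <- anchoredProfile(sig, anchors, window = 10)
    expect_true(all(p@mean[p@n > 0] == 0.5))
    expect_true(all(p@n == 2L))
    ## hand-built two-anchor case on a sparse signal
    sig2 <- data.frame(chrom = "c", pos = c(28, 30, 31, 59, 61),
                       value = c(1, 2, 3, 4, 6))
    p2 <- anchoredProfile(sig2, anchors, window = 2)
    pt <- profileTable(p2)
    expect_equal(pt$mean[pt$offset == -2], 1)       # only pos 28
    expect_equal(pt$mean[pt$offset == -1], 4)       # only pos 59
    expect_equal(pt$mean[pt$offset == 0], 2)        # only pos 30
    expect_equal(pt$mean[pt$offset == 1], mean(c(3, 6)))
    expect_equal(pt$n[pt$offset == 2], 0L)
    expect_true(is.na(pt$mean[pt$offset == 2]))
})

test_that("a '-' strand anchor mirrors the '+' computation", {
    sig <- data.frame(chrom = "c", pos = 40:60,
                      value = sin(seq(0, 2, length.out = 21)))
    plus <- anchoredProfile(sig, data.frame(chrom = "c", pos = 50,
                                            strand = "+"), window = 10)
    minus <- anchoredProfile(sig, data.frame(chrom = "c", pos = 50,
                                             strand = "-"), window = 10)
    expect_equal(minus@mean, rev(plus@mean))
    expect_equal(minus@n, rev(plus@n))
    expect_error(anchoredProfile(sig, sig[0, c("chrom", "pos")], 10),
                 class = "chromameth_input_error")
})

mkGenes <- function(chrom, start0, end0, strand) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start0 + 1,
                                                  end = end0),
                                 strand = strand)
    S4Vectors::mcols(gr)$gene_id <- sprintf("g%02d", seq_along(gr))
    S4Vectors::mcols(gr)$expression <- rep(1, length(gr))
    gr
}

test_that("metagene of a constant signal is flat", {
    gs <- mkGenes("c", c(2000, 9000), c(3200, 10500), c("+", "-"))
    sig <- data.frame(chrom = "c", pos = 0:11999, value = 0.3)
    mg <- metageneProfile(sig, gs)
    pt <- profileTable(mg)
    expect_true(all(abs(pt$mean[pt$n > 0] - 0.3) < 1e-12))
})

test_that("fractional-position signal maps to the identity ramp", {
    gs <- mkGenes("c", 3000, 4200, "+")
    pos <- 3000:4199
    sig <- data.frame(chrom = "c", pos = pos,
                      value = (pos - 3000 + 0.5) / 1200)
    mg <- metageneProfile(sig, gs)
    pt <- profileTable(mg)
    body <- pt[pt$region == "body", ]
    expect_equal(body$mean, body$mid, tolerance = 1e-3)
})

test_that("metagene is invariant under strand flip + coordinate mirror", {
    L <- 12000
    set.seed(31)
    pos <- sort(sample(0:(L - 1), 3000))
    val <- runif(length(pos))
    gs <- mkGenes("c", c(2000, 7000), c(3500, 8600), c("+", "-"))
    mg1 <- metageneProfile(data.frame(chrom = "c", pos = pos, value = val),
                           gs)
    gsM <- mkGenes("c", L - c(3500, 8600), L - c(2000, 7000), c("-", "+"))
    mg2 <- metageneProfile(data.frame(chrom = "c", pos = L - 1 - pos,
                                      value = val), gsM)
    expect_equal(profileTable(mg1)$mean, profileTable(mg2)$mean)
    expect_equal(profileTable(mg1)$n, profileTable(mg2)$n)
})

test_that("short genes are excluded and counted", {
    gs <- mkGenes("c", c(100, 5000), c(250, 6000), c("+", "+"))
    sig <- data.frame(chrom = "c", pos = 0:7000, value = 1)
    mg <- metageneProfile(sig, gs)
    expect_equal(mg@nGenes, 1L)
    expect_equal(mg@nExcluded, 1L)
    expect_error(metageneProfile(sig, gs[1]),
                 class = "chromameth_input_error")
})

test_that("meta-nucleosome profile is symmetric and peaks on occupancy", {
    cfg <- tinyConfig()
    sim <- cachedSim("WT", 1, cfg)
    occSig <- trackSignal(sim$landscape, "occupancy")
    mn <- metaNucleosome(occSig, dyads(sim$landscape), window = 120)
    pt <- profileTable(mn)
    ## occupancy is a plateau of 1 across the core: the center attains
    ## the maximum and the flanks fall away
    expect_equal(pt$mean[pt$offset == 0], max(pt$mean))
    expect_lt(pt$mean[pt$offset == 120], pt$mean[pt$offset == 0])
    ## symmetric by construction of the strandless anchors
    expect_equal(pt$mean, rev(pt$mean))
})

test_that("periodicity estimation recovers pure and noisy cosines", {
    x170 <- cos(2 * pi * (-850:850) / 170)
    expect_equal(estimatePeriodicity(x170, 120, 220)$period, 170)
    x10 <- cos(2 * pi * (-73:73) / 10)
    expect_equal(estimatePeriodicity(x10, 5, 20)$period, 10)
    set.seed(77)
    for (truePeriod in c(150, 170, 190)) {
        x <- cos(2 * pi * (0:3500) / truePeriod) +
            rnorm(3501, 0, sd = 1 / sqrt(2) / 2)   # SNR 2
        est <- estimatePeriodicity(x, 120, 220)$period
        expect_lte(abs(est - truePeriod), 2)
    }
    expect_error(estimatePeriodicity(x10, 5, 60),
                 class = "chromameth_input_error")
})

test_that("periodicity estimator equals a brute-force autocorrelation scan", {
    bruteScan <- function(x, minP, maxP, tol = 0.25) {
        w <- maxP
        trend <- vapply(seq_along(x), function(i) {
            ## centered moving average; even widths extend one step forward
            lo <- i - (w %/% 2 - 1); hi <- i + w %/% 2
            if (lo < 1 || hi > length(x)) return(NA_real_)
            mean(x[lo:hi])
        }, numeric(1))
        d <- (x - trend)
        d <- d[!is.na(d)]
        m <- mean(d)
        denom <- sum((d - m)^2)
        ac <- vapply(1:maxP, function(l)
            sum((d[seq_len(length(d) - l)] - m) *
                (d[(l + 1):length(d)] - m)) / denom, numeric(1))
        rng <- minP:maxP
        best <- rng[which.max(ac[rng])]
        divs <- rng[best %% rng == 0 & rng < best &
                    ac[rng] >= (1 - tol) * max(ac[rng])]
        if (length(divs)) best <- min(divs)
        best
    }
    set.seed(13)
    for (rep in 1:6) {
        period <- sample(c(8, 10, 12, 150, 170), 1)
        n <- if (period > 100) 1800 else 160
        x <- cos(2 * pi * (0:n) / period) + rnorm(n + 1, 0, 0.4)
        rng <- if (period > 100) c(120, 220) else c(5, 20)
        expect_equal(estimatePeriodicity(x, rng[1], rng[2])$period,
                     bruteScan(x, rng[1], rng[2]),
                     info = sprintf("rep %d period %d", rep, period))
    }
})

test_that("linker/core contrast matches hand arithmetic", {
    dy <- list(c = c(500L, 700L))
    uniform <- data.frame(chrom = "c", pos = 400:800, value = 0.05)
    expect_equal(linkerCoreIncrease(uniform, dy)$increasePercent, 0)
    pos <- 400:800
    dist <- pmin(abs(pos - 500), abs(pos - 700))
    twoStrata <- data.frame(chrom = "c", pos = pos,
                            value = ifelse(dist <= 73, 0.04, 0.06))
    lc <- linkerCoreIncrease(twoStrata, dy)
    expect_equal(lc$increasePercent, 50)
    expect_equal(lc$core, 0.04)
    expect_equal(lc$linker, 0.06)
    allCore <- data.frame(chrom = "c", pos = 450:550, value = 1)
    expect_error(linkerCoreIncrease(allCore, dy),
                 class = "chromameth_input_error")
})
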