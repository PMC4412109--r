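test_that("feature binning averages tracks and pools CpG counts per bin", {
    cfg <- tinyConfig()
    sim <- cachedSim("WT", 1, cfg)
    ls <- sim$landscape
    lsConst <- ls
    lsConst@tracks$PolII <- lapply(occupancy(ls), function(v)
        rep(0.42, length(v)))
    bf <- binFeatures(lsConst, sim$meth, binWidth = 200, pseudocount = 1e-3)
    expect_true(all(abs(bf$PolII - log(0.42 + 1e-3)) < 1e-12))
    expect_false("lambda_spike" %in% bf$chrom)
    expect_true(all(bf$end - bf$start == 200))
    ## hand re-computation for two bins
    md <- methData(sim$meth)
    md <- md[md$chrom == "chrI" & !is.na(md$context) &
             md$context == "CpG" & md$cov > 0, ]
    for (b in c(3, 17)) {
        sel <- md$pos >= (b - 1) * 200 & md$pos < b * 200
        hand <- log(sum(md$mc[sel]) / sum(md$cov[sel]) + 1e-3)
        expect_equal(bf$meth[bf$chrom == "chrI" & bf$start == (b - 1) * 200],
                     hand)
        handOcc <- log(mean(occupancy(ls)$chrI[((b - 1) * 200 + 1):(b * 200)]) +
                       1e-3)
        expect_equal(bf$occupancy[bf$chrom == "chrI" &
                                  bf$start == (b - 1) * 200], handOcc)
    }
    ## a bin without covered CpG gets a missing methylation value
    empty <- methylationTable(md[0, ], spikeIn = "lambda_spike")
    bf0 <- binFeatures(ls, empty)
    expect_true(all(is.na(bf0$meth)))
    expect_equal(attr(bf0, "nNoMeth"), nrow(bf0))
})

test_that("an exact linear response is recovered perfectly", {
    set.seed(3)
    d <- data.frame(x1 = rnorm(50), x2 = runif(50))
    d$y <- 2 - 3 * d$x1 + 0.5 * d$x2
    ## summary.lm flags the (intentionally) perfect fit
    f <- suppressWarnings(fitLinearModel(d, c("x1", "x2"), "y"))
    expect_equal(unname(f@coefficients), c(2, -3, 0.5), tolerance = 1e-10)
    expect_equal(f@adjR2, 1, tolerance = 1e-10)
    expect_equal(f@pearson, 1, tolerance = 1e-10)
})

test_that("independent noise yields adjusted R-squared near zero", {
    set.seed(8)
    vals <- replicate(5, {
        d <- data.frame(x1 = rnorm(1000), x2 = rnorm(1000),
                        y = rnorm(1000))
        fitLinearModel(d, c("x1", "x2"), "y")@adjR2
    })
    expect_true(all(abs(vals) < 0.02))
})

test_that("simple regression matches the closed-form slope and intercept", {
    d <- data.frame(x = c(1, 2, 4, 5, 7), y = c(2, 3, 5.5, 6, 9))
    f <- fitLinearModel(d, "x", "y")
    slope <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) /
        sum((d$x - mean(d$x))^2)
    intercept <- mean(d$y) - slope * mean(d$x)
    expect_equal(unname(f@coefficients), c(intercept, slope))
    r2 <- cor(d$x, d$y)^2
    expect_equal(f@r2, r2)
    expect_equal(f@adjR2, 1 - (1 - r2) * (5 - 1) / (5 - 1 - 1))
})

test_that("OLS equals the brute-force normal-equation solution", {
    set.seed(21)
    for (rep in 1:8) {
        n <- sample(10:30, 1)
        p <- sample(1:3, 1)
        X <- matrix(rnorm(n * p), n, p)
        colnames(X) <- paste0("x", seq_len(p))
        d <- as.data.frame(X)
        d$y <- rnorm(n)
        f <- fitLinearModel(d, colnames(X), "y")
        Xd <- cbind(1, X)
        beta <- solve(t(Xd) %*% Xd, t(Xd) %*% d$y)
        expect_equal(unname(f@coefficients), as.numeric(beta),
                     tolerance = 1e-8)
        res <- d$y - Xd %*% beta
        r2 <- 1 - sum(res^2) / sum((d$y - mean(d$y))^2)
        expect_equal(f@r2, r2, tolerance = 1e-8)
        expect_equal(f@adjR2, 1 - (1 - r2) * (n - 1) / (n - p - 1),
                     tolerance = 1e-8)
    }
})

test_that("coefficients recover the generating model within 3 SE", {
    set.seed(14)
    hits <- replicate(10, {
        n <- 400
        d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
        d$y <- 1 + 0.8 * d$x1 - 0.5 * d$x2 + rnorm(n, 0, 0.7)
        fit <- lm(y ~ x1 + x2, d)
        se <- sqrt(diag(vcov(fit)))
        f <- fitLinearModel(d, c("x1", "x2"), "y")
        all(abs(f@coefficients - c(1, 0.8, -0.5)) < 3 * se)
    })
    expect_gte(sum(hits), 9)
})

test_that("predictor-set comparison is monotone, comparable and deterministic", {
    set.seed(5)
    d <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
    d$y <- d$x1 + 0.3 * d$x2 + rnorm(200, 0, 0.5)
    cmp <- comparePredictorSets(d, "y", list(
        one = "x1", two = c("x1", "x2"), three = c("x1", "x2", "x3"),
        twoAgain = c("x1", "x2")))
    ## adding a predictor never decreases unadjusted R2
    expect_gte(cmp$r2[cmp$set == "two"], cmp$r2[cmp$set == "one"])
    expect_gte(cmp$r2[cmp$set == "three"], cmp$r2[cmp$set == "two"])
    ## a duplicated set yields identical values
    expect_equal(cmp[cmp$set == "two", -1], cmp[cmp$set == "twoAgain", -1],
                 ignore_attr = TRUE)
    ## all sets fit on the identical row subset
    expect_equal(unique(cmp$n), 200L)
})

test_that("constant predictors are dropped with a warning", {
    set.seed(6)
    d <- data.frame(x1 = rnorm(100), flat = 0)
    d$y <- d$x1 + rnorm(100, 0, 0.1)
    expect_warning(f <- fitLinearModel(d, c("x1", "flat"), "y"),
                   "constant")
    expect_equal(f@dropped, "flat")
    expect_equal(f@predictors, "x1")
})
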