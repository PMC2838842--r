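pairedDesign <- function(nArr) makeDesign("two-group-paired", nGroups = 2,
                                          technicalReplicates = nArr)

test_that("design matrix ranks match the free-parameter count of the layout", {
    d <- pairedDesign(10)
    expect_equal(buildDesignMatrix(d, modelSpec(includeArray = TRUE))@rank,
                 11L)  # intercept + 1 treatment + 9 free array effects
    expect_equal(buildDesignMatrix(d, modelSpec(includeArray = FALSE))@rank,
                 2L)
})

test_that("a single-array design drops the array column as aliased, not silently", {
    d <- HybridizationDesign(data.frame(
        array_id = "A1", dye = c("Cy3", "Cy5"), sample_id = c("s1", "s2"),
        treatment = c("T1", "T2"), unit = "u"))
    b <- buildDesignMatrix(d, modelSpec(includeArray = TRUE))
    expect_equal(b@rank, 2L)
    expect_true("arrayA1" %in% b@aliased)
})

test_that("fitGene recovers noiseless coefficients exactly", {
    d <- pairedDesign(6)
    b <- buildDesignMatrix(d, modelSpec(includeArray = TRUE))
    beta <- seq_len(b@rank) / 10
    y <- drop(b@matrix %*% beta)
    fit <- fitGene(y, b)
    expect_equal(unname(fit@coefficients), beta, tolerance = 1e-10)
    expect_equal(fit@rss, 0)
    expect_true(fit@exactFit)
})

test_that("fitGene matches an independent pseudo-inverse solve on random probes", {
    d <- pairedDesign(6)
    b <- buildDesignMatrix(d, modelSpec(includeArray = TRUE))
    set.seed(31)
    for (i in 1:10) {
        y <- rnorm(12, 9, 1)
        fit <- fitGene(y, b)
        orc <- pinvFit(b@matrix, y)
        expect_equal(unname(fit@coefficients), orc$beta, tolerance = 1e-9)
        expect_equal(fit@rss, orc$rss, tolerance = 1e-9)
    }
})

test_that("the intensity-model F-test reproduces classical one-way ANOVA", {
    d <- HybridizationDesign(data.frame(
        array_id = rep(paste0("A", 1:3), each = 2),
        dye = rep(c("Cy3", "Cy5"), 3),
        sample_id = paste0("s", 1:6),
        treatment = rep(c("T1", "T2"), each = 3)[c(1, 4, 2, 5, 3, 6)],
        unit = "u"))
    spec <- modelSpec(includeArray = FALSE)
    b <- buildDesignMatrix(d, spec)
    set.seed(32)
    y <- rnorm(6) + (designTable(d)$treatment == "T2")
    full <- fitGene(y, b)
    ft <- fTestTreatment(full, fitGene(y, dropTreatment(b)))
    lmfit <- anova(lm(y ~ factor(designTable(d)$treatment)))
    expect_equal(ft$F, lmfit$`F value`[1], tolerance = 1e-10)
    expect_equal(ft$p, lmfit$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("the ratio-model F-test equals the paired t-test on log-ratios", {
    nArr <- 8
    d <- pairedDesign(nArr)
    sim <- simulateDataset(simConfig(nProbes = 30, technicalReplicates = nArr,
                                     sigmaArray = 0.3, seed = 33))
    rt <- fitDataset(sim$channels, sim$design, modelSpec(includeArray = TRUE))
    tab <- designTable(sim$design)
    vals <- assay(sim$channels)
    g1 <- rownames(tab)[tab$treatment == "G1"]
    g2 <- rownames(tab)[tab$treatment == "G2"]
    ## order both by array so columns pair up
    g1 <- g1[order(sub(":.*", "", g1))]
    g2 <- g2[order(sub(":.*", "", g2))]
    for (p in c(1, 7, 30)) {
        M <- vals[p, g2] - vals[p, g1]
        tt <- t.test(M)
        expect_equal(rt$F[p], unname(tt$statistic)^2, tolerance = 1e-8)
        expect_equal(rt$p[p], tt$p.value, tolerance = 1e-8)
    }
})

test_that("degenerate responses are flagged, not thrown", {
    d <- pairedDesign(4)
    bF <- buildDesignMatrix(d, modelSpec(includeArray = TRUE))
    bR <- buildDesignMatrix(d, modelSpec(includeArray = FALSE))
    y <- rep(5, 8)
    ftConst <- fTestTreatment(fitGene(y, bF), fitGene(y, dropTreatment(bF)))
    expect_equal(ftConst$F, 0)
    expect_equal(ftConst$p, 1)
    expect_equal(unname(fitGene(y, bR)@mValues), 0)
})

test_that("BIC prefers the smaller model at equal fit and errors on mismatched n", {
    gf <- function(rss, n, rank) new("GeneFit", coefficients = 0,
        fitted = numeric(n), rss = rss, dfResidual = as.integer(n - rank),
        n = as.integer(n),
        logLik = -n / 2 * (log(2 * pi) + log(rss / n) + 1),
        bic = n * (log(2 * pi) + log(rss / n) + 1) + (rank + 1) * log(n),
        fStat = NA_real_, pValue = NA_real_, mValues = 0, exactFit = FALSE)
    expect_equal(bicCompare(gf(2, 16, 9), gf(2, 16, 2)), "intensity")
    expect_error(bicCompare(gf(2, 16, 9), gf(2, 12, 2)), "n differs")
})

test_that("fitDataset is rowwise-independent and shares M-values across models", {
    sim <- simulateDataset(simConfig(nProbes = 100, technicalReplicates = 8,
                                     seed = 34))
    fits <- fitBoth(sim)
    expect_equal(nrow(fits$ratio), 100L)
    ## balanced design: treatment effect estimates identical across models
    expect_equal(fits$ratio$`M.G2-G1`, fits$intensity$`M.G2-G1`,
                 tolerance = 1e-10)
    ## permuting probe rows permutes results identically
    perm <- sample(100)
    shuffled <- sim$channels[perm, ]
    rtP <- fitDataset(shuffled, sim$design, modelSpec(includeArray = TRUE))
    expect_equal(rtP$p, fits$ratio$p[perm], tolerance = 1e-12)
})

test_that("M-values are antisymmetric under group relabeling", {
    sim <- simulateDataset(simConfig(nProbes = 20, topology = "interwoven-loop",
                                     nGroups = 3, nUnitsPerGroup = 2,
                                     seed = 35))
    rt <- fitDataset(sim$channels, sim$design, modelSpec(includeArray = FALSE))
    tab <- designTable(sim$design)
    tab$treatment <- chartr("13", "31", tab$treatment)  # swap G1 <-> G3
    rt2 <- fitDataset(sim$channels, HybridizationDesign(tab),
                      modelSpec(includeArray = FALSE))
    expect_equal(rt2$`M.G3-G1`, -rt$`M.G3-G1`, tolerance = 1e-10)
})

test_that("null probes give uniform p-values under both models", {
    ## zero array variance: both models are correctly specified under the
    ## null (with array effects present the intensity model is not)
    sim <- simulateDataset(simConfig(nProbes = 500, technicalReplicates = 8,
                                     fractionDE = 0, sigmaArray = 0,
                                     seed = 36))
    fits <- fitBoth(sim)
    expect_gt(ks.test(fits$ratio$p, "punif")$p.value, 0.01)
    expect_gt(ks.test(fits$intensity$p, "punif")$p.value, 0.01)
})

test_that("result tables round-trip through TSV", {
    sim <- simulateDataset(simConfig(nProbes = 10, seed = 37))
    rt <- fitDataset(sim$channels, sim$design, modelSpec(includeArray = TRUE))
    f <- withr::local_tempfile(fileext = ".tsv")
    writeResultTable(rt, f)
    back <- readResultTable(f)
    expect_equal(back$p, rt$p, tolerance = 1e-15)
    expect_equal(back$`M.G2-G1`, rt$`M.G2-G1`, tolerance = 1e-15)
})
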