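test_that("p-value rank correlation is 1 for rank-equivalent tables, ~0 for noise", {
    set.seed(41)
    p <- runif(1000)
    r1 <- fakeResults(p)
    expect_equal(pvalueReproducibility(r1, r1), 1)
    ## strictly increasing transform leaves ranks (hence rho) unchanged
    expect_equal(pvalueReproducibility(r1, fakeResults(p^2)), 1)
    expect_lt(abs(pvalueReproducibility(r1, fakeResults(runif(1000)))), 0.1)
    expect_error(pvalueReproducibility(fakeResults(c(.1, .2)),
                                       fakeResults(c(.1, .2))), "at least 3")
})

test_that("bin overlap is 1 for identical rankings and 0 for reversed ones", {
    set.seed(42)
    p <- runif(200)
    r1 <- fakeResults(p)
    expect_true(all(binOverlap(r1, r1, 50)$overlap == 1))
    ## exactly reversed ranking, 2 bins of 100: nothing shared per bin
    rev2 <- fakeResults(1 - p)
    expect_equal(binOverlap(r1, rev2, 100)$overlap, c(0, 0))
    ## invariant to monotone transforms of either p-vector
    expect_equal(binOverlap(r1, fakeResults(log(p + 1), ids = r1$probe_id),
                            50)$overlap,
                 binOverlap(r1, fakeResults(p, ids = r1$probe_id),
                            50)$overlap)
    ## trailing partial bin uses its own size
    bo <- binOverlap(r1, r1, 70)
    expect_equal(bo$size, c(70, 70, 60))
    expect_true(all(bo$overlap == 1))
})

test_that("top-k overlap obeys its identities and the k/n law for random ranks", {
    set.seed(43)
    p <- runif(2000)
    r1 <- fakeResults(p)
    curve <- topkOverlapCurve(r1, r1)
    expect_true(all(curve$overlap == 1))
    expect_equal(topkOverlapCurve(r1, fakeResults(runif(2000)),
                                  kMin = 2000, kMax = 2000)$overlap, 1)
    ## expectation k/n under independent rankings, averaged over seeds
    ks <- c(100, 500, 900)
    acc <- matrix(0, 20, length(ks))
    for (s in 1:20) {
        set.seed(s)
        acc[s, ] <- topkOverlapCurve(r1, fakeResults(runif(2000)),
                                     kMin = 100, kMax = 1000,
                                     step = 400)$overlap
    }
    expect_true(all(abs(colMeans(acc) - ks / 2000) < 0.02))
})

test_that("recall at the ratio cutoff matches brute-force enumeration", {
    rR <- fakeResults(c(.01, .02, .03, .04, .05, .3, .4, .5, .6, .7))
    ## intensity analysis: smaller p everywhere preserves recall 1
    rI <- fakeResults(rR$p / 10, ids = rR$probe_id)
    out <- recallAtRatioCutoff(rR, rI, k = 5)
    expect_equal(out$recall, 1)
    same <- recallAtRatioCutoff(rR, rR, k = 5)
    expect_equal(same$recall, 1)
    expect_equal(same$extra, 0)
    ## hand-checkable table: intensity reorders two probes across the cutoff
    pI <- c(.01, .02, .06, .04, .05, .02, .4, .5, .6, .7)
    out2 <- recallAtRatioCutoff(rR, fakeResults(pI, ids = rR$probe_id), k = 5)
    cutoff <- sort(rR$p)[5]
    topIds <- rR$probe_id[order(rR$p)][1:5]
    expect_equal(out2$recall,
                 mean(pI[match(topIds, rR$probe_id)] <= cutoff))  # 4/5
    expect_equal(out2$recall, 0.8)
    expect_equal(out2$extra, sum(pI[-match(topIds, rR$probe_id)] < cutoff))
    expect_equal(out2$extra, 1L)
})

## In the factorial loop (T1,T2),(T2,T3),(T3,T4),(T4,T1) the sample pair
## (T1, T2) is co-hybridized on A1 while the same two samples also sit on
## A4 (Cy5) and A2 (Cy3): the in-silico reconstruction of the A1 ratio.
reconstructionSim <- function(sigmaNoise, seed)
    simulateDataset(simConfig(nProbes = 400,
                              topology = "factorial-replicated",
                              nGroups = 4, nUnitsPerGroup = 1,
                              technicalReplicates = 1, fractionDE = 1,
                              effectSd = 0.5, sigmaArray = 0,
                              sigmaNoise = sigmaNoise, seed = seed))

test_that("reconstructed ratios correlate with direct ratios when array effects are small", {
    sim <- reconstructionSim(0.05, 51)
    ## trivially: "reconstructing" from the direct channels themselves
    recId <- reconstructRatios(sim$channels, sim$design,
                               data.frame(channelA = "A1:Cy3",
                                          channelB = "A1:Cy5",
                                          directArray = "A1"))
    expect_equal(recId$meanR, 1)
    ## genuine off-array reconstruction of the same sample pair
    rec <- reconstructRatios(sim$channels, sim$design,
                             data.frame(channelA = "A4:Cy5",
                                        channelB = "A2:Cy3",
                                        directArray = "A1"))
    expect_gt(rec$meanR, 0.95)
    expect_error(reconstructRatios(sim$channels, sim$design,
                                   data.frame(channelA = "A9:Cy3",
                                              channelB = "A2:Cy3",
                                              directArray = "A1")),
                 "channel not in matrix")
    ## direct array must co-hybridize the named samples
    expect_error(reconstructRatios(sim$channels, sim$design,
                                   data.frame(channelA = "A4:Cy5",
                                              channelB = "A2:Cy3",
                                              directArray = "A3")),
                 "does not co-hybridize")
})

test_that("reconstruction quality degrades monotonically with channel noise", {
    rs <- vapply(c(0.05, 0.3, 1.0), function(sn) {
        sim <- reconstructionSim(sn, 52)
        reconstructRatios(sim$channels, sim$design,
                          data.frame(channelA = "A4:Cy5",
                                     channelB = "A2:Cy3",
                                     directArray = "A1"))$meanR
    }, numeric(1))
    expect_gt(rs[1], 0.95)
    expect_true(all(diff(rs) < 0))
})

test_that("treatment effect sizes dominate array effect sizes when simulated so", {
    sim <- simulateDataset(simConfig(nProbes = 300, technicalReplicates = 8,
                                     fractionDE = 1, effectSd = 1,
                                     sigmaArray = 0.05, seed = 53))
    rt <- fitDataset(sim$channels, sim$design, modelSpec(includeArray = TRUE))
    es <- effectSizeComparison(rt)
    expect_gt(mean(es$sizes$treatment), mean(es$sizes$array))
    expect_s3_class(es$treatmentDensity, "density")
    rtI <- fitDataset(sim$channels, sim$design,
                      modelSpec(includeArray = FALSE))
    expect_error(effectSizeComparison(rtI), "array")
})

test_that("single-probe effect sizes equal the absolute pairwise M-value", {
    d <- makeDesign("two-group-paired", technicalReplicates = 4)
    tab <- designTable(d)
    y <- ifelse(tab$treatment == "G2", 0.25, -0.25) + 8
    cs <- ChannelSet(matrix(y, 1, dimnames = list("p1", rownames(tab))),
                     arrayIds = tab$array_id, dyes = tab$dye,
                     logScale = TRUE)
    rt <- fitDataset(cs, d, modelSpec(includeArray = TRUE))
    es <- effectSizeComparison(rt)
    expect_equal(es$sizes$treatment, 0.5)
    expect_equal(es$sizes$array, 0, tolerance = 1e-10)
})

test_that("channel clustering pairs technical replicates and matches longhand linkage", {
    set.seed(54)
    base <- rnorm(50)
    vals <- cbind(base, base, rnorm(50))
    cs <- ChannelSet(vals, arrayIds = c("A1", "A1", "A2"),
                     dyes = c("Cy3", "Cy5", "Cy3"), logScale = TRUE)
    hc <- clusterChannels(cs)
    ## identical channels merge first at height 0
    expect_equal(hc$merge[1, ], c(-1, -2))
    expect_equal(hc$height[1], 0, tolerance = 1e-12)
    ## longhand complete linkage on the 3-channel correlation matrix
    dmat <- 1 - cor(vals)
    expect_equal(hc$height[2], max(dmat[3, 1:2]), tolerance = 1e-12)

    ## simulated factorial: each treatment's replicate channels are siblings
    sim <- simulateDataset(simConfig(nProbes = 300,
                                     topology = "factorial-replicated",
                                     nGroups = 4, nUnitsPerGroup = 1,
                                     technicalReplicates = 2,
                                     fractionDE = 1, effectSd = 1.5,
                                     sigmaArray = 0.05, sigmaNoise = 0.1,
                                     seed = 55))
    hc2 <- clusterChannels(sim$channels)
    grp <- designTable(sim$design)[hc2$labels, "treatment"]
    cl <- cutree(hc2, k = 4)
    expect_true(all(tapply(grp, cl, function(g) length(unique(g))) == 1))

    expect_error(clusterChannels(ChannelSet(cbind(c(1, 1), c(1, 2), c(2, 1)),
                                            arrayIds = c("A1", "A1", "A2"),
                                            dyes = c("Cy3", "Cy5", "Cy3"),
                                            logScale = TRUE)),
                 "constant channel")
})

test_that("dendrograms export as readable Newick trees", {
    sim <- simulateDataset(simConfig(nProbes = 50, technicalReplicates = 3,
                                     seed = 56))
    f <- withr::local_tempfile(fileext = ".nwk")
    writeDendrogram(clusterChannels(sim$channels), f)
    tree <- ape::read.tree(f)
    ## ':' is reserved in Newick; labels come back with '-' instead
    expect_setequal(tree$tip.label, chartr(":", "-", colnames(sim$channels)))
})

test_that("M-value reproducibility is 1 for identical tables and ~0 under the null", {
    sim <- simulateDataset(simConfig(nProbes = 400, technicalReplicates = 8,
                                     fractionDE = 0, seed = 57))
    fits <- fitBoth(sim)
    expect_equal(mValueReproducibility(fits$ratio, fits$ratio, "G2", "G1"), 1)
    ## sign flip when the contrast is reversed
    expect_equal(mValueReproducibility(fits$ratio, fits$ratio, "G1", "G2"), 1)
    sim2 <- simulateDataset(simConfig(nProbes = 400, technicalReplicates = 8,
                                      fractionDE = 0, seed = 58))
    rt2 <- fitDataset(sim2$channels, sim2$design,
                      modelSpec(includeArray = TRUE))
    expect_lt(abs(mValueReproducibility(fits$ratio, rt2, "G2", "G1")), 0.15)
    expect_error(mValueReproducibility(fits$ratio, rt2, "G2", "G9"),
                 "not present")
})
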