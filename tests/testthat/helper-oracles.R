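suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(withr)
})

## Independent oracles used across tests.  These deliberately avoid the
## package's own fitting path: least squares via an SVD pseudo-inverse,
## F-tests from the textbook RSS formula, rejection rates by Monte Carlo.

## Moore-Penrose pseudo-inverse least squares.
pinvFit <- function(X, y) {
    s <- svd(X)
    pos <- s$d > 1e-10 * s$d[1L]
    beta <- s$v[, pos, drop = FALSE] %*%
        ((t(s$u[, pos, drop = FALSE]) %*% y) / s$d[pos])
    fitted <- drop(X %*% beta)
    list(beta = drop(beta), fitted = fitted, rss = sum((y - fitted)^2))
}

## Textbook F-test of nested least-squares models.
oracleF <- function(X, Xr, y) {
    f <- pinvFit(X, y)
    r <- pinvFit(Xr, y)
    df2 <- length(y) - qr(X)$rank
    df1 <- qr(X)$rank - qr(Xr)$rank
    F <- ((r$rss - f$rss) / df1) / (f$rss / df2)
    list(F = F, p = pf(F, df1, df2, lower.tail = FALSE),
         rss = f$rss, beta = f$beta)
}

## Monte-Carlo rejection rate of the paired t-test: arrays share an array
## effect which the within-array difference cancels exactly.
mcPairedPower <- function(delta, sigmaE, sigmaA, nArr, alpha, reps, seed) {
    set.seed(seed)
    d <- matrix(rnorm(reps * nArr, mean = delta, sd = sqrt(2) * sigmaE),
                reps, nArr)
    m <- rowMeans(d)
    s <- sqrt((rowSums(d^2) - nArr * m^2) / (nArr - 1))
    tstat <- m / (s / sqrt(nArr))
    mean(abs(tstat) > qt(1 - alpha / 2, nArr - 1))
}

## Monte-Carlo rejection rate of the pooled two-sample t-test under the
## sampling model the intensity analysis assumes: independent channels
## with per-channel sd sqrt(sigmaA^2 + sigmaE^2).
mcTwoSamplePower <- function(delta, sigmaE, sigmaA, nArr, alpha, reps, seed) {
    set.seed(seed)
    sdc <- sqrt(sigmaA^2 + sigmaE^2)
    y1 <- matrix(rnorm(reps * nArr, 0, sdc), reps, nArr)
    y2 <- matrix(rnorm(reps * nArr, delta, sdc), reps, nArr)
    m1 <- rowMeans(y1); m2 <- rowMeans(y2)
    ss1 <- rowSums(y1^2) - nArr * m1^2
    ss2 <- rowSums(y2^2) - nArr * m2^2
    sp <- sqrt((ss1 + ss2) / (2 * nArr - 2))
    tstat <- (m2 - m1) / (sp * sqrt(2 / nArr))
    mean(abs(tstat) > qt(1 - alpha / 2, 2 * nArr - 2))
}

## Bundle with all treatment columns removed (reduced model for F-tests).
dropTreatment <- function(b) {
    keep <- setdiff(seq_len(b@rank), b@treatmentCols)
    new("DesignMatrixBundle", matrix = b@matrix[, keep, drop = FALSE],
        aliased = b@aliased, rank = length(keep),
        treatmentCols = integer(0), treatmentLevels = b@treatmentLevels,
        arrayCols = match(b@arrayCols, keep), channels = b@channels)
}

## A small simulated dataset fit under both model specifications.
fitBoth <- function(sim, unit = NULL) {
    list(ratio = fitDataset(sim$channels, sim$design,
                            modelSpec(unit = unit, includeArray = TRUE)),
         intensity = fitDataset(sim$channels, sim$design,
                                modelSpec(unit = unit, includeArray = FALSE)))
}

## Result table with given p-values (minimal columns for ranking metrics).
fakeResults <- function(p, ids = sprintf("P%04d", seq_along(p)))
    data.frame(probe_id = ids, p = p, stringsAsFactors = FALSE)
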