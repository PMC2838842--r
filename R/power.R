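## Analytic power of the two genewise analyses for a direct two-group
## design in which both groups are co-hybridized on every array, via the
## non-central t distribution.  Array effects are treated as fixed, as the
## ratio model implies: pairing cancels them exactly, while the two-sample
## (intensity) analysis absorbs them into the per-channel variance.

.checkPowerArgs <- function(delta, sigmaE, sigmaA, nArrays, alpha) {
    if (any(sigmaE <= 0)) stop("sigmaE must be > 0")
    if (any(sigmaA < 0)) stop("sigmaA must be >= 0")
    if (any(nArrays < 2)) stop("nArrays must be >= 2")
    if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
    invisible(TRUE)
}

## Two-sided rejection probability of a t-test with noncentrality ncp.
.ncpPower <- function(ncp, df, alpha) {
    len <- max(length(ncp), length(df), length(alpha))
    ncp <- rep_len(ncp, len)
    df <- rep_len(df, len)
    alpha <- rep_len(alpha, len)
    tcrit <- stats::qt(1 - alpha / 2, df)
    pow <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
        stats::pt(-tcrit, df, ncp = ncp)
    ## exact size at zero effect (the ncp algorithm is only ~1e-8 accurate)
    pow[ncp == 0] <- alpha[ncp == 0]
    pow
}

#' Power of the paired analysis (model with array effect)
#'
#' The ratio-based analysis of a direct two-group design reduces to a
#' paired t-test on within-array log2 differences: the array term cancels,
#' the difference has standard deviation sqrt(2) sigmaE, and the test has
#' nArrays - 1 degrees of freedom.  Power is invariant to `sigmaA`.
#'
#' @param delta true treatment effect (log2 units).
#' @param sigmaE within-array residual standard deviation.
#' @param sigmaA between-array (array-effect) standard deviation;
#'   accepted for interface symmetry, has no influence here.
#' @param nArrays number of arrays (pairs).
#' @param alpha two-sided test level (default 0.05).
#' @return rejection probability in `[0, 1]`; vectorized over arguments.
#' @examples
#' powerWithArrayEffect(0, 0.2, nArrays = 10)     # = alpha
#' powerWithArrayEffect(0.5, 0.2, nArrays = 10)   # near 1
#' @export
powerWithArrayEffect <- function(delta, sigmaE, sigmaA = 0, nArrays,
                                 alpha = 0.05) {
    .checkPowerArgs(delta, sigmaE, sigmaA, nArrays, alpha)
    df <- nArrays - 1
    ncp <- delta / (sqrt(2) * sigmaE / sqrt(nArrays))
    .ncpPower(ncp, df, alpha)
}

#' Power of the two-sample analysis (model without array effect)
#'
#' The intensity-based analysis treats the 2 nArrays channels as two
#' independent groups of nArrays observations with per-channel standard
#' deviation sqrt(sigmaA^2 + sigmaE^2) and 2 nArrays - 2 degrees of
#' freedom.  It gains degrees of freedom over the paired analysis but pays
#' for any array variance it cannot cancel.
#'
#' @inheritParams powerWithArrayEffect
#' @return rejection probability in `[0, 1]`; vectorized over arguments.
#' @export
powerWithoutArrayEffect <- function(delta, sigmaE, sigmaA = 0, nArrays,
                                    alpha = 0.05) {
    .checkPowerArgs(delta, sigmaE, sigmaA, nArrays, alpha)
    df <- 2 * nArrays - 2
    sdc <- sqrt(sigmaA^2 + sigmaE^2)
    ncp <- delta / (sdc * sqrt(2 / nArrays))
    .ncpPower(ncp, df, alpha)
}

#' Power curves of both analyses over a sample-size grid
#'
#' Evaluates [powerWithArrayEffect()] and [powerWithoutArrayEffect()] on
#' an increasing grid of array counts and locates crossings (sign changes
#' of their difference, with a linearly interpolated crossing point).
#' Whenever sigmaA > 0 the curve including the array effect is the
#' steeper one at small n.
#'
#' @inheritParams powerWithArrayEffect
#' @param nGrid increasing integer vector of array counts, all >= 2.
#' @return list with `curve` (`data.frame`: `n`, `powerWith`,
#'   `powerWithout`, `diff`) and `crossings` (interpolated n values where
#'   the difference changes sign; empty if none).
#' @export
powerCurves <- function(delta, sigmaE, sigmaA = 0, nGrid = 2:50,
                        alpha = 0.05) {
    if (is.unsorted(nGrid, strictly = TRUE))
        stop("nGrid must be strictly increasing")
    pw <- powerWithArrayEffect(delta, sigmaE, sigmaA, nGrid, alpha)
    po <- powerWithoutArrayEffect(delta, sigmaE, sigmaA, nGrid, alpha)
    d <- pw - po
    s <- sign(d)
    idx <- which(s[-1L] * s[-length(s)] < 0)
    crossings <- vapply(idx, function(i) {
        ## linear interpolation of the zero of d between nGrid[i], nGrid[i+1]
        nGrid[i] + d[i] * (nGrid[i + 1L] - nGrid[i]) / (d[i] - d[i + 1L])
    }, numeric(1L))
    list(curve = data.frame(n = nGrid, powerWith = pw, powerWithout = po,
                            diff = d),
         crossings = crossings)
}

#' Average power over a set of probes with differential signal
#'
#' Restricts to probes with |effect size| strictly larger than `minEffect`
#' (emulating a set containing differential signal) and averages the
#' chosen analysis's per-probe power -- the expected number of genes
#' declared significant divided by the gene count.
#'
#' @param deltas per-probe effect sizes (log2 units).
#' @param sigmaE,sigmaA per-probe (or scalar, recycled) standard
#'   deviations.
#' @param nArrays number of arrays.
#' @param alpha two-sided test level.
#' @param minEffect effect-size filter (default 0.25, strict inequality).
#' @param model `"with"` (array effect) or `"without"`.
#' @return mean power over the retained probes.
#' @export
averagePower <- function(deltas, sigmaE, sigmaA = 0, nArrays, alpha = 0.05,
                         minEffect = 0.25, model = c("with", "without")) {
    model <- match.arg(model)
    np <- length(deltas)
    sigmaE <- rep_len(sigmaE, np)
    sigmaA <- rep_len(sigmaA, np)
    keep <- abs(deltas) > minEffect
    if (!any(keep))
        stop("no probes with |effect| > ", minEffect)
    f <- if (model == "with") powerWithArrayEffect else
        powerWithoutArrayEffect
    mean(f(deltas[keep], sigmaE[keep], sigmaA[keep], nArrays, alpha))
}

#' Estimate per-probe variance components from a ratio/intensity fit pair
#'
#' The within-array residual sd (sigmaE) is taken from the ratio-model
#' residual variance; the array-effect sd (sigmaA) from the difference of
#' the intensity- and ratio-model residual variances, floored at zero.
#'
#' @param rtRatio,rtIntensity result tables from [fitDataset()] over the
#'   same data under the ratio and intensity specifications.
#' @return `data.frame` with `probe_id`, `sigmaE`, `sigmaA`.
#' @export
estimateVarianceComponents <- function(rtRatio, rtIntensity) {
    if (!identical(rtRatio$probe_id, rtIntensity$probe_id))
        stop("result tables must cover identical probes in identical order")
    data.frame(probe_id = rtRatio$probe_id,
               sigmaE = sqrt(rtRatio$sigma2),
               sigmaA = sqrt(pmax(0, rtIntensity$sigma2 - rtRatio$sigma2)),
               stringsAsFactors = FALSE)
}
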