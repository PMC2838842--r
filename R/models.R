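## Genewise ANOVA of single-channel log2 intensities:
##   y = mu + tau_treatment (+ eta_unit) (+ alpha_array) + eps
## With the per-gene array effect alpha the analysis is ratio-based
## (equivalent to modeling within-array log-ratios); without it the
## channels are treated as exchangeable observations (intensity-based).

## Build the full-column matrix before rank reduction.  Treatment and unit
## use reference-level (treatment-contrast) coding; array uses one
## indicator per array so that redundant arrays are dropped (and reported)
## by the rank reduction rather than silently absorbed.
.buildColumns <- function(tab, spec, withTreatment = TRUE) {
    n <- nrow(tab)
    cols <- list(`(Intercept)` = rep(1, n))
    term <- "intercept"
    trLev <- sort(unique(tab[[spec@treatment]]))
    if (withTreatment) {
        if (length(trLev) < 2L)
            stop("treatment factor must have at least two levels")
        for (l in trLev[-1L]) {
            cols[[paste0("treatment", l)]] <- as.numeric(
                tab[[spec@treatment]] == l)
            term <- c(term, "treatment")
        }
    }
    if (!is.na(spec@unit)) {
        uLev <- sort(unique(tab[[spec@unit]]))
        for (l in uLev[-1L]) {
            cols[[paste0("unit", l)]] <- as.numeric(tab[[spec@unit]] == l)
            term <- c(term, "unit")
        }
    }
    if (spec@includeArray) {
        aLev <- unique(tab$array_id)
        for (l in aLev) {
            cols[[paste0("array", l)]] <- as.numeric(tab$array_id == l)
            term <- c(term, "array")
        }
    }
    X <- do.call(cbind, cols)
    rownames(X) <- rownames(tab)
    list(X = X, term = term, treatmentLevels = trLev)
}

## Sequential rank reduction: columns are admitted in order (intercept,
## treatment, unit, array), so a column fully confounded with earlier
## terms is dropped.  Returns retained indices and dropped labels.
.reduceRank <- function(X) {
    keep <- integer(0)
    for (j in seq_len(ncol(X))) {
        cand <- X[, c(keep, j), drop = FALSE]
        if (qr(cand)$rank == length(keep) + 1L)
            keep <- c(keep, j)
    }
    keep
}

#' Build a reduced-rank design matrix for the genewise model
#'
#' Columns are intercept, treatment contrasts (reference-level coding),
#' optional unit contrasts and optional per-array indicators; no dye term
#' is ever included.  Aliased (fully confounded) columns are dropped by a
#' sequential rank reduction that admits columns in that order -- so
#' nuisance array columns, not treatment contrasts, absorb any partial
#' confounding -- and are reported in the `aliased` slot, never silently.
#'
#' @param design a [HybridizationDesign-class] (rows define channel order).
#' @param spec a [ModelSpec-class].
#' @return a [DesignMatrixBundle-class].
#' @examples
#' d <- makeDesign("two-group-paired", nGroups = 2, technicalReplicates = 10)
#' buildDesignMatrix(d, modelSpec(includeArray = TRUE))@rank   # 11
#' buildDesignMatrix(d, modelSpec(includeArray = FALSE))@rank  # 2
#' @export
buildDesignMatrix <- function(design, spec) {
    tab <- designTable(design)
    bad <- is.na(tab[[spec@treatment]])
    if (!is.na(spec@unit)) bad <- bad | is.na(tab[[spec@unit]])
    if (any(bad))
        stop("channels with undefined factor levels: ",
             paste(rownames(tab)[bad], collapse = ", "))
    built <- .buildColumns(tab, spec, withTreatment = TRUE)
    keep <- .reduceRank(built$X)
    droppedTreat <- setdiff(which(built$term == "treatment"), keep)
    if (length(droppedTreat) == sum(built$term == "treatment"))
        stop("treatment not estimable: all treatment contrasts aliased")
    if (length(droppedTreat) > 0L)
        warning("treatment contrast(s) aliased, reported in bundle: ",
                paste(colnames(built$X)[droppedTreat], collapse = ", "))
    X <- built$X[, keep, drop = FALSE]
    new("DesignMatrixBundle",
        matrix = X,
        aliased = colnames(built$X)[setdiff(seq_len(ncol(built$X)), keep)],
        rank = ncol(X),
        treatmentCols = which(built$term[keep] == "treatment"),
        treatmentLevels = built$treatmentLevels,
        arrayCols = which(built$term[keep] == "array"),
        channels = rownames(tab))
}

## Reduced model for the treatment F-test: same columns minus treatment.
.buildReduced <- function(design, spec) {
    tab <- designTable(design)
    built <- .buildColumns(tab, spec, withTreatment = FALSE)
    keep <- .reduceRank(built$X)
    built$X[, keep, drop = FALSE]
}

.gaussLogLik <- function(rss, n) {
    ## profile ML log-likelihood at sigma-hat^2 = RSS/n
    ifelse(rss <= 0, Inf, -n / 2 * (log(2 * pi) + log(rss / n) + 1))
}

.mValueNames <- function(lev) {
    if (length(lev) < 2L) return(character(0))
    pr <- utils::combn(length(lev), 2L)
    paste0("M.", lev[pr[2L, ]], "-", lev[pr[1L, ]])
}

## Levels whose treatment contrast was dropped as aliased (inestimable).
.droppedTreatmentLevels <- function(bundle)
    sub("^treatment", "", grep("^treatment", bundle@aliased, value = TRUE))

## tauMat: levels x probes matrix of treatment coefficients (reference 0).
.mValuesFromTau <- function(tauMat, lev) {
    pr <- utils::combn(length(lev), 2L)
    out <- tauMat[pr[2L, ], , drop = FALSE] - tauMat[pr[1L, ], , drop = FALSE]
    rownames(out) <- .mValueNames(lev)
    out
}

#' Fit the genewise linear model for one probe
#'
#' Ordinary least squares of a probe's channel vector on a reduced-rank
#' design matrix.  The log-likelihood is the Gaussian profile likelihood at
#' the ML variance estimate RSS/n, and BIC = -2 logLik + p log(n) with
#' p = rank + 1 (residual variance counts as a parameter).  With zero
#' residual degrees of freedom the fit is returned with `dfResidual = 0`
#' and no exception; downstream tests report `NA` p-values for it.
#'
#' @param y numeric vector of the probe's log2 intensities, in the channel
#'   order of `bundle`.
#' @param bundle a [DesignMatrixBundle-class].
#' @return a [GeneFit-class].
#' @export
fitGene <- function(y, bundle) {
    X <- bundle@matrix
    if (length(y) != nrow(X))
        stop("length(y) must equal the number of channels in the bundle")
    qx <- qr(X)
    coef <- qr.coef(qx, y)
    fitted <- drop(X %*% coef)
    rss <- sum((y - fitted)^2)
    tol <- 1e-12 * max(1, sum(y^2))
    exact <- rss <= tol
    if (exact) rss <- 0
    n <- length(y)
    lev <- bundle@treatmentLevels
    tau <- matrix(0, length(lev), 1L, dimnames = list(lev, NULL))
    if (length(bundle@treatmentCols))
        tau[match(sub("^treatment", "",
                      colnames(X)[bundle@treatmentCols]), lev), 1L] <-
            coef[bundle@treatmentCols]
    tau[.droppedTreatmentLevels(bundle), 1L] <- NA_real_
    mv <- drop(.mValuesFromTau(tau, lev))
    names(mv) <- .mValueNames(lev)
    new("GeneFit", coefficients = coef, fitted = fitted, rss = rss,
        dfResidual = as.integer(n - bundle@rank), n = as.integer(n),
        logLik = .gaussLogLik(rss, n),
        bic = -2 * .gaussLogLik(rss, n) + (bundle@rank + 1) * log(n),
        fStat = NA_real_, pValue = NA_real_, mValues = mv,
        exactFit = exact)
}

#' Treatment F-test from nested genewise fits
#'
#' F = ((RSS_reduced - RSS_full)/q) / (RSS_full/df_full) with
#' q = df_reduced - df_full; the p-value is the upper tail of the central
#' F distribution.  An exact full fit (RSS = 0) yields p = 0 with the
#' `exactFit` flag; zero residual df in the full model yields `NA`.
#'
#' @param fitFull,fitReduced [GeneFit-class] objects for the same response,
#'   the reduced fit lacking all treatment columns.
#' @return list with elements `F`, `p`, `df1`, `df2`, `exactFit`.
#' @export
fTestTreatment <- function(fitFull, fitReduced) {
    if (fitFull@n != fitReduced@n)
        stop("fits are not on the same response (n differs)")
    q <- fitReduced@dfResidual - fitFull@dfResidual
    if (q < 1L)
        stop("reduced fit must have larger residual df than the full fit")
    if (fitFull@dfResidual == 0L)
        return(list(F = NA_real_, p = NA_real_, df1 = q, df2 = 0L,
                    exactFit = fitFull@exactFit))
    if (fitFull@exactFit) {
        ## reduced model also exact (e.g. constant y): no treatment signal
        if (fitReduced@exactFit)
            return(list(F = 0, p = 1, df1 = q, df2 = fitFull@dfResidual,
                        exactFit = TRUE))
        return(list(F = Inf, p = 0, df1 = q, df2 = fitFull@dfResidual,
                    exactFit = TRUE))
    }
    Fstat <- max(0, fitReduced@rss - fitFull@rss) / q /
        (fitFull@rss / fitFull@dfResidual)
    list(F = Fstat,
         p = stats::pf(Fstat, q, fitFull@dfResidual, lower.tail = FALSE),
         df1 = q, df2 = fitFull@dfResidual, exactFit = FALSE)
}

#' BIC model selection between the ratio and intensity fits of one probe
#'
#' The preferred model is the one with the lower BIC; ties go to the
#' intensity model (fewer parameters).
#'
#' @param fitRatio,fitIntensity [GeneFit-class] objects for the same
#'   response under the model with and without the array effect.
#' @return `"ratio"` or `"intensity"`.
#' @export
bicCompare <- function(fitRatio, fitIntensity) {
    if (fitRatio@n != fitIntensity@n)
        stop("fits are not on the same response (n differs)")
    if (fitRatio@bic < fitIntensity@bic) "ratio" else "intensity"
}

#' Fit the genewise model to every probe of a dataset
#'
#' Fits, per probe, the least-squares model given by `spec` and the
#' corresponding reduced model without treatment terms, and computes the
#' treatment F-test, BIC, residual variance and all pairwise treatment
#' effect sizes (M-values).  The design matrix is probe-independent, so it
#' is built once and applied to all probes in a single batched solve.
#'
#' @param cs a log2-scale [ChannelSet-class]; its channels must be a
#'   subset of the design's channels.
#' @param design a [HybridizationDesign-class].
#' @param spec a [ModelSpec-class].
#' @return a `data.frame` ("result table") with one row per probe and
#'   columns `probe_id`, `model` (`"ratio"`/`"intensity"`), `F`, `p`,
#'   `neg_log10_p`, `bic`, `df_resid`, `sigma2`, then one `M.<a>-<b>`
#'   column per treatment pair.  Attributes: `coefficients` (probes x
#'   parameters matrix) and `bundle` (the [DesignMatrixBundle-class]).
#' @export
fitDataset <- function(cs, design, spec) {
    if (!isTRUE(metadata(cs)$logScale))
        stop("fitDataset expects log2-scale data; run quantileNormalize()")
    chans <- colnames(cs)
    missing <- setdiff(chans, channelIds(design))
    if (length(missing))
        stop("channels absent from design: ", paste(missing, collapse = ", "))
    dsub <- subsetDesign(design, chans)
    bundle <- buildDesignMatrix(dsub, spec)
    Xr <- .buildReduced(dsub, spec)
    X <- bundle@matrix
    n <- nrow(X)
    tY <- t(assay(cs, "exprs"))          # channels x probes
    qf <- qr(X)
    coef <- qr.coef(qf, tY)              # rank x probes
    rssF <- colSums(qr.resid(qf, tY)^2)
    rssR <- colSums(qr.resid(qr(Xr), tY)^2)
    dfF <- n - bundle@rank
    dfR <- n - ncol(Xr)
    q <- dfR - dfF
    if (q < 1L)
        stop("treatment adds no parameters; cannot test")
    tolv <- 1e-12 * pmax(1, colSums(tY^2))
    exact <- rssF <= tolv
    exactR <- rssR <= tolv
    rssF[exact] <- 0
    if (dfF >= 1L) {
        Fstat <- pmax(0, rssR - rssF) / q / (rssF / dfF)
        p <- stats::pf(Fstat, q, dfF, lower.tail = FALSE)
        Fstat[exact & !exactR] <- Inf
        p[exact & !exactR] <- 0
        Fstat[exact & exactR] <- 0    # constant probe: no treatment signal
        p[exact & exactR] <- 1
    } else {
        Fstat <- rep(NA_real_, length(rssF))
        p <- rep(NA_real_, length(rssF))
    }
    ll <- .gaussLogLik(rssF, n)
    bic <- -2 * ll + (bundle@rank + 1) * log(n)
    lev <- bundle@treatmentLevels
    tau <- matrix(0, length(lev), ncol(tY), dimnames = list(lev, NULL))
    if (length(bundle@treatmentCols))
        tau[match(sub("^treatment", "",
                      colnames(X)[bundle@treatmentCols]), lev), ] <-
            coef[bundle@treatmentCols, , drop = FALSE]
    tau[.droppedTreatmentLevels(bundle), ] <- NA_real_
    M <- .mValuesFromTau(tau, lev)
    rt <- data.frame(probe_id = rownames(cs),
                     model = if (spec@includeArray) "ratio" else "intensity",
                     F = Fstat, p = p, neg_log10_p = -log10(p),
                     bic = bic, df_resid = dfF,
                     sigma2 = if (dfF >= 1L) rssF / dfF else NA_real_,
                     stringsAsFactors = FALSE)
    for (i in seq_len(nrow(M))) rt[[rownames(M)[i]]] <- M[i, ]
    rownames(rt) <- rt$probe_id
    attr(rt, "coefficients") <- t(coef)
    attr(rt, "bundle") <- bundle
    rt
}

## Stable probe ordering by p-value; ties broken by probe_id.
.rankOrder <- function(rt) order(rt$p, rt$probe_id)

#' Per-probe BIC model selection over a dataset
#'
#' @param rtRatio,rtIntensity result tables from [fitDataset()] under the
#'   ratio and intensity specifications (same probes, same channels).
#' @return a `data.frame` with `probe_id`, `bic_ratio`, `bic_intensity`,
#'   `preferred`; the attribute `"fractionIntensity"` gives the proportion
#'   of probes for which the intensity model wins (ties included).
#' @export
bicSelection <- function(rtRatio, rtIntensity) {
    if (!identical(rtRatio$probe_id, rtIntensity$probe_id))
        stop("result tables must cover identical probes in identical order")
    pref <- ifelse(rtRatio$bic < rtIntensity$bic, "ratio", "intensity")
    out <- data.frame(probe_id = rtRatio$probe_id,
                      bic_ratio = rtRatio$bic,
                      bic_intensity = rtIntensity$bic,
                      preferred = pref, stringsAsFactors = FALSE)
    attr(out, "fractionIntensity") <- mean(pref == "intensity")
    out
}

#' Read / write result tables
#'
#' Tab-delimited with the column layout of [fitDataset()] output.
#'
#' @param rt a result table.
#' @param path file path.
#' @export
writeResultTable <- function(rt, path) {
    num <- vapply(rt, is.numeric, logical(1L))
    out <- rt
    for (j in which(num)) out[[j]] <- formatC(rt[[j]], digits = 17,
                                              format = "g")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
    rt <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    rownames(rt) <- rt$probe_id
    rt
}
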