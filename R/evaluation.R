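## Reproducibility and comparison metrics for pairs of genewise result
## tables (technical-replicate halves, or ratio vs intensity analyses of
## the same half).  Gene rankings order by p-value; ties are broken by
## probe_id so every ranking is deterministic.

.alignTables <- function(r1, r2, minProbes = 3L) {
    if (!setequal(r1$probe_id, r2$probe_id))
        stop("result tables must cover identical probe sets")
    if (nrow(r1) < minProbes)
        stop("need at least ", minProbes, " probes")
    r2 <- r2[match(r1$probe_id, r2$probe_id), , drop = FALSE]
    list(r1 = r1, r2 = r2)
}

#' Rank correlation of p-values between two analyses
#'
#' Spearman's rho of the per-probe p-values (the default, rank-equivalent
#' whether applied to p or -log10 p); `"pearson-log10"` instead correlates
#' the -log10 p-values linearly.
#'
#' @param r1,r2 result tables from [fitDataset()] over identical probes.
#' @param method `"spearman"` or `"pearson-log10"`.
#' @return the correlation coefficient.
#' @export
pvalueReproducibility <- function(r1, r2,
                                  method = c("spearman", "pearson-log10")) {
    method <- match.arg(method)
    al <- .alignTables(r1, r2)
    if (method == "spearman")
        stats::cor(al$r1$p, al$r2$p, method = "spearman")
    else
        stats::cor(-log10(al$r1$p), -log10(al$r2$p))
}

#' Overlap of equal-rank p-value bins between two analyses
#'
#' Genes are ordered by p-value in each table and assigned to consecutive
#' bins of `binSize` genes; the overlap fraction of bin b is the number of
#' genes placed in bin b by both analyses divided by the bin size (a
#' trailing partial bin uses its own size).
#'
#' @param r1,r2 result tables over identical probes.
#' @param binSize number of genes per bin (default 1000).
#' @return `data.frame` with columns `bin`, `size`, `overlap`.
#' @export
binOverlap <- function(r1, r2, binSize = 1000L) {
    al <- .alignTables(r1, r2)
    n <- nrow(al$r1)
    if (binSize > n) stop("binSize exceeds probe count")
    binOf <- function(rt) {
        b <- integer(n)
        b[.rankOrder(rt)] <- ceiling(seq_len(n) / binSize)
        b
    }
    b1 <- binOf(al$r1); b2 <- binOf(al$r2)
    nb <- max(b1)
    size <- tabulate(b1, nb)
    overlap <- vapply(seq_len(nb),
                      function(b) sum(b1 == b & b2 == b) / size[b],
                      numeric(1L))
    data.frame(bin = seq_len(nb), size = size, overlap = overlap)
}

#' Top-k overlap curve between two gene rankings
#'
#' For list sizes k from `kMin` to `kMax` in steps of `step`, the fraction
#' of genes occurring in the top-k lists of both analyses.
#'
#' @param r1,r2 result tables over identical probes.
#' @param kMin,kMax,step list-size grid (defaults 10 to 1000 by 10).
#' @return `data.frame` with columns `k` and `overlap` (fractions in
#'   `[0, 1]`).
#' @export
topkOverlapCurve <- function(r1, r2, kMin = 10L, kMax = 1000L, step = 10L) {
    al <- .alignTables(r1, r2)
    n <- nrow(al$r1)
    if (kMax > n) stop("kMax exceeds probe count")
    ord1 <- .rankOrder(al$r1)
    pos2 <- integer(n)
    pos2[.rankOrder(al$r2)] <- seq_len(n)
    posOfOrd1 <- pos2[ord1]       # rank in r2 of the i-th ranked gene of r1
    ks <- seq.int(kMin, kMax, by = step)
    overlap <- vapply(ks, function(k) sum(posOfOrd1[seq_len(k)] <= k) / k,
                      numeric(1L))
    data.frame(k = ks, overlap = overlap)
}

#' Recall of ratio-selected genes at the ratio p-value cutoff
#'
#' Uses the p-value of the k-th most significant gene of the ratio
#' analysis as a significance cutoff for the intensity analysis: recall is
#' the fraction of the ratio top-k also reaching that cutoff under the
#' intensity model, and `extra` counts genes outside the ratio top-k whose
#' intensity p-value is strictly below the cutoff (the additional genes
#' the more sensitive analysis picks up).
#'
#' @param rRatio,rIntensity result tables over identical probes.
#' @param k size of the ratio-selected list (default 1000).
#' @return list with `recall`, `extra`, `cutoff`.
#' @export
recallAtRatioCutoff <- function(rRatio, rIntensity, k = 1000L) {
    al <- .alignTables(rRatio, rIntensity)
    n <- nrow(al$r1)
    if (k > n) stop("k exceeds probe count")
    ord <- .rankOrder(al$r1)
    top <- ord[seq_len(k)]
    cutoff <- al$r1$p[ord[k]]
    recall <- mean(al$r2$p[top] <= cutoff)
    extra <- sum(al$r2$p[-top] < cutoff)
    list(recall = recall, extra = extra, cutoff = cutoff)
}

#' Compare directly measured and in-silico reconstructed log-ratios
#'
#' For each requested sample pair, the direct M-values (log2 differences
#' of the two channels co-hybridized on one array) are correlated with
#' reconstructed M-values formed from two intensity measurements of the
#' same sample pair taken on other arrays.  The design is used to orient
#' the direct array's channels to the samples of the named off-array
#' channels.  Apply the A > 7 filter before calling.
#'
#' @param cs a log2-scale [ChannelSet-class].
#' @param design a [HybridizationDesign-class].
#' @param pairings `data.frame` with columns `channelA`, `channelB`
#'   (off-array channel identifiers measuring samples A and B) and
#'   `directArray` (an array co-hybridizing the same two samples).
#' @return list with `perPairing` (a `data.frame` of Pearson correlations)
#'   and `meanR`; the attribute `"M"` holds per-pairing direct and
#'   reconstructed M-value vectors.
#' @export
reconstructRatios <- function(cs, design, pairings) {
    if (!isTRUE(metadata(cs)$logScale))
        stop("reconstructRatios expects log2-scale data")
    vals <- assay(cs, "exprs")
    tab <- designTable(design)
    rs <- numeric(nrow(pairings))
    Ms <- vector("list", nrow(pairings))
    for (i in seq_len(nrow(pairings))) {
        chA <- as.character(pairings$channelA[i])
        chB <- as.character(pairings$channelB[i])
        da <- as.character(pairings$directArray[i])
        for (ch in c(chA, chB))
            if (!ch %in% colnames(vals))
                stop("channel not in matrix: ", ch)
        dch <- rownames(tab)[tab$array_id == da]
        if (length(dch) != 2L)
            stop("direct array ", da, " does not have two channels")
        sA <- tab[chA, "sample_id"]; sB <- tab[chB, "sample_id"]
        dA <- dch[tab[dch, "sample_id"] == sA]
        dB <- dch[tab[dch, "sample_id"] == sB]
        if (length(dA) != 1L || length(dB) != 1L)
            stop("direct array ", da, " does not co-hybridize samples ",
                 sA, " and ", sB)
        direct <- vals[, dA] - vals[, dB]
        recon <- vals[, chA] - vals[, chB]
        rs[i] <- stats::cor(direct, recon)
        Ms[[i]] <- data.frame(direct = direct, reconstructed = recon)
    }
    out <- list(perPairing = data.frame(channelA = pairings$channelA,
                                        channelB = pairings$channelB,
                                        directArray = pairings$directArray,
                                        r = rs),
                meanR = mean(rs))
    attr(out, "M") <- Ms
    out
}

#' Per-probe treatment versus array effect sizes
#'
#' From a ratio-model result table, computes for each probe the mean
#' absolute treatment effect (|M| averaged over all unordered treatment
#' pairs) and the mean absolute estimated array coefficient (reference
#' coding), plus smoothed histograms of both (Gaussian kernel density,
#' Silverman's rule-of-thumb bandwidth by default).
#'
#' @param rt a result table from [fitDataset()] with a ratio-model
#'   specification (array coefficients retained in its attributes).
#' @param bw kernel bandwidth; default `"nrd0"` (Silverman).
#' @return list with `sizes` (`data.frame`: `probe_id`, `treatment`,
#'   `array`), `treatmentDensity` and `arrayDensity`.
#' @export
effectSizeComparison <- function(rt, bw = "nrd0") {
    bundle <- attr(rt, "bundle")
    coefs <- attr(rt, "coefficients")
    if (is.null(bundle) || is.null(coefs))
        stop("result table lacks fit attributes; use fitDataset() output")
    if (length(bundle@arrayCols) == 0L)
        stop("no estimable array coefficients (was this an intensity fit?)")
    mcols <- grep("^M\\.", colnames(rt), value = TRUE)
    trSize <- rowMeans(abs(rt[, mcols, drop = FALSE]))
    arSize <- rowMeans(abs(coefs[, bundle@arrayCols, drop = FALSE]))
    dens <- function(x)
        if (length(x) >= 2L) stats::density(x, bw = bw) else NULL
    list(sizes = data.frame(probe_id = rt$probe_id, treatment = trSize,
                            array = arSize, stringsAsFactors = FALSE),
         treatmentDensity = dens(trSize),
         arrayDensity = dens(arSize))
}

#' Hierarchical clustering of single channels
#'
#' Complete-linkage agglomerative clustering of the channels, by default
#' on the distance 1 - Pearson correlation of the channel value vectors
#' (scale-free, the standard expression QC choice); Euclidean distance is
#' available as an option.  On a well-behaved dataset the two channels
#' measuring the same sample (or sample-treatment combination) merge as
#' siblings regardless of which array carried them.
#'
#' @param cs a log2-scale [ChannelSet-class] with at least 3 channels.
#' @param method `"correlation"` or `"euclidean"`.
#' @return an [stats::hclust] object over channels.
#' @export
setGeneric("clusterChannels",
           function(cs, method = c("correlation", "euclidean"))
               standardGeneric("clusterChannels"))

#' @rdname clusterChannels
#' @export
setMethod("clusterChannels", "ChannelSet",
function(cs, method = c("correlation", "euclidean")) {
    method <- match.arg(method)
    vals <- assay(cs, "exprs")
    if (ncol(vals) < 3L) stop("need at least 3 channels to cluster")
    if (method == "correlation") {
        sds <- apply(vals, 2L, stats::sd)
        if (any(sds == 0))
            stop("constant channel vector(s), correlation undefined: ",
                 paste(colnames(vals)[sds == 0], collapse = ", "))
        d <- stats::as.dist(1 - stats::cor(vals))
    } else {
        d <- stats::dist(t(vals))
    }
    stats::hclust(d, method = "complete")
})

#' Write a dendrogram in Newick format
#'
#' Merge heights become branch lengths.
#'
#' @param hc an [stats::hclust] object, e.g. from [clusterChannels()].
#' @param path output file path.
#' @export
writeDendrogram <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Reproducibility of treatment effect sizes between replicate halves
#'
#' Pearson correlation of the per-probe M-values for one treatment pair
#' (e.g. group 0 versus group 6) estimated independently in the two
#' technical-replicate result tables.
#'
#' @param r1,r2 result tables over identical probes.
#' @param groupA,groupB treatment level names of the contrast.
#' @return Pearson correlation of the two M-value vectors.
#' @export
mValueReproducibility <- function(r1, r2, groupA, groupB) {
    al <- .alignTables(r1, r2)
    getM <- function(rt) {
        fwd <- paste0("M.", groupA, "-", groupB)
        rev <- paste0("M.", groupB, "-", groupA)
        if (fwd %in% colnames(rt)) rt[[fwd]]
        else if (rev %in% colnames(rt)) -rt[[rev]]
        else stop("contrast ", groupA, " vs ", groupB,
                  " not present in result table")
    }
    m1 <- getM(al$r1); m2 <- getM(al$r2)
    if (anyNA(m1) || anyNA(m2))
        stop("contrast ", groupA, " vs ", groupB, " not estimable")
    stats::cor(m1, m2)
}
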