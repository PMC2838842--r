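#' Read two-channel intensity data
#'
#' Two dialects are supported:
#'
#' * `"wide-tsv"`: a single tab-delimited file whose first column holds
#'   probe identifiers and whose remaining columns are named
#'   `"<array_id>:<dye>"` (dye case-insensitive).  Lines starting with `#`
#'   are ignored.
#' * `"agilent-fe"`: one Feature-Extraction-style tab-delimited file per
#'   array, reduced to a probe-identifier column plus a green and a red
#'   signal column (default `gMedianSignal` / `rMedianSignal`).
#'
#' Probes are aligned by identifier across arrays; probes absent from any
#' array are dropped with a warning reporting the count.  No background
#' correction is applied at any point.
#'
#' @param x for `"wide-tsv"`, a file path or data.frame; for
#'   `"agilent-fe"`, a character vector of per-array file paths.
#' @param dialect input format, see above.
#' @param probeCol,greenCol,redCol column names for the `"agilent-fe"`
#'   dialect.
#' @param arrayIds array identifiers for `"agilent-fe"`; defaults to file
#'   base names without extension.
#' @return a raw-scale [ChannelSet-class] (2 channels per array).
#' @export
readChannels <- function(x, dialect = c("wide-tsv", "agilent-fe"),
                         probeCol = "ProbeName", greenCol = "gMedianSignal",
                         redCol = "rMedianSignal", arrayIds = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "wide-tsv") {
        tab <- if (is.character(x))
            utils::read.delim(x, comment.char = "#", check.names = FALSE,
                              stringsAsFactors = FALSE)
        else as.data.frame(x, check.names = FALSE)
        if (ncol(tab) < 3L)
            stop("wide-tsv input needs a probe column plus >= 2 channels")
        probes <- as.character(tab[[1L]])
        vals <- as.matrix(tab[, -1L, drop = FALSE])
        if (!is.numeric(vals))
            stop("non-numeric signal values in wide-tsv input")
        parts <- strsplit(colnames(vals), ":", fixed = TRUE)
        if (any(lengths(parts) != 2L))
            stop("wide-tsv channel columns must be named '<array>:<dye>'")
        arr <- vapply(parts, `[`, "", 1L)
        dye <- normalizeDye(vapply(parts, `[`, "", 2L))
        if (!all(dye %in% .DYES))
            stop("unrecognized dye in column names: ",
                 paste(unique(dye[!dye %in% .DYES]), collapse = ", "))
        return(ChannelSet(vals, arrayIds = arr, dyes = dye,
                          probeIds = probes, logScale = FALSE,
                          provenance = "read: wide-tsv"))
    }
    ## agilent-fe: one file per array
    paths <- as.character(x)
    if (is.null(arrayIds))
        arrayIds <- sub("\\.[^.]*$", "", basename(paths))
    stopifnot(length(arrayIds) == length(paths))
    per <- lapply(paths, function(p) {
        tab <- utils::read.delim(p, comment.char = "#", check.names = FALSE,
                                 stringsAsFactors = FALSE)
        for (cc in c(probeCol, greenCol, redCol))
            if (!cc %in% colnames(tab))
                stop("column '", cc, "' not found in ", p)
        if (anyDuplicated(tab[[probeCol]]))
            stop("duplicated probe identifiers in ", p)
        if (!is.numeric(tab[[greenCol]]) || !is.numeric(tab[[redCol]]))
            stop("non-numeric signal values in ", p)
        tab[, c(probeCol, greenCol, redCol)]
    })
    common <- Reduce(intersect, lapply(per, function(t) t[[probeCol]]))
    if (length(common) == 0L)
        stop("no probes in common across input files")
    nAll <- length(unique(unlist(lapply(per, function(t) t[[probeCol]]))))
    dropped <- nAll - length(common)
    if (dropped > 0L)
        warning(dropped, " probe(s) dropped (absent from at least one array)")
    ## keep the probe order of the first file, restricted to common probes
    common <- per[[1L]][[probeCol]][per[[1L]][[probeCol]] %in% common]
    vals <- matrix(NA_real_, length(common), 2L * length(paths))
    arr <- rep(arrayIds, each = 2L)
    dye <- rep(c("Cy3", "Cy5"), length(paths))
    for (i in seq_along(per)) {
        idx <- match(common, per[[i]][[probeCol]])
        vals[, 2L * i - 1L] <- per[[i]][[greenCol]][idx]
        vals[, 2L * i]      <- per[[i]][[redCol]][idx]
    }
    ChannelSet(vals, arrayIds = arr, dyes = dye, probeIds = common,
               logScale = FALSE, provenance = "read: agilent-fe")
}

#' Quantile-normalize pooled channels and log2-transform
#'
#' All single channels (2 per array) are pooled into one quantile
#' normalization: each channel's sorted values are replaced by the
#' rank-wise mean across channels, tied values receiving the mean of the
#' reference values at their tied ranks.  This makes the channels
#' exchangeable, which the intensity-based analysis requires.  The log2
#' transform is applied after normalization.  Zero or negative intensities
#' are rejected (no background correction or pseudocount is ever applied,
#' so they indicate an upstream problem).
#'
#' @param cs a raw-scale [ChannelSet-class] with strictly positive values.
#' @return a log2-scale [ChannelSet-class]; every channel has an identical
#'   sorted value distribution.
#' @export
setGeneric("quantileNormalize",
           function(cs) standardGeneric("quantileNormalize"))

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ChannelSet", function(cs) {
    if (isTRUE(metadata(cs)$logScale))
        stop("input is already log2-scale; quantile normalization expects ",
             "raw intensities")
    vals <- assay(cs, "exprs")
    bad <- vapply(seq_len(ncol(vals)),
                  function(j) any(vals[, j] <= 0 | !is.finite(vals[, j])),
                  logical(1L))
    if (any(bad))
        stop("nonpositive or non-finite intensities in channel(s): ",
             paste(colnames(vals)[bad], collapse = ", "))
    norm <- limma::normalizeQuantiles(vals, ties = TRUE)
    out <- log2(norm)
    dimnames(out) <- dimnames(vals)
    res <- ChannelSet(out, arrayIds = colData(cs)$array_id,
                      dyes = colData(cs)$dye, probeIds = rownames(vals),
                      logScale = TRUE,
                      provenance = c(metadata(cs)$provenance,
                                     "quantile-normalized (pooled channels), log2"))
    res
})

#' Mean log2 intensity (A-value) per probe
#'
#' @param cs a log2-scale [ChannelSet-class].
#' @return numeric vector of row means of the log2 values (recomputed from
#'   the current matrix, never cached).
#' @export
setGeneric("aValues", function(cs) standardGeneric("aValues"))

#' @rdname aValues
#' @export
setMethod("aValues", "ChannelSet", function(cs) {
    if (!isTRUE(metadata(cs)$logScale))
        stop("A-values are defined on log2-scale data; normalize first")
    rowMeans(assay(cs, "exprs"))
})

#' Filter probes by mean log2 intensity
#'
#' Retains exactly the probes whose mean log2 intensity over all channels
#' exceeds the threshold (strict inequality).  Removal is global: a probe
#' failing the filter is removed from every channel, so per-probe sample
#' sizes stay equal across the dataset.
#'
#' @param cs a log2-scale [ChannelSet-class].
#' @param threshold log2-units cutoff (default 7); `-Inf` keeps everything.
#' @return the filtered [ChannelSet-class].
#' @export
setGeneric("filterByIntensity",
           function(cs, threshold = 7) standardGeneric("filterByIntensity"))

#' @rdname filterByIntensity
#' @export
setMethod("filterByIntensity", "ChannelSet", function(cs, threshold = 7) {
    if (length(threshold) != 1L || is.na(threshold) || is.nan(threshold))
        stop("threshold must be a single non-missing number")
    keep <- aValues(cs) > threshold
    out <- cs[keep, ]
    metadata(out)$provenance <- c(metadata(out)$provenance,
                                  paste0("filtered A > ", threshold, ": ",
                                         sum(keep), "/", length(keep),
                                         " probes kept"))
    out
})

#' Write a channel matrix as wide TSV
#'
#' First column `probe_id`, remaining columns `"<array>:<dye>"`; a leading
#' `#` comment line records processing provenance.  Values are written
#' with 17 significant digits so that [readChannels()] round-trips them
#' exactly.
#'
#' @param cs a [ChannelSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeChannels <- function(cs, path) {
    vals <- assay(cs, "exprs")
    con <- file(path, "w")
    on.exit(close(con))
    prov <- paste(c(if (isTRUE(metadata(cs)$logScale)) "log2" else "raw",
                    metadata(cs)$provenance), collapse = "; ")
    writeLines(paste0("# ", prov), con)
    writeLines(paste(c("probe_id", colnames(vals)), collapse = "\t"), con)
    body <- cbind(rownames(vals),
                  matrix(formatC(vals, digits = 17, format = "g"),
                         nrow(vals), ncol(vals)))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
    invisible(path)
}
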