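#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.DYES <- c("Cy3", "Cy5")

#' Container for single-channel log2 (or raw) intensities
#'
#' A `ChannelSet` holds a probes x channels matrix of two-color microarray
#' intensities, one column per (array, dye) channel.  It extends
#' [SummarizedExperiment::SummarizedExperiment] with the convention that
#' `colData` carries at least `array_id` and `dye`, and column names are
#' `"<array_id>:<dye>"`.  `metadata()$logScale` records whether values are
#' log2-transformed; `metadata()$provenance` records processing history.
#'
#' @export
setClass("ChannelSet", contains = "SummarizedExperiment")

setValidity("ChannelSet", function(object) {
    msg <- character(0)
    cd <- colData(object)
    if (!all(c("array_id", "dye") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'array_id' and 'dye'")
    else {
        if (!all(cd$dye %in% .DYES))
            msg <- c(msg, "dye must be 'Cy3' or 'Cy5'")
        key <- paste(cd$array_id, cd$dye, sep = ":")
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (array_id, dye) channel")
        if (!identical(colnames(object), key))
            msg <- c(msg, "column names must be '<array_id>:<dye>'")
    }
    if (length(SummarizedExperiment::assayNames(object)) < 1L ||
        SummarizedExperiment::assayNames(object)[1L] != "exprs")
        msg <- c(msg, "first assay must be named 'exprs'")
    if (length(msg)) msg else TRUE
})

#' Construct a ChannelSet
#'
#' @param values numeric matrix, probes in rows and channels in columns.
#' @param arrayIds character vector, one array identifier per channel.
#' @param dyes character vector of `"Cy3"`/`"Cy5"`, one per channel.
#' @param probeIds probe identifiers; defaults to `rownames(values)`.
#' @param logScale logical; are the values log2-transformed?
#' @param provenance character vector of processing notes.
#' @return A [ChannelSet-class] object.
#' @examples
#' m <- matrix(rnorm(12, 10), 3, 4)
#' cs <- ChannelSet(m, arrayIds = rep(c("A1", "A2"), each = 2),
#'                  dyes = rep(c("Cy3", "Cy5"), 2),
#'                  probeIds = paste0("p", 1:3), logScale = TRUE)
#' @export
ChannelSet <- function(values, arrayIds, dyes, probeIds = rownames(values),
                       logScale = FALSE, provenance = character(0)) {
    values <- as.matrix(values)
    if (is.null(probeIds))
        probeIds <- paste0("probe", seq_len(nrow(values)))
    dyes <- normalizeDye(dyes)
    stopifnot(length(arrayIds) == ncol(values), length(dyes) == ncol(values))
    rownames(values) <- as.character(probeIds)
    colnames(values) <- paste(arrayIds, dyes, sep = ":")
    se <- SummarizedExperiment(
        assays = list(exprs = values),
        colData = DataFrame(array_id = as.character(arrayIds), dye = dyes,
                            row.names = colnames(values)))
    obj <- new("ChannelSet", se)
    metadata(obj)$logScale <- isTRUE(logScale)
    metadata(obj)$provenance <- provenance
    obj
}

setMethod("show", "ChannelSet", function(object) {
    cat("ChannelSet:", nrow(object), "probes x", ncol(object), "channels (",
        length(unique(colData(object)$array_id)), "arrays ),",
        if (isTRUE(metadata(object)$logScale)) "log2" else "raw", "scale\n")
    if (length(metadata(object)$provenance))
        cat("provenance:", paste(metadata(object)$provenance, collapse = "; "),
            "\n")
})

#' Hybridization design of a dual-color experiment
#'
#' Maps every (array, dye) channel to the sample hybridized in it and the
#' sample's factor levels: treatment (group), unit (cell line or subject)
#' and, optionally, a technical replicate set used when splitting the data
#' into two biologically identical halves.
#'
#' @slot table a `data.frame` with columns `array_id`, `dye`, `sample_id`,
#'   `treatment`, `unit`, `replicate_set` (the last may be `NA`).
#' @export
setClass("HybridizationDesign", representation(table = "data.frame"))

.DESIGN_COLS <- c("array_id", "dye", "sample_id", "treatment", "unit",
                  "replicate_set")

setValidity("HybridizationDesign", function(object) {
    tab <- object@table
    msg <- character(0)
    if (nrow(tab) == 0L)
        msg <- c(msg, "design is empty")
    if (!all(.DESIGN_COLS %in% colnames(tab)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(.DESIGN_COLS, colnames(tab)),
                                  collapse = ", ")))
    else {
        if (!all(tab$dye %in% .DYES))
            msg <- c(msg, "dye values must be 'Cy3' or 'Cy5'")
        ## duplicate (array, dye) channels are representable so that
        ## validateDesign() can report them
    }
    if (length(msg)) msg else TRUE
})

normalizeDye <- function(x) {
    x <- as.character(x)
    low <- tolower(x)
    out <- ifelse(low %in% c("cy3", "green", "g"), "Cy3",
                  ifelse(low %in% c("cy5", "red", "r"), "Cy5", x))
    out
}

#' Construct a HybridizationDesign
#'
#' @param table a `data.frame` with columns `array_id`, `dye`, `sample_id`,
#'   `treatment`, `unit` and optionally `replicate_set`.  Dye values are
#'   matched case-insensitively.
#' @return A [HybridizationDesign-class].
#' @export
HybridizationDesign <- function(table) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (!"replicate_set" %in% colnames(table))
        table$replicate_set <- NA_integer_
    for (cc in c("array_id", "dye", "sample_id", "treatment", "unit"))
        if (cc %in% colnames(table)) table[[cc]] <- as.character(table[[cc]])
    table$dye <- normalizeDye(table$dye)
    table <- table[, intersect(.DESIGN_COLS, colnames(table)), drop = FALSE]
    rownames(table) <- make.unique(paste(table$array_id, table$dye,
                                         sep = ":"))
    new("HybridizationDesign", table = table)
}

setMethod("show", "HybridizationDesign", function(object) {
    tab <- object@table
    cat("HybridizationDesign:", nrow(tab), "channels on",
        length(unique(tab$array_id)), "arrays;",
        length(unique(tab$treatment)), "treatment level(s),",
        length(unique(tab$unit)), "unit(s)\n")
})

#' A split of a design into two technical-replicate halves
#'
#' @slot half1,half2 character vectors of channel identifiers
#'   (`"array:dye"`), disjoint and jointly exhaustive for the parent design.
#' @slot rule the splitting rule used.
#' @export
setClass("ReplicateSplit",
         representation(half1 = "character", half2 = "character",
                        rule = "character"))

setMethod("show", "ReplicateSplit", function(object) {
    cat("ReplicateSplit (rule:", object@rule, "): ",
        length(object@half1), "+", length(object@half2), "channels\n")
})

#' Specification of a genewise linear model
#'
#' The ratio-based analysis models log2 intensities with a per-gene array
#' effect (equivalent to analyzing within-array log-ratios); the
#' intensity-based analysis omits the array effect and treats channels as
#' exchangeable observations.  The two specifications differ only in
#' `includeArray`.  Dye is never modeled (designs are assumed dye-balanced
#' and dye bias removed by normalization).
#'
#' @slot treatment name of the treatment factor column in the design.
#' @slot unit name of the unit (cell line) factor, or `NA` to omit it.
#' @slot includeArray logical; include per-array effects (ratio analysis)?
#' @export
setClass("ModelSpec",
         representation(treatment = "character", unit = "character",
                        includeArray = "logical"))

#' @param treatment,unit,includeArray see slot descriptions.
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(treatment = "treatment", unit = NA_character_,
                      includeArray = TRUE) {
    if (is.null(unit)) unit <- NA_character_
    new("ModelSpec", treatment = treatment, unit = as.character(unit),
        includeArray = isTRUE(includeArray))
}

setMethod("show", "ModelSpec", function(object) {
    cat("ModelSpec:", if (object@includeArray) "ratio-based (array effect)"
        else "intensity-based (no array effect)",
        "| treatment =", object@treatment,
        if (!is.na(object@unit)) paste("| unit =", object@unit) else "", "\n")
})

#' Reduced-rank design matrix with aliasing report
#'
#' @slot matrix the channels x parameters model matrix after dropping
#'   aliased (fully confounded) columns.
#' @slot aliased labels of dropped columns.
#' @slot rank the rank (= retained column count).
#' @slot treatmentCols indices of retained treatment-contrast columns.
#' @slot treatmentLevels levels of the treatment factor (first = reference).
#' @slot arrayCols indices of retained array-effect columns.
#' @slot channels channel identifiers, in row order.
#' @export
setClass("DesignMatrixBundle",
         representation(matrix = "matrix", aliased = "character",
                        rank = "integer", treatmentCols = "integer",
                        treatmentLevels = "character", arrayCols = "integer",
                        channels = "character"))

setValidity("DesignMatrixBundle", function(object) {
    if (object@rank != ncol(object@matrix))
        "rank must equal retained column count" else TRUE
})

setMethod("show", "DesignMatrixBundle", function(object) {
    cat("DesignMatrixBundle:", nrow(object@matrix), "channels x",
        object@rank, "parameters;", length(object@aliased),
        "aliased column(s) dropped\n")
    if (length(object@aliased))
        cat("aliased:", paste(object@aliased, collapse = ", "), "\n")
})

#' Per-probe least-squares fit
#'
#' @slot coefficients named coefficient estimates on the reduced basis.
#' @slot fitted fitted values.
#' @slot rss residual sum of squares.
#' @slot dfResidual residual degrees of freedom (n - rank).
#' @slot n number of channels used.
#' @slot logLik Gaussian profile maximum log-likelihood.
#' @slot bic -2 logLik + p log(n) with p = rank + 1 (residual variance
#'   counts as a parameter).
#' @slot fStat,pValue treatment F statistic and p-value (`NA` until a
#'   treatment F-test is performed).
#' @slot mValues pairwise treatment contrasts (log2 effect sizes), named
#'   `"<a>-<b>"` for tau_a - tau_b.
#' @slot exactFit TRUE when RSS is numerically zero.
#' @export
setClass("GeneFit",
         representation(coefficients = "numeric", fitted = "numeric",
                        rss = "numeric", dfResidual = "integer",
                        n = "integer", logLik = "numeric", bic = "numeric",
                        fStat = "numeric", pValue = "numeric",
                        mValues = "numeric", exactFit = "logical"))

setMethod("show", "GeneFit", function(object) {
    cat("GeneFit: n =", object@n, ", rank =", object@n - object@dfResidual,
        ", RSS =", format(object@rss, digits = 4),
        ", BIC =", format(object@bic, digits = 6), "\n")
    if (!is.na(object@fStat))
        cat("treatment F =", format(object@fStat, digits = 4),
            ", p =", format(object@pValue, digits = 4), "\n")
})
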