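#' Channel identifiers of a design or channel set
#'
#' @param object a [HybridizationDesign-class] or [ChannelSet-class].
#' @return character vector `"<array_id>:<dye>"`, in object order.
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))

#' @rdname channelIds
#' @export
setMethod("channelIds", "HybridizationDesign",
          function(object) rownames(object@table))

#' @rdname channelIds
#' @export
setMethod("channelIds", "ChannelSet", function(object) colnames(object))

#' Design table accessor
#'
#' @param object a [HybridizationDesign-class].
#' @return the underlying `data.frame` (one row per channel).
#' @export
setGeneric("designTable", function(object) standardGeneric("designTable"))

#' @rdname designTable
#' @export
setMethod("designTable", "HybridizationDesign", function(object) object@table)

#' Validate a hybridization design
#'
#' Reports structural problems: arrays missing a dye partner, duplicated
#' channels, channels with undefined sample/treatment/unit, and per-treatment
#' dye imbalance.  Validation never throws; callers decide whether the
#' violations are fatal.  Severity `"error"` marks a malformed design,
#' `"warning"` marks an analyzable but unbalanced one.
#'
#' @param design a [HybridizationDesign-class].
#' @return a `data.frame` with columns `severity` and `message`; zero rows
#'   if and only if the design is well-formed and dye-balanced.
#' @examples
#' d <- makeDesign("two-group-paired", nGroups = 2, technicalReplicates = 4)
#' validateDesign(d)   # zero rows
#' @export
setGeneric("validateDesign", function(design) standardGeneric("validateDesign"))

#' @rdname validateDesign
#' @export
setMethod("validateDesign", "HybridizationDesign", function(design) {
    tab <- designTable(design)
    sev <- character(0); txt <- character(0)
    add <- function(s, m) {
        sev <<- c(sev, s); txt <<- c(txt, m)
    }
    dup <- paste(tab$array_id, tab$dye)
    for (d in unique(dup[duplicated(dup)]))
        add("error", paste0("duplicate dye on array: ", d))
    cnt <- table(tab$array_id)
    for (a in names(cnt)[cnt == 1L])
        add("error", paste0("array ", a, " missing dye partner (",
                            setdiff(.DYES, tab$dye[tab$array_id == a]),
                            ")"))
    for (a in names(cnt)[cnt > 2L])
        add("error", paste0("array ", a, " has more than two channels"))
    for (cc in c("sample_id", "treatment", "unit")) {
        bad <- is.na(tab[[cc]]) | tab[[cc]] == ""
        if (any(bad))
            add("error", paste0("undefined ", cc, " for channel(s): ",
                                paste(rownames(tab)[bad], collapse = ", ")))
    }
    for (tr in unique(tab$treatment)) {
        sub <- tab[tab$treatment == tr, , drop = FALSE]
        n3 <- sum(sub$dye == "Cy3"); n5 <- sum(sub$dye == "Cy5")
        if (n3 != n5)
            add("warning", paste0("dye imbalance for treatment ", tr,
                                  " (Cy3=", n3, ", Cy5=", n5, ")"))
    }
    data.frame(severity = sev, message = txt, stringsAsFactors = FALSE)
})

#' Split a design into two technical-replicate halves
#'
#' Splits the channels of a design into two biologically identical halves
#' so that reproducibility of downstream gene rankings can be assessed.
#' Two rules are supported:
#'
#' * `"by-replicate-set"`: channels follow their `replicate_set` label
#'   (both channels of an array always share a label), as when an entire
#'   factorial experiment is hybridized twice.
#' * `"once-per-subject"`: every unit (subject) must occur on exactly two
#'   channels; each half receives one of them, as when each subject of a
#'   loop design is hybridized twice.  A deterministic greedy pass over
#'   arrays keeps an array's two channels in the same half whenever both of
#'   its subjects still need that half, so that within-array pairs (and
#'   hence the array-effect model) remain estimable in each half; on a
#'   single loop this alternates whole arrays between halves, and the two
#'   halves pair subjects differently on arrays.  With `seed` set, arrays
#'   are processed in random order instead, giving a random valid split.
#'
#' @param design a [HybridizationDesign-class].
#' @param rule `"by-replicate-set"` or `"once-per-subject"`.
#' @param seed optional integer; randomizes the once-per-subject split.
#' @return a [ReplicateSplit-class]; halves are disjoint and jointly
#'   exhaustive.
#' @examples
#' d <- makeDesign("interwoven-loop", nGroups = 7, nUnitsPerGroup = 7)
#' sp <- splitReplicates(d, "once-per-subject")
#' length(sp@half1)  # 49
#' @export
setGeneric("splitReplicates",
           function(design, rule = c("by-replicate-set", "once-per-subject"),
                    seed = NULL)
               standardGeneric("splitReplicates"))

#' @rdname splitReplicates
#' @export
setMethod("splitReplicates", "HybridizationDesign",
function(design, rule = c("by-replicate-set", "once-per-subject"),
         seed = NULL) {
    rule <- match.arg(rule)
    tab <- designTable(design)
    ch <- rownames(tab)
    if (rule == "by-replicate-set") {
        rs <- tab$replicate_set
        if (any(is.na(rs)))
            stop("replicate_set must be defined on every channel for ",
                 "rule 'by-replicate-set'")
        lev <- sort(unique(rs))
        if (length(lev) != 2L)
            stop("replicate_set must take exactly two values, got: ",
                 paste(lev, collapse = ", "))
        return(new("ReplicateSplit", half1 = ch[rs == lev[1L]],
                   half2 = ch[rs == lev[2L]], rule = rule))
    }
    cnt <- table(tab$unit)
    if (any(cnt != 2L))
        stop("rule 'once-per-subject' requires every unit on exactly two ",
             "channels; offending unit(s): ",
             paste(names(cnt)[cnt != 2L], collapse = ", "))
    arrays <- unique(tab$array_id)
    if (!is.null(seed)) {
        set.seed(as.integer(seed))
        arrays <- sample(arrays)
    }
    in1 <- character(0); in2 <- character(0)
    h1 <- character(0); h2 <- character(0)
    for (a in arrays) {
        rows <- which(tab$array_id == a)
        u <- tab$unit[rows]
        if (length(rows) == 2L && u[1L] == u[2L]) {
            h1 <- c(h1, ch[rows[1L]]); in1 <- c(in1, u[1L])
            h2 <- c(h2, ch[rows[2L]]); in2 <- c(in2, u[2L])
        } else if (!any(u %in% in1)) {
            h1 <- c(h1, ch[rows]); in1 <- c(in1, u)
        } else if (!any(u %in% in2)) {
            h2 <- c(h2, ch[rows]); in2 <- c(in2, u)
        } else {
            for (i in seq_along(rows)) {
                if (!(u[i] %in% in1)) {
                    h1 <- c(h1, ch[rows[i]]); in1 <- c(in1, u[i])
                } else {
                    h2 <- c(h2, ch[rows[i]]); in2 <- c(in2, u[i])
                }
            }
        }
    }
    new("ReplicateSplit", half1 = h1, half2 = h2, rule = rule)
})

#' Read / write a hybridization design table
#'
#' Tab-delimited with header columns `array_id`, `dye`, `sample_id`,
#' `treatment`, `unit` and optionally `replicate_set`; dye values are
#' matched case-insensitively; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return `readDesign`: a [HybridizationDesign-class].
#' @export
readDesign <- function(path) {
    tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    HybridizationDesign(tab)
}

#' @param design a [HybridizationDesign-class] to write.
#' @rdname readDesign
#' @export
writeDesign <- function(design, path) {
    utils::write.table(designTable(design), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Subset a design to a set of channels
#'
#' @param design a [HybridizationDesign-class].
#' @param channels channel identifiers (`"array:dye"`), e.g. one half of a
#'   [splitReplicates()] result.
#' @return a [HybridizationDesign-class] restricted to those channels, in
#'   the requested order.
#' @export
subsetDesign <- function(design, channels) {
    tab <- designTable(design)
    missing <- setdiff(channels, rownames(tab))
    if (length(missing))
        stop("unknown channel(s): ", paste(missing, collapse = ", "))
    HybridizationDesign(tab[channels, , drop = FALSE])
}
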