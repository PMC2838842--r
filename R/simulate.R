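## Synthetic dual-color datasets with the variance structure the genewise
## models assume:
##   y(probe, channel) = mu + tau[treatment] + b[unit] + alpha[array]
##                       + dyeEffect (Cy5) + noise
## All effects are per-probe; array effects in particular are spot-level
## (per probe per array), matching the genewise alpha the ratio model
## estimates.  One root seed expands into fixed per-component substreams,
## drawn probe-major, so enlarging nProbes appends draws without
## perturbing existing ones.

#' Simulation configuration
#'
#' Defaults describe a modern high-quality two-color platform: log2
#' baselines around 10 (sd 1), small residual noise (`sigmaNoise` 0.2),
#' an array effect that is present but small relative to treatment
#' (`sigmaArray` 0.1), no dye bias, and 30% differentially expressed
#' probes with effects drawn from N(0, 0.4) log2 units.  `sigmaUnit`
#' models subject-level biological variation (0 for cell lines; around
#' 0.6 for a human-tissue, brain-like scenario).
#'
#' @param nProbes number of probes.
#' @param topology `"two-group-paired"` (both groups co-hybridized on
#'   every array), `"factorial-replicated"` (every unit receives every
#'   treatment; within each technical replicate set a unit's treatments
#'   are chained around a dye-balanced loop of arrays) or
#'   `"interwoven-loop"` (treatment groups chained g -> g+1 around one
#'   loop over distinct subjects, every subject hybridized exactly twice,
#'   once per dye).
#' @param nGroups number of treatment groups (2 for paired; >= 3 for the
#'   loop).
#' @param nUnitsPerGroup units per group (loop); total units receiving
#'   every treatment (factorial).
#' @param technicalReplicates arrays (paired) or replicate sets
#'   (factorial); the loop always hybridizes each unit twice.
#' @param baselineMean,baselineSd per-probe baseline log2 intensity.
#' @param fractionDE fraction of probes with a true treatment effect.
#' @param effectSd sd of true effects for DE probes (reference group 0).
#' @param effectValues optional fixed effect sizes recycled over DE probes
#'   (overrides `effectSd`).
#' @param sigmaNoise residual (within-channel) sd, log2 units.
#' @param sigmaArray spot-level array-effect sd.
#' @param sigmaUnit subject-level biological sd.
#' @param dyeEffect additive shift on Cy5 channels (default 0; designs
#'   are dye-balanced and the fitted models carry no dye term).
#' @param seed mandatory integer root seed.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(nProbes = 1000L,
                      topology = c("two-group-paired",
                                   "factorial-replicated",
                                   "interwoven-loop"),
                      nGroups = 2L, nUnitsPerGroup = 1L,
                      technicalReplicates = 8L,
                      baselineMean = 10, baselineSd = 1,
                      fractionDE = 0.3, effectSd = 0.4,
                      effectValues = NULL,
                      sigmaNoise = 0.2, sigmaArray = 0.1, sigmaUnit = 0,
                      dyeEffect = 0, seed) {
    topology <- match.arg(topology)
    if (missing(seed) || is.null(seed))
        stop("a seed is mandatory for every stochastic run")
    stopifnot(nProbes >= 1, nGroups >= 2, nUnitsPerGroup >= 1,
              technicalReplicates >= 1,
              baselineSd >= 0, fractionDE >= 0, fractionDE <= 1,
              effectSd >= 0, sigmaNoise >= 0, sigmaArray >= 0,
              sigmaUnit >= 0)
    structure(list(nProbes = as.integer(nProbes), topology = topology,
                   nGroups = as.integer(nGroups),
                   nUnitsPerGroup = as.integer(nUnitsPerGroup),
                   technicalReplicates = as.integer(technicalReplicates),
                   baselineMean = baselineMean, baselineSd = baselineSd,
                   fractionDE = fractionDE, effectSd = effectSd,
                   effectValues = effectValues,
                   sigmaNoise = sigmaNoise, sigmaArray = sigmaArray,
                   sigmaUnit = sigmaUnit, dyeEffect = dyeEffect,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

#' Read a simulation configuration from a flat YAML file
#'
#' Keys are the arguments of [simConfig()].
#'
#' @param path YAML file path.
#' @param seed optional override of the file's seed.
#' @return a `SimConfig`.
#' @export
readSimConfig <- function(path, seed = NULL) {
    vals <- yaml::read_yaml(path)
    if (!is.null(seed)) vals$seed <- seed
    do.call(simConfig, vals)
}

#' Generate a standard hybridization topology
#'
#' @param topology see [simConfig()].
#' @param nGroups,nUnitsPerGroup,technicalReplicates see [simConfig()].
#' @return a [HybridizationDesign-class], dye-balanced where the topology
#'   permits.
#' @examples
#' makeDesign("two-group-paired", nGroups = 2, technicalReplicates = 10)
#' makeDesign("interwoven-loop", nGroups = 7, nUnitsPerGroup = 7)
#' @export
makeDesign <- function(topology = c("two-group-paired",
                                    "factorial-replicated",
                                    "interwoven-loop"),
                       nGroups = 2L, nUnitsPerGroup = 1L,
                       technicalReplicates = 2L) {
    topology <- match.arg(topology)
    if (topology == "two-group-paired") {
        if (nGroups != 2L)
            stop("two-group-paired requires exactly 2 groups")
        nArr <- technicalReplicates
        rows <- lapply(seq_len(nArr), function(a) {
            g <- c("G1", "G2")
            ## dye-swap every other array
            dyes <- if (a %% 2L == 1L) c("Cy3", "Cy5") else c("Cy5", "Cy3")
            data.frame(array_id = paste0("A", a), dye = dyes,
                       sample_id = g, treatment = g, unit = g,
                       replicate_set = rep(((a - 1L) %/% 2L) %% 2L + 1L, 2L))
        })
        return(HybridizationDesign(do.call(rbind, rows)))
    }
    if (topology == "factorial-replicated") {
        ## per unit and replicate set: a dye-balanced loop over the
        ## treatments (nGroups arrays; every treatment once per dye), the
        ## layout of one cell-line slide
        rows <- list()
        a <- 0L
        for (u in seq_len(nUnitsPerGroup)) {
            unit <- paste0("U", u)
            for (r in seq_len(technicalReplicates)) {
                for (g in seq_len(nGroups)) {
                    a <- a + 1L
                    tr <- paste0("T", c(g, g %% nGroups + 1L))
                    rows[[length(rows) + 1L]] <- data.frame(
                        array_id = paste0("A", a), dye = c("Cy3", "Cy5"),
                        sample_id = paste0(unit, ".", tr, ".r", r),
                        treatment = tr, unit = unit,
                        replicate_set = rep(r, 2L))
                }
            }
        }
        return(HybridizationDesign(do.call(rbind, rows)))
    }
    ## interwoven loop: one cycle over all samples, consecutive samples in
    ## consecutive groups; sample i is Cy3 on array i and Cy5 on array i-1.
    if (nGroups < 3L)
        stop("interwoven-loop requires at least 3 groups")
    N <- nGroups * nUnitsPerGroup
    grp <- paste0("G", (seq_len(N) - 1L) %% nGroups + 1L)
    unit <- paste0("U", seq_len(N))
    rows <- lapply(seq_len(N), function(i) {
        j <- i %% N + 1L     # co-hybridized next sample around the loop
        data.frame(array_id = paste0("A", i), dye = c("Cy3", "Cy5"),
                   sample_id = c(unit[i], unit[j]),
                   treatment = c(grp[i], grp[j]),
                   unit = c(unit[i], unit[j]),
                   replicate_set = NA_integer_)
    })
    HybridizationDesign(do.call(rbind, rows))
}

## Fixed substream seeds below 2^31, one per stochastic component.
.substream <- function(seed, k)
    as.integer((as.numeric(seed) + k * 1299709) %% 2147483647)

## rnorm drawn probe-major: a probes x m matrix whose first nProbes*m
## draws are unchanged when nProbes grows.
.drawMatrix <- function(nProbes, m, sd, seed) {
    set.seed(seed)
    if (sd == 0) return(matrix(0, nProbes, m))
    matrix(stats::rnorm(nProbes * m, 0, sd), nProbes, m, byrow = TRUE)
}

#' Simulate a dual-color dataset with ground truth
#'
#' Generates log2 intensities probe by channel as baseline + treatment
#' effect + unit (subject) effect + spot-level array effect + optional dye
#' shift + Gaussian noise, on the design given by the config topology.
#' Identical seeds give bit-identical output.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `channels` (a log2-scale
#'   [ChannelSet-class]), `design` (a [HybridizationDesign-class]) and
#'   `truth` (list: `probes` data.frame with `probe_id`, `mu`, `de` and
#'   one `tau.<group>` column per group; `arrayEffects` and `unitEffects`
#'   matrices).
#' @export
simulateDataset <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    design <- makeDesign(config$topology, config$nGroups,
                         config$nUnitsPerGroup, config$technicalReplicates)
    tab <- designTable(design)
    P <- config$nProbes
    groups <- sort(unique(tab$treatment))
    units <- unique(tab$unit)
    arrays <- unique(tab$array_id)
    G <- length(groups); U <- length(units); A <- length(arrays)
    nCh <- nrow(tab)

    set.seed(.substream(config$seed, 1L))
    mu <- stats::rnorm(P, config$baselineMean, config$baselineSd)
    set.seed(.substream(config$seed, 2L))
    de <- stats::runif(P) < config$fractionDE
    ## treatment effects: reference group = 0; DE probes get effects on
    ## the other groups
    tau <- matrix(0, P, G, dimnames = list(NULL, groups))
    if (G > 1L) {
        if (is.null(config$effectValues)) {
            eff <- .drawMatrix(P, G - 1L, config$effectSd,
                               .substream(config$seed, 3L))
        } else {
            eff <- matrix(rep_len(config$effectValues, P * (G - 1L)),
                          P, G - 1L)
        }
        eff[!de, ] <- 0
        tau[, -1L] <- eff
    }
    b <- .drawMatrix(P, U, config$sigmaUnit, .substream(config$seed, 4L))
    alpha <- .drawMatrix(P, A, config$sigmaArray, .substream(config$seed, 5L))
    eps <- .drawMatrix(P, nCh, config$sigmaNoise, .substream(config$seed, 6L))

    gi <- match(tab$treatment, groups)
    ui <- match(tab$unit, units)
    ai <- match(tab$array_id, arrays)
    vals <- matrix(0, P, nCh)
    for (c in seq_len(nCh))
        vals[, c] <- mu + tau[, gi[c]] + b[, ui[c]] + alpha[, ai[c]] +
            eps[, c] + if (tab$dye[c] == "Cy5") config$dyeEffect else 0
    probeIds <- sprintf("P%05d", seq_len(P))
    rownames(vals) <- probeIds
    cs <- ChannelSet(vals, arrayIds = tab$array_id, dyes = tab$dye,
                     probeIds = probeIds, logScale = TRUE,
                     provenance = paste0("simulated: ", config$topology,
                                         ", seed ", config$seed))
    truthProbes <- data.frame(probe_id = probeIds, mu = mu, de = de,
                              stringsAsFactors = FALSE)
    for (g in seq_len(G)) truthProbes[[paste0("tau.", groups[g])]] <- tau[, g]
    dimnames(b) <- list(probeIds, units)
    dimnames(alpha) <- list(probeIds, arrays)
    list(channels = cs, design = design,
         truth = list(probes = truthProbes, arrayEffects = alpha,
                      unitEffects = b))
}

#' Write a simulated dataset to disk
#'
#' Writes `channels.tsv` (wide TSV, see [writeChannels()]), `design.tsv`,
#' `truth.tsv` (per-probe true parameters) plus `array_effects.tsv` and
#' `unit_effects.tsv`.  [readChannels()] round-trips the matrix exactly.
#'
#' @param sim a [simulateDataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeChannels(sim$channels, file.path(dir, "channels.tsv"))
    writeDesign(sim$design, file.path(dir, "design.tsv"))
    wt <- function(x, f) {
        num <- vapply(x, is.numeric, logical(1L))
        for (j in which(num)) x[[j]] <- formatC(x[[j]], digits = 17,
                                                format = "g")
        utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    wt(sim$truth$probes, "truth.tsv")
    wt(data.frame(probe_id = rownames(sim$truth$arrayEffects),
                  sim$truth$arrayEffects, check.names = FALSE),
       "array_effects.tsv")
    wt(data.frame(probe_id = rownames(sim$truth$unitEffects),
                  sim$truth$unitEffects, check.names = FALSE),
       "unit_effects.tsv")
    invisible(dir)
}
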