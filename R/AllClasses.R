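#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## Controlled vocabularies used throughout the package.  Strains follow the
## factorial knockout design: a reference strain, the two single-deletion
## strains and the double-deletion strain.
.STRAINS    <- c("control", "atfA_del", "atfB_del", "double_del")
.TREATMENTS <- c("untreated", "MSB")
.CELL_TYPES <- c("mycelium", "conidium")

## The nine dependence categories.  AA/BB: dependent on one factor only;
## AB: both factors required, either deletion is as severe as the double;
## A/B: either factor suffices, only the double deletion has an effect;
## A-B1..A-B5: both factors contribute, single deletions give intermediate
## expression (the five sub-patterns encode which deletion is stronger).
.CATEGORIES <- c("AA", "BB", "AB", "A/B", "A-B1", "A-B2", "A-B3", "A-B4", "A-B5")

#' Dependence category labels
#'
#' @return Character vector of the nine transcription-factor dependence
#'   categories in canonical order.
#' @export
dependenceCategories <- function() .CATEGORIES

#' FactorialCounts: counts plus factorial sample annotation
#'
#' A \linkS4class{SummarizedExperiment} holding a non-negative integer count
#' matrix (assay \code{"counts"}) whose \code{colData} describes the factorial
#' knockout design: columns \code{strain}, \code{treatment}, \code{cell_type},
#' \code{batch} and \code{replicate}.
#'
#' @export
setClass("FactorialCounts", contains = "SummarizedExperiment")

setValidity("FactorialCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
        if (any(is.na(cnt)))
            msg <- c(msg, "counts must not contain NA")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain", "treatment", "cell_type", "batch", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("strain" %in% colnames(cd) &&
        !all(as.character(cd$strain) %in% .STRAINS))
        msg <- c(msg, paste0("strain must be one of: ",
                             paste(.STRAINS, collapse = ", ")))
    if ("treatment" %in% colnames(cd) &&
        !all(as.character(cd$treatment) %in% .TREATMENTS))
        msg <- c(msg, paste0("treatment must be one of: ",
                             paste(.TREATMENTS, collapse = ", ")))
    if ("cell_type" %in% colnames(cd) &&
        !all(as.character(cd$cell_type) %in% .CELL_TYPES))
        msg <- c(msg, paste0("cell_type must be one of: ",
                             paste(.CELL_TYPES, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (length(msg)) msg else TRUE
})

#' Construct a FactorialCounts object
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param sampleSheet data.frame with columns \code{sample_id}, \code{strain},
#'   \code{treatment}, \code{cell_type}, \code{batch}, \code{replicate}.
#'   Sample IDs must match the count matrix columns exactly (order may differ).
#' @param lengths optional named numeric vector of gene lengths in bp; stored
#'   in \code{rowData(x)$length_bp}.
#' @return A \linkS4class{FactorialCounts} object.
#' @examples
#' cnt <- matrix(0:7, nrow = 2,
#'               dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     strain = c("control", "control", "atfA_del", "atfA_del"),
#'                     treatment = "untreated", cell_type = "mycelium",
#'                     batch = "b1", replicate = rep(1:2, 2))
#' fc <- FactorialCounts(cnt, sheet)
#' @export
FactorialCounts <- function(counts, sampleSheet, lengths = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("count matrix must have gene rownames and sample colnames")
    if (!"sample_id" %in% colnames(sampleSheet))
        stop("sample sheet lacks a 'sample_id' column")
    extra <- setdiff(sampleSheet$sample_id, colnames(counts))
    if (length(extra))
        stop("sample(s) in sheet but not in count matrix: ",
             paste(extra, collapse = ", "))
    extra <- setdiff(colnames(counts), sampleSheet$sample_id)
    if (length(extra))
        stop("sample(s) in count matrix but not in sheet: ",
             paste(extra, collapse = ", "))
    sampleSheet <- sampleSheet[match(colnames(counts), sampleSheet$sample_id), ,
                               drop = FALSE]
    cd <- S4Vectors::DataFrame(sampleSheet, row.names = sampleSheet$sample_id)
    rd <- S4Vectors::DataFrame(row.names = rownames(counts))
    if (!is.null(lengths)) {
        miss <- setdiff(rownames(counts), names(lengths))
        if (length(miss))
            stop("gene length missing for: ",
                 paste(utils::head(miss, 5), collapse = ", "))
        rd$length_bp <- unname(lengths[rownames(counts)])
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd, rowData = rd)
    new("FactorialCounts", se)
}

#' SetSystem: a named collection of gene sets over one condition
#'
#' Holds the gene sets (Set0, Set0+, Set1..Set27 and their upregulated "+"
#' mirrors, plus the five A-B sub-sets) derived from the regulation calls of
#' one condition (cell type x treatment), together with the gene universe the
#' calls were made over.
#'
#' @slot sets named list of character vectors of gene IDs.
#' @slot condition free-text condition label, e.g. "mycelium,untreated".
#' @slot universe character vector of all genes tested in the condition.
#' @export
setClass("SetSystem",
         representation(sets = "list", condition = "character",
                        universe = "character"))

setValidity("SetSystem", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "sets must be uniquely named")
    bad <- !vapply(object@sets, is.character, logical(1))
    if (any(bad))
        msg <- c(msg, "each set must be a character vector of gene IDs")
    outside <- vapply(object@sets,
                      function(s) any(!s %in% object@universe), logical(1))
    if (any(outside))
        msg <- c(msg, paste0("set(s) contain genes outside the universe: ",
                             paste(names(object@sets)[outside], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @describeIn SetSystem-class Named list of gene sets.
#' @param x,object a \code{SetSystem}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname SetSystem-class
#' @export
setMethod("geneSets", "SetSystem", function(x) x@sets)

#' @describeIn SetSystem-class Integer vector of set sizes.
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname SetSystem-class
#' @export
setMethod("setSizes", "SetSystem",
          function(x) vapply(x@sets, length, integer(1)))

#' @describeIn SetSystem-class The gene universe of the condition.
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))

#' @rdname SetSystem-class
#' @export
setMethod("setUniverse", "SetSystem", function(x) x@universe)

#' @describeIn SetSystem-class Condition label.
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname SetSystem-class
#' @export
setMethod("conditionLabel", "SetSystem", function(x) x@condition)

setMethod("show", "SetSystem", function(object) {
    cat("SetSystem for condition '", object@condition, "'\n", sep = "")
    cat("  universe: ", length(object@universe), " genes; ",
        length(object@sets), " sets\n", sep = "")
    key <- intersect(c("Set1", "Set2", "Set3", "Set26", "Set27"),
                     names(object@sets))
    if (length(key)) {
        sz <- setSizes(object)[key]
        cat("  ", paste(sprintf("%s=%d", key, sz), collapse = "  "), "\n",
            sep = "")
    }
})

#' SimConfig: parameters of the synthetic factorial experiment
#'
#' @slot nGenes number of non-marker genes to simulate (two knockout marker
#'   genes, \code{atfA} and \code{atfB}, are appended on top).
#' @slot replicates biological replicates per (strain, treatment) group.
#' @slot meanDepth expected reads per sample.
#' @slot baselineLogRange log10 bounds of the per-gene baseline expression
#'   (expected count at the 1e6-read reference depth).
#' @slot dispersion mean NB dispersion alpha.
#' @slot dispersionShape shape of the gamma distribution the per-gene
#'   dispersions are drawn from (with mean \code{dispersion}); \code{Inf}
#'   means every gene gets the scalar \code{dispersion}.
#' @slot classProportions named fractions over the nine dependence categories
#'   plus \code{msb_up}, \code{msb_down} and \code{none}; must sum to 1.
#' @slot effectMultipliers named numeric \code{c(high=, mid=, low=)} relative
#'   group means used by the canonical per-category patterns.
#' @slot msbFoldChange fold change applied to MSB-responsive genes under MSB.
#' @slot nBatches number of batches (1 for the mycelium scenario, 2 for the
#'   conidium scenario).
#' @slot batchSd sdlog of the per-gene lognormal batch factor.
#' @slot depthJitterSd sdlog of the per-sample lognormal depth factor.
#' @slot cellType "mycelium" or "conidium".
#' @slot seed integer seed driving all randomness.
#' @export
setClass("SimConfig",
         representation(nGenes = "numeric", replicates = "numeric",
                        meanDepth = "numeric", baselineLogRange = "numeric",
                        dispersion = "numeric", dispersionShape = "numeric",
                        classProportions = "numeric",
                        effectMultipliers = "numeric",
                        msbFoldChange = "numeric",
                        nBatches = "numeric", batchSd = "numeric",
                        depthJitterSd = "numeric", cellType = "character",
                        seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
    if (object@replicates < 2) msg <- c(msg, "replicates must be >= 2")
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
    if (length(object@baselineLogRange) != 2 ||
        diff(object@baselineLogRange) < 0)
        msg <- c(msg, "baselineLogRange must be increasing log10 bounds")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    p <- object@classProportions
    want <- c(.CATEGORIES, "msb_up", "msb_down", "none")
    if (!setequal(names(p), want))
        msg <- c(msg, paste0("classProportions must be named exactly: ",
                             paste(want, collapse = ", ")))
    else if (abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "classProportions must sum to 1")
    if (any(p < 0)) msg <- c(msg, "classProportions must be non-negative")
    em <- object@effectMultipliers
    if (!setequal(names(em), c("high", "mid", "low")))
        msg <- c(msg, "effectMultipliers must be named high, mid, low")
    else {
        if (!(0 < em["low"] && em["low"] < em["mid"] && em["mid"] < em["high"]))
            msg <- c(msg, "need 0 < low < mid < high")
        else if (log2(em["high"] / em["mid"]) <= 1 ||
                 log2(em["mid"] / em["low"]) <= 1)
            msg <- c(msg, paste0("log2(high/mid) and log2(mid/low) must ",
                                 "exceed the fold-change threshold of 1"))
    }
    if (!object@cellType %in% .CELL_TYPES)
        msg <- c(msg, "cellType must be 'mycelium' or 'conidium'")
    if (object@nBatches < 1) msg <- c(msg, "nBatches must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes (+2 knockout markers),",
        object@replicates, "replicates/group,", object@cellType,
        "scenario,", object@nBatches, "batch(es)\n")
    cat("  depth", format(object@meanDepth, big.mark = ","),
        " dispersion", object@dispersion,
        if (is.finite(object@dispersionShape))
            paste0("(gamma, shape ", object@dispersionShape, ")")
        else "(constant)", " seed", object@seed, "\n")
})

#' Default class proportions of the synthetic generator
#'
#' Fractions of genes assigned to each designed dependence category, to the
#' two MSB-responsiveness classes and to the unaffected background.
#'
#' @return Named numeric vector summing to 1.
#' @export
defaultClassProportions <- function() {
    p <- c(AA = 0.05, BB = 0.02, AB = 0.01, `A/B` = 0.01,
           `A-B1` = 0.005, `A-B2` = 0.005, `A-B3` = 0.005,
           `A-B4` = 0.005, `A-B5` = 0.005,
           msb_up = 0.05, msb_down = 0.05)
    c(p, none = 1 - sum(p))
}

#' Build a simulation configuration
#'
#' @param nGenes,replicates,meanDepth,baselineLogRange,dispersion,dispersionShape
#'   see \linkS4class{SimConfig}.
#' @param classProportions,effectMultipliers,msbFoldChange,nBatches,batchSd,depthJitterSd,cellType,seed
#'   see \linkS4class{SimConfig}.
#' @details \code{nBatches} defaults to 2 for the conidium scenario and 1 for
#'   the mycelium scenario, mirroring the two-experiment origin of conidial
#'   samples in the experimental design the generator emulates.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 500, seed = 1)
#' @export
simConfig <- function(nGenes = 2000, replicates = 3, meanDepth = 1e6,
                      baselineLogRange = c(1, 4), dispersion = 0.05,
                      dispersionShape = 2,
                      classProportions = defaultClassProportions(),
                      effectMultipliers = c(high = 1, mid = 0.25, low = 0.0625),
                      msbFoldChange = 4,
                      nBatches = if (cellType == "conidium") 2L else 1L,
                      batchSd = 0.1, depthJitterSd = 0.05,
                      cellType = "mycelium", seed = 1L) {
    new("SimConfig", nGenes = nGenes, replicates = replicates,
        meanDepth = meanDepth, baselineLogRange = baselineLogRange,
        dispersion = dispersion, dispersionShape = dispersionShape,
        classProportions = classProportions,
        effectMultipliers = effectMultipliers, msbFoldChange = msbFoldChange,
        nBatches = nBatches, batchSd = batchSd,
        depthJitterSd = depthJitterSd, cellType = cellType, seed = seed)
}
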