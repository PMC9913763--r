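## Synthetic factorial knockout experiments with known per-gene ground truth.
##
## Counts are negative binomial with mean
##   baseline x strain multiplier x treatment multiplier
##            x depth factor x batch factor,
## where the strain multipliers follow the canonical pattern of the gene's
## designed dependence category (control always "high").  Two knockout
## marker genes ("atfA", "atfB") are appended: each has zero mean in the
## strains carrying its deletion, and the atfB marker is additionally
## reduced to "mid" level in the atfA-deletion background, emulating the
## downregulation of atfB upon atfA deletion.

#' Simulate a factorial knockout RNA-seq experiment
#'
#' Generates one sample per (strain, treatment, replicate) for the
#' configured cell type, with negative-binomial counts and a truth table
#' recording every gene's designed dependence category and
#' MSB-responsiveness.
#'
#' All randomness derives from \code{config@seed} via \code{set.seed};
#' the generator order is: baselines, gene lengths, dispersions, class
#' assignment, batch factors, depth jitter, counts.  Identical
#' configurations therefore give bitwise-identical outputs.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return List with \code{experiment} (a \linkS4class{FactorialCounts} with
#'   gene lengths in \code{rowData}), \code{truth} (data.frame with columns
#'   \code{gene_id}, \code{category}, \code{msb_response},
#'   \code{baseline_mean}, \code{length_bp}, \code{is_knockout_marker}) and
#'   \code{lengths} (named vector of gene lengths in bp).
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 50, seed = 7))
#' dim(SummarizedExperiment::assay(sim$experiment))
#' @export
simulateExperiment <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    nG <- as.integer(config@nGenes)
    ids <- sprintf("g%05d", seq_len(nG))

    baseline <- 10^stats::runif(nG, config@baselineLogRange[1],
                                config@baselineLogRange[2])
    lengths <- round(10^stats::runif(nG, 2.5, 4))   # 316 bp .. 10 kb
    alpha <- if (is.finite(config@dispersionShape))
        stats::rgamma(nG, shape = config@dispersionShape,
                      scale = config@dispersion / config@dispersionShape)
    else rep(config@dispersion, nG)
    alpha <- pmax(alpha, 1e-8)

    p <- config@classProportions
    cls <- sample(names(p), nG, replace = TRUE, prob = p)

    ## append knockout markers
    ids <- c(ids, "atfA", "atfB")
    baseline <- c(baseline, 500, 300)
    lengths <- c(lengths, 2000, 1800)
    names(lengths) <- ids
    alpha <- c(alpha, rep(max(1e-8, config@dispersion), 2))
    cls <- c(cls, "none", "none")
    nTot <- nG + 2L
    isMarker <- c(rep(FALSE, nG), TRUE, TRUE)

    ## strain multipliers per gene (nTot x 4)
    em <- config@effectMultipliers
    strainMult <- matrix(1, nTot, length(.STRAINS),
                         dimnames = list(ids, .STRAINS))
    for (cat in .CATEGORIES) {
        idx <- which(cls == cat)
        if (!length(idx)) next
        pat <- canonicalPattern(cat)$multipliers
        strainMult[idx, ] <- rep(em[pat[.STRAINS]], each = length(idx))
    }
    strainMult["atfA", c("atfA_del", "double_del")] <- 0
    strainMult["atfB", c("atfB_del", "double_del")] <- 0
    strainMult["atfB", "atfA_del"] <- em["mid"]

    msb <- ifelse(cls == "msb_up", "up",
                  ifelse(cls == "msb_down", "down", "none"))
    treatMult <- cbind(untreated = rep(1, nTot),
                       MSB = ifelse(msb == "up", config@msbFoldChange,
                                    ifelse(msb == "down",
                                           1 / config@msbFoldChange, 1)))

    ## sample layout
    reps <- as.integer(config@replicates)
    layout <- expand.grid(replicate = seq_len(reps),
                          treatment = .TREATMENTS, strain = .STRAINS,
                          stringsAsFactors = FALSE)
    layout <- layout[, c("strain", "treatment", "replicate")]
    nB <- as.integer(config@nBatches)
    layout$batch <- paste0("b", ((layout$replicate - 1L) %% nB) + 1L)
    layout$cell_type <- config@cellType
    layout$sample_id <- sprintf("%s_%s_%s_r%d",
                                substr(config@cellType, 1, 3),
                                sub("_del", "", layout$strain),
                                ifelse(layout$treatment == "MSB", "msb", "unt"),
                                layout$replicate)
    nS <- nrow(layout)

    batchFac <- matrix(1, nTot, nB)
    if (nB > 1)
        for (b in 2:nB)
            batchFac[, b] <- stats::rlnorm(nTot, 0, config@batchSd)
    depth <- (config@meanDepth / 1e6) *
        stats::rlnorm(nS, 0, config@depthJitterSd)

    bi <- match(layout$batch, paste0("b", seq_len(nB)))
    mu <- baseline * strainMult[, layout$strain, drop = FALSE] *
        treatMult[, layout$treatment, drop = FALSE] *
        batchFac[, bi, drop = FALSE]
    mu <- sweep(mu, 2L, depth, "*")
    counts <- matrix(stats::rnbinom(nTot * nS, mu = mu,
                                    size = rep(1 / alpha, nS)),
                     nrow = nTot,
                     dimnames = list(ids, layout$sample_id))

    truth <- data.frame(
        gene_id = ids,
        category = ifelse(cls %in% .CATEGORIES, cls, "none"),
        msb_response = msb,
        baseline_mean = baseline,
        length_bp = unname(lengths),
        is_knockout_marker = isMarker,
        stringsAsFactors = FALSE)

    sheet <- layout[, c("sample_id", "strain", "treatment", "cell_type",
                        "batch", "replicate")]
    experiment <- FactorialCounts(counts, sheet, lengths = lengths)
    list(experiment = experiment, truth = truth, lengths = lengths)
}

#' Score recovered dependence calls against the simulated truth
#'
#' Per-category precision and recall, a confusion matrix, and aggregate
#' precision/recall for the AtfA-dependent (Set26) and AtfB-dependent
#' (Set27) gene sets.  Knockout marker genes are excluded from scoring.
#'
#' @param truth truth table from \code{\link{simulateExperiment}}.
#' @param calls data.frame (or DataFrame) with columns \code{gene_id} and
#'   \code{category}, e.g. the \code{categories} element of
#'   \code{\link{dependentSets}}.
#' @return List with \code{perCategory} (data.frame: category, n_true,
#'   n_called, tp, precision, recall; precision is NA when nothing was
#'   called), \code{aggregate} (same rows for Set26/Set27), and
#'   \code{confusion} (table truth x called).
#' @export
evaluateRecovery <- function(truth, calls) {
    calls <- as.data.frame(calls)
    truth <- truth[!truth$is_knockout_marker, , drop = FALSE]
    if (!setequal(truth$gene_id, calls$gene_id))
        stop("truth and calls must cover the same gene universe ",
             "(after dropping knockout markers)")
    calls <- calls[match(truth$gene_id, calls$gene_id), , drop = FALSE]
    tcat <- truth$category
    ccat <- calls$category
    lev <- c(.CATEGORIES, "none")
    confusion <- table(truth = factor(tcat, lev), called = factor(ccat, lev))
    pr <- function(truthIn, callIn) {
        tp <- sum(truthIn & callIn)
        nT <- sum(truthIn); nC <- sum(callIn)
        data.frame(n_true = nT, n_called = nC, tp = tp,
                   precision = if (nC > 0) tp / nC else NA_real_,
                   recall = if (nT > 0) tp / nT else NA_real_)
    }
    perCategory <- do.call(rbind, lapply(.CATEGORIES, function(cat)
        cbind(category = cat, pr(tcat == cat, ccat == cat))))
    aDep <- setdiff(.CATEGORIES, "BB")
    bDep <- setdiff(.CATEGORIES, "AA")
    aggregate <- rbind(
        cbind(set = "Set26", pr(tcat %in% aDep, ccat %in% aDep)),
        cbind(set = "Set27", pr(tcat %in% bDep, ccat %in% bDep)))
    list(perCategory = perCategory, aggregate = aggregate,
         confusion = confusion)
}
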