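## Orchestration and reporting: run the comparisons of a condition, build
## its set system, summarize it in the layout of the published condition
## tables, and overlap set systems across conditions.

#' Run the dependence analysis for one condition
#'
#' Executes the five strain comparisons of a (cell type, treatment)
#' condition and the per-strain MSB vs untreated comparisons, converts them
#' to regulation calls, builds the full set system and assigns every tested
#' gene a dependence category.
#'
#' @param x a \linkS4class{FactorialCounts}.
#' @param cellType,treatment the condition.
#' @param lfcThreshold,alpha,gate see \code{\link{classifyRegulated}}.
#' @param batchAdjusted logical; default adjusts for batch whenever the
#'   samples of the cell type span more than one batch.
#' @param msbStrains strains whose MSB comparisons are run (for Set0 and
#'   the "any strain" MSB-responsive union); the control strain is always
#'   included.
#' @details The five strain comparisons share a per-gene dispersion pooled
#'   over all four strains of the condition
#'   (\code{\link{conditionDispersion}}); the MSB comparisons estimate
#'   theirs from their own two groups.
#' @return List with \code{system} (full \linkS4class{SetSystem} including
#'   Set26/Set27), \code{categories} (DataFrame gene_id, category,
#'   category_up), \code{regulation} (named list of regulation tables),
#'   \code{de} (named list of DE result DataFrames) and \code{msb}
#'   (regulation tables of the MSB comparisons, named by strain).
#' @export
callDependence <- function(x, cellType, treatment, lfcThreshold = 1,
                           alpha = 0.05, gate = "nominal",
                           batchAdjusted = NULL,
                           msbStrains = .STRAINS) {
    stopifnot(is(x, "FactorialCounts"))
    cd <- SummarizedExperiment::colData(x)
    inCt <- cd$cell_type == cellType
    if (!any(inCt)) stop("no samples of cell type ", cellType)
    if (is.null(batchAdjusted))
        batchAdjusted <- length(unique(cd$batch[inCt])) > 1
    cmps <- strainComparisons(cellType, treatment, batchAdjusted)
    disp <- conditionDispersion(x, cellType, treatment)
    de <- lapply(cmps, function(cmp)
        deTest(x, cmp, alpha = alpha, dispersion = disp))
    regulation <- lapply(de, classifyRegulated, lfcThreshold = lfcThreshold,
                         alpha = alpha, gate = gate)
    msbStrains <- union("control", msbStrains)
    msbDe <- lapply(msbStrains, function(s)
        deTest(x, msbComparison(s, cellType, batchAdjusted), alpha = alpha))
    names(msbDe) <- msbStrains
    msb <- lapply(msbDe, classifyRegulated, lfcThreshold = lfcThreshold,
                  alpha = alpha, gate = gate)
    regulation[[.MSB_CONTROL_COMPARISON]] <- msb[["control"]]
    condition <- paste(cellType, treatment, sep = ",")
    system <- buildPrimarySets(regulation, condition = condition)
    system <- deriveSets(system)
    dep <- dependentSets(system)
    c(dep, list(regulation = regulation, de = c(de, msbDe), msb = msb))
}

#' ConditionSummary: the published per-condition table layout
#'
#' @slot condition condition label.
#' @slot setCounts named integer vector of primary set sizes (Set1/Set1+,
#'   Set2/Set2+, Set3/Set3+, and Set0/Set0+ when available).
#' @slot dependent named list with entries \code{Set26} and \code{Set27},
#'   each a list holding \code{total}, the per-category \code{breakdown}
#'   and the MSB cross-tabulation.
#' @export
setClass("ConditionSummary",
         representation(condition = "character", setCounts = "integer",
                        dependent = "list"))

setMethod("show", "ConditionSummary", function(object) {
    cat("Condition:", object@condition, "\n")
    sc <- object@setCounts
    lab <- c(Set1 = "Responsive to atfA deletion",
             Set2 = "Responsive to atfB deletion",
             Set3 = "Responsive to the double deletion")
    for (nm in names(lab))
        if (all(c(nm, paste0(nm, "+")) %in% names(sc)))
            cat(sprintf("  %s (%s/%s+): %d upregulated, %d downregulated\n",
                        lab[[nm]], nm, nm, sc[[paste0(nm, "+")]], sc[[nm]]))
    for (dn in names(object@dependent)) {
        d <- object@dependent[[dn]]
        who <- if (dn == "Set26") "AtfA-dependent" else "AtfB-dependent"
        bd <- d$breakdown[d$breakdown > 0]
        cat(sprintf("  %s genes (%s): %d genes (%s)\n", who, dn, d$total,
                    paste(sprintf("%d %s", bd, names(bd)), collapse = ", ")))
        if (!is.null(d$msb))
            cat(sprintf("    (%d upregulated and %d downregulated MSB %s)\n",
                        d$msb$overlap[d$msb$direction == "up"],
                        d$msb$overlap[d$msb$direction == "down"],
                        "stress-responsive genes"))
    }
})

#' Summarize one condition's set system
#'
#' Counts of the primary sets, the Set26/Set27 totals with their
#' per-category breakdown (the partition property is enforced), and the
#' MSB-responsiveness cross-tabulation when Set0/Set0+ are present.
#'
#' @param system full \linkS4class{SetSystem} (after
#'   \code{\link{dependentSets}}).
#' @param alpha significance level for the MSB enrichment flags.
#' @return A \linkS4class{ConditionSummary}.
#' @export
summarizeCondition <- function(system, alpha = 0.05) {
    stopifnot(is(system, "SetSystem"))
    sets <- geneSets(system)
    need <- c("Set26", "Set27", "Set21", "Set22", "Set23", "Set24",
              paste0("A-B", 1:5))
    if (!all(need %in% names(sets)))
        stop("system lacks the dependence sets; run dependentSets() first")
    .checkPartition(system, "")
    prim <- intersect(c("Set0", "Set0+", "Set1", "Set1+", "Set2", "Set2+",
                        "Set3", "Set3+"), names(sets))
    setCounts <- setSizes(system)[prim]
    breakdownFor <- function(setName) {
        catSet <- c(AA = "Set21", BB = "Set22", AB = "Set23", `A/B` = "Set24",
                    `A-B1` = "A-B1", `A-B2` = "A-B2", `A-B3` = "A-B3",
                    `A-B4` = "A-B4", `A-B5` = "A-B5")
        keep <- if (setName == "Set26") setdiff(names(catSet), "BB")
                else setdiff(names(catSet), "AA")
        bd <- vapply(catSet[keep], function(nm) length(sets[[nm]]),
                     integer(1))
        names(bd) <- keep
        total <- length(sets[[setName]])
        if (sum(bd) != total)
            stop("internal error: ", setName, " breakdown (", sum(bd),
                 ") does not sum to its total (", total, ")")
        msb <- NULL
        if (all(c("Set0", "Set0+") %in% names(sets)))
            msb <- msbCrosstab(sets[[setName]], sets[["Set0"]],
                               sets[["Set0+"]], setUniverse(system),
                               alpha = alpha)
        list(total = total, breakdown = bd, msb = msb)
    }
    new("ConditionSummary", condition = conditionLabel(system),
        setCounts = setCounts,
        dependent = list(Set26 = breakdownFor("Set26"),
                         Set27 = breakdownFor("Set27")))
}

#' Overlaps between the sets of two conditions
#'
#' For every set name present in both systems, the overlap count and,
#' optionally, the percentage relative to the first system's set (the
#' convention used when comparing conidial against mycelial sets).
#'
#' @param systemA,systemB two \linkS4class{SetSystem} objects.
#' @param setNames set names to tabulate; default the names common to both.
#' @param percentRelativeTo \code{"A"}, \code{"B"} or \code{"none"}.
#' @return data.frame with columns \code{set_name}, \code{size_a},
#'   \code{size_b}, \code{overlap} and (unless \code{"none"}) \code{pct}.
#' @export
crossConditionOverlaps <- function(systemA, systemB, setNames = NULL,
                                   percentRelativeTo = c("A", "B", "none")) {
    percentRelativeTo <- match.arg(percentRelativeTo)
    stopifnot(is(systemA, "SetSystem"), is(systemB, "SetSystem"))
    sa <- geneSets(systemA); sb <- geneSets(systemB)
    if (is.null(setNames)) setNames <- intersect(names(sa), names(sb))
    rows <- lapply(setNames, function(nm) {
        ov <- length(intersect(sa[[nm]], sb[[nm]]))
        r <- data.frame(set_name = nm, size_a = length(sa[[nm]]),
                        size_b = length(sb[[nm]]), overlap = ov,
                        stringsAsFactors = FALSE)
        if (percentRelativeTo != "none") {
            st <- overlapStats(sa[[nm]], sb[[nm]],
                               reference = percentRelativeTo)
            r$pct <- st$pct
        }
        r
    })
    do.call(rbind, rows)
}

#' Run the whole synthetic pipeline end to end
#'
#' Simulates a factorial experiment, runs the dependence analysis for both
#' treatments of the configured cell type, summarizes both conditions,
#' tabulates the treated/untreated overlaps and scores the recovered
#' categories against the simulated truth.  Optionally writes all tables
#' under \code{outdir}.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outdir optional output directory (created if missing).
#' @param lfcThreshold,alpha,gate regulation-call settings.
#' @param verbose log per-stage gene counts to stderr.
#' @return List with \code{sim}, \code{conditions} (per treatment: the
#'   \code{\link{callDependence}} result, its \code{summary} and its
#'   \code{recovery}), and \code{overlaps} (treated vs untreated).
#' @export
runPipeline <- function(config, outdir = NULL, lfcThreshold = 1,
                        alpha = 0.05, gate = "nominal",
                        verbose = interactive()) {
    log <- function(...) if (verbose) message(...)
    sim <- simulateExperiment(config)
    log("simulated ", nrow(sim$experiment), " genes x ",
        ncol(sim$experiment), " samples")
    conditions <- list()
    for (tr in .TREATMENTS) {
        res <- callDependence(sim$experiment, config@cellType, tr,
                              lfcThreshold = lfcThreshold, alpha = alpha,
                              gate = gate)
        res$summary <- summarizeCondition(res$system, alpha = alpha)
        calls <- data.frame(gene_id = res$categories$gene_id,
                            category = res$categories$category,
                            stringsAsFactors = FALSE)
        ## genes outside the tested universe count as 'none' calls
        missing <- setdiff(sim$truth$gene_id, calls$gene_id)
        if (length(missing))
            calls <- rbind(calls, data.frame(gene_id = missing,
                                             category = "none"))
        calls <- calls[!calls$gene_id %in%
                           sim$truth$gene_id[sim$truth$is_knockout_marker], ]
        res$recovery <- evaluateRecovery(sim$truth, calls)
        sz <- setSizes(res$system)
        log(config@cellType, ",", tr, ": universe ",
            length(setUniverse(res$system)), "; Set26 ", sz[["Set26"]],
            "; Set27 ", sz[["Set27"]])
        conditions[[tr]] <- res
    }
    overlaps <- crossConditionOverlaps(conditions$MSB$system,
                                       conditions$untreated$system,
                                       percentRelativeTo = "none")
    out <- list(sim = sim, conditions = conditions, overlaps = overlaps)
    if (!is.null(outdir)) .writePipeline(out, outdir)
    out
}

.writePipeline <- function(res, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(outdir, ...)
    writeCounts(SummarizedExperiment::assay(res$sim$experiment, "counts"),
                p("counts.tsv"))
    writeSampleSheet(as.data.frame(
        SummarizedExperiment::colData(res$sim$experiment)),
        p("sample_sheet.tsv"))
    utils::write.table(res$sim$truth, p("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeGeneLengths(res$sim$lengths, p("gene_lengths.tsv"))
    for (tr in names(res$conditions)) {
        cond <- res$conditions[[tr]]
        for (nm in names(cond$de))
            writeDEResult(cond$de[[nm]],
                          p(paste0("de_", tr, "_", nm, ".tsv")))
        writeSetSystem(cond$system, p(paste0("sets_", tr, ".tsv")),
                       p(paste0("set_sizes_", tr, ".json")))
        utils::write.table(as.data.frame(cond$categories),
                           p(paste0("categories_", tr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cond$recovery$perCategory,
                           p(paste0("recovery_", tr, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(res$overlaps, p("overlaps_msb_vs_untreated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(outdir)
}
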