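## Simplified negative-binomial differential expression for two-group
## comparisons of the factorial design: median-of-ratios normalization,
## pooled method-of-moments dispersion, NB log-link GLM fit by Fisher
## scoring, Wald tests referenced to a t distribution with residual df,
## and Benjamini-Hochberg adjustment within each comparison.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with positive
#' counts in every sample) of the ratio of the count to the gene's geometric
#' mean across samples.
#'
#' @param counts non-negative count matrix, genes in rows.
#' @return Positive numeric vector, one factor per sample.
#' @examples
#' computeSizeFactors(rbind(c(10, 20), c(100, 200)))
#' @export
computeSizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("no gene has positive counts in all samples; ",
             "filter samples or supply deeper data")
    lc <- log(counts[pos, , drop = FALSE])
    geo <- rowMeans(lc)
    sf <- apply(exp(lc - geo), 2L, stats::median)
    if (any(!is.finite(sf)) || any(sf <= 0))
        stop("size factor estimation failed (non-positive factor)")
    sf
}

#' Method-of-moments dispersion with a floor
#'
#' Pooled within-group variance v and grand mean m of the normalized counts
#' give alpha = max(floor, (v - m) / m^2) per gene.
#'
#' @param normCounts matrix of normalized counts, genes in rows.
#' @param groups group label per sample (at least 2 replicates per group).
#' @param floor lower bound for the dispersion.
#' @return Numeric vector of per-gene dispersions (>= \code{floor}).
#' @export
estimateDispersion <- function(normCounts, groups, floor = 1e-8) {
    normCounts <- as.matrix(normCounts)
    groups <- as.character(groups)
    if (length(groups) != ncol(normCounts))
        stop("groups must have one label per sample")
    tab <- table(groups)
    if (any(tab < 2))
        stop("each group needs >= 2 replicates")
    ss <- 0
    for (g in names(tab)) {
        sub <- normCounts[, groups == g, drop = FALSE]
        ss <- ss + rowSums((sub - rowMeans(sub))^2)
    }
    v <- ss / (length(groups) - length(tab))
    m <- rowMeans(normCounts)
    alpha <- ifelse(m > 0, (v - m) / m^2, floor)
    pmax(floor, alpha)
}

#' Declare a two-group comparison
#'
#' @param numerator,reference lists with elements \code{strain} and
#'   \code{treatment} describing group A (numerator) and group B (reference)
#'   of the ordered comparison "A vs B"; log2 fold changes use B as
#'   reference.
#' @param cellType cell type the comparison is restricted to.
#' @param batchAdjusted logical; include an additive batch term in the GLM.
#' @param label comparison label; a canonical one is built when omitted.
#' @return An object of class \code{"Comparison"} (a structured list).
#' @examples
#' comparison(list(strain = "atfA_del", treatment = "untreated"),
#'            list(strain = "control", treatment = "untreated"), "mycelium")
#' @export
comparison <- function(numerator, reference, cellType,
                       batchAdjusted = FALSE, label = NULL) {
    stopifnot(is.list(numerator), is.list(reference),
              all(c("strain", "treatment") %in% names(numerator)),
              all(c("strain", "treatment") %in% names(reference)))
    if (identical(numerator, reference))
        stop("numerator and reference groups must differ")
    if (!cellType %in% .CELL_TYPES)
        stop("unknown cell type: ", cellType)
    if (is.null(label)) {
        label <- if (numerator$treatment == reference$treatment)
            paste0(numerator$strain, "_vs_", reference$strain)
        else if (numerator$strain == reference$strain)
            paste0(numerator$treatment, "_vs_", reference$treatment, "_",
                   numerator$strain)
        else paste0(numerator$strain, ".", numerator$treatment, "_vs_",
                    reference$strain, ".", reference$treatment)
    }
    structure(list(numerator = numerator, reference = reference,
                   cellType = cellType, batchAdjusted = batchAdjusted,
                   label = label),
              class = "Comparison")
}

#' @export
print.Comparison <- function(x, ...) {
    cat("Comparison: ", x$label, " [", x$cellType,
        if (x$batchAdjusted) ", batch-adjusted" else "", "]\n", sep = "")
    invisible(x)
}

#' The five canonical strain comparisons of one condition
#'
#' Comparisons feeding Set1, Set2, Set3, Set11 and Set12: each deletion
#' strain against the control and the double mutant against each single
#' mutant, all within one (cell type, treatment) condition.
#'
#' @param cellType,treatment the condition.
#' @param batchAdjusted logical, include a batch term (the conidial scenario).
#' @return Named list of \code{\link{comparison}} objects keyed by their
#'   canonical labels.
#' @export
strainComparisons <- function(cellType, treatment, batchAdjusted = FALSE) {
    pairs <- list(c("atfA_del", "control"),
                  c("atfB_del", "control"),
                  c("double_del", "control"),
                  c("double_del", "atfB_del"),
                  c("double_del", "atfA_del"))
    out <- lapply(pairs, function(p)
        comparison(list(strain = p[1], treatment = treatment),
                   list(strain = p[2], treatment = treatment),
                   cellType = cellType, batchAdjusted = batchAdjusted))
    stats::setNames(out, vapply(out, `[[`, "", "label"))
}

#' The MSB vs untreated comparison within one strain
#'
#' @param strain strain label.
#' @param cellType cell type.
#' @param batchAdjusted logical.
#' @return A \code{\link{comparison}} with label
#'   \code{"MSB_vs_untreated_<strain>"}.
#' @export
msbComparison <- function(strain, cellType, batchAdjusted = FALSE) {
    comparison(list(strain = strain, treatment = "MSB"),
               list(strain = strain, treatment = "untreated"),
               cellType = cellType, batchAdjusted = batchAdjusted)
}

## Vectorized NB GLM fit with log link and fixed per-gene dispersion.
## y: G x n counts; X: n x p design; offset: length-n log size factors;
## alpha: length-G dispersions.  Returns coefficients, se of each
## coefficient, and a converged flag per gene.
.nbGlmFit <- function(y, X, offset, alpha, tol = 1e-8, maxit = 100L,
                      etaClamp = 30) {
    G <- nrow(y); n <- ncol(y); p <- ncol(X)
    off <- matrix(offset, nrow = G, ncol = n, byrow = TRUE)
    ## initialize: intercept at log of offset-corrected mean, rest 0
    beta <- matrix(0, G, p)
    beta[, 1] <- log(pmax(rowMeans(y / exp(off)), 1e-3))
    ## precompute cross products of design columns
    XX <- matrix(0, n, p * p)
    for (j in seq_len(p)) for (k in seq_len(p))
        XX[, (j - 1) * p + k] <- X[, j] * X[, k]
    converged <- rep(FALSE, G)
    for (it in seq_len(maxit)) {
        eta <- beta %*% t(X) + off
        eta <- pmin(pmax(eta, -etaClamp), etaClamp)
        mu <- exp(eta)
        w <- mu / (1 + alpha * mu)
        z <- eta - off + (y - mu) / mu
        A <- w %*% XX                 # G x p^2, rows are vec(X'WX)
        B <- (w * z) %*% X            # G x p, rows are X'Wz
        newbeta <- .solveBatch(A, B, p)
        bad <- !is.finite(rowSums(newbeta))
        if (any(bad)) newbeta[bad, ] <- beta[bad, , drop = FALSE]
        delta <- abs(newbeta - beta)
        step <- apply(delta, 1L, max)
        conv <- is.finite(step) & step < tol
        beta <- newbeta
        converged <- converged | conv
        if (all(converged)) break
    }
    eta <- pmin(pmax(beta %*% t(X) + off, -etaClamp), etaClamp)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    A <- w %*% XX
    se <- .seBatch(A, p)
    bad <- !is.finite(rowSums(se)) | !is.finite(rowSums(beta))
    converged[bad] <- FALSE
    list(beta = beta, se = se, converged = converged, mu = mu)
}

## Solve the G per-gene p x p systems A_g x = b_g (A row-vectorized).
.solveBatch <- function(A, B, p) {
    G <- nrow(A)
    if (p == 1L) return(B / A)
    if (p == 2L) {
        a <- A[, 1]; b <- A[, 2]; d <- A[, 4]
        det <- a * d - b * b
        cbind((d * B[, 1] - b * B[, 2]) / det,
              (a * B[, 2] - b * B[, 1]) / det)
    } else if (p == 3L) {
        a11 <- A[, 1]; a12 <- A[, 2]; a13 <- A[, 3]
        a22 <- A[, 5]; a23 <- A[, 6]; a33 <- A[, 9]
        c11 <- a22 * a33 - a23 * a23
        c12 <- a13 * a23 - a12 * a33
        c13 <- a12 * a23 - a13 * a22
        c22 <- a11 * a33 - a13 * a13
        c23 <- a12 * a13 - a11 * a23
        c33 <- a11 * a22 - a12 * a12
        det <- a11 * c11 + a12 * c12 + a13 * c13
        cbind((c11 * B[, 1] + c12 * B[, 2] + c13 * B[, 3]) / det,
              (c12 * B[, 1] + c22 * B[, 2] + c23 * B[, 3]) / det,
              (c13 * B[, 1] + c23 * B[, 2] + c33 * B[, 3]) / det)
    } else {
        out <- matrix(NA_real_, G, p)
        for (g in seq_len(G)) {
            Ag <- matrix(A[g, ], p, p)
            out[g, ] <- tryCatch(solve(Ag, B[g, ]),
                                 error = function(e) rep(NA_real_, p))
        }
        out
    }
}

## Standard errors: sqrt of the diagonal of (X'WX)^{-1}, per gene.
.seBatch <- function(A, p) {
    G <- nrow(A)
    if (p == 1L) return(matrix(sqrt(1 / A), G, 1))
    if (p == 2L) {
        a <- A[, 1]; b <- A[, 2]; d <- A[, 4]
        det <- a * d - b * b
        cbind(sqrt(d / det), sqrt(a / det))
    } else if (p == 3L) {
        a11 <- A[, 1]; a12 <- A[, 2]; a13 <- A[, 3]
        a22 <- A[, 5]; a23 <- A[, 6]; a33 <- A[, 9]
        c11 <- a22 * a33 - a23 * a23
        c22 <- a11 * a33 - a13 * a13
        c33 <- a11 * a22 - a12 * a12
        det <- a11 * c11 + a12 * (a13 * a23 - a12 * a33) +
            a13 * (a12 * a23 - a13 * a22)
        cbind(sqrt(c11 / det), sqrt(c22 / det), sqrt(c33 / det))
    } else {
        out <- matrix(NA_real_, G, p)
        for (g in seq_len(G)) {
            Ag <- matrix(A[g, ], p, p)
            d <- tryCatch(diag(solve(Ag)), error = function(e) rep(NA_real_, p))
            out[g, ] <- sqrt(d)
        }
        out
    }
}

#' Negative-binomial Wald test for one comparison
#'
#' Subsets the experiment to the two groups of the comparison, normalizes by
#' median-of-ratios size factors, estimates per-gene dispersions by pooled
#' method of moments, fits an NB log-link GLM (intercept + group, plus batch
#' indicators when \code{batchAdjusted}), and tests the group coefficient
#' with a Wald statistic referenced to a t distribution with residual
#' degrees of freedom (a small-sample calibration; see the package
#' vignette).  p-values are BH-adjusted across tested genes within the
#' comparison.
#'
#' @param x a \linkS4class{FactorialCounts} object.
#' @param cmp a \code{\link{comparison}}.
#' @param alpha nominal significance level stored with the result (used by
#'   \code{\link{classifyRegulated}}).
#' @param dispersionFloor lower bound for the dispersion estimate.
#' @param dispersion optional named per-gene dispersion vector (e.g. from
#'   \code{\link{conditionDispersion}}, which pools over all strains of a
#'   condition); when omitted, dispersions are estimated from the two
#'   groups of the comparison.
#' @param dispersionDf degrees of freedom behind \code{dispersion}; sets
#'   the df of the t reference for the Wald statistic.  Defaults to the
#'   residual df of the fit.
#' @return \code{DataFrame} with columns \code{gene_id}, \code{base_mean},
#'   \code{log2fc}, \code{se}, \code{stat}, \code{p}, \code{padj} and
#'   \code{status} (\code{tested}, \code{not_tested} for all-zero genes,
#'   \code{not_converged}); comparison label, residual df and \code{alpha}
#'   in \code{metadata()}.
#' @export
deTest <- function(x, cmp, alpha = 0.05, dispersionFloor = 1e-8,
                   dispersion = NULL, dispersionDf = NULL) {
    stopifnot(is(x, "FactorialCounts"), inherits(cmp, "Comparison"))
    cd <- SummarizedExperiment::colData(x)
    inGroup <- function(g)
        cd$strain == g$strain & cd$treatment == g$treatment &
        cd$cell_type == cmp$cellType
    selA <- inGroup(cmp$numerator)
    selB <- inGroup(cmp$reference)
    if (!any(selA))
        stop("no samples for numerator group of ", cmp$label,
             " in cell type ", cmp$cellType)
    if (!any(selB))
        stop("no samples for reference group of ", cmp$label,
             " in cell type ", cmp$cellType)
    if (sum(selA) < 2 || sum(selB) < 2)
        stop("both groups of ", cmp$label, " need >= 2 replicates")
    sel <- selA | selB
    y <- SummarizedExperiment::assay(x, "counts")[, sel, drop = FALSE]
    grp <- ifelse(selA[sel], "A", "B")
    batch <- as.character(cd$batch[sel])
    sf <- computeSizeFactors(y)
    norm <- sweep(y, 2L, sf, "/")
    tested <- unname(rowSums(y) > 0)
    if (is.null(dispersion)) {
        disp <- estimateDispersion(norm[tested, , drop = FALSE], grp,
                                   floor = dispersionFloor)
    } else {
        miss <- setdiff(rownames(y)[tested], names(dispersion))
        if (length(miss))
            stop("dispersion missing for gene(s): ",
                 paste(utils::head(miss, 5), collapse = ", "))
        disp <- pmax(unname(dispersion[rownames(y)[tested]]),
                     dispersionFloor)
    }
    if (cmp$batchAdjusted) {
        if (length(unique(batch)) < 2)
            stop("batch adjustment requested for ", cmp$label,
                 " but fewer than 2 batches are present")
        X <- stats::model.matrix(~ factor(batch) + factor(grp, c("B", "A")))
    } else {
        X <- stats::model.matrix(~ factor(grp, c("B", "A")))
    }
    groupCol <- ncol(X)              # the group coefficient is last
    fit <- .nbGlmFit(y[tested, , drop = FALSE], X, log(sf), disp)
    df <- if (!is.null(dispersionDf)) dispersionDf
          else if (!is.null(attr(dispersion, "df"))) attr(dispersion, "df")
          else nrow(X) - ncol(X)
    G <- nrow(y)
    out <- S4Vectors::DataFrame(
        gene_id = rownames(y),
        base_mean = unname(rowMeans(norm)),
        log2fc = NA_real_, se = NA_real_, stat = NA_real_,
        p = NA_real_, padj = NA_real_,
        status = ifelse(tested, "tested", "not_tested"))
    lfc <- fit$beta[, groupCol] / log(2)
    se <- fit$se[, groupCol] / log(2)
    stat <- fit$beta[, groupCol] / fit$se[, groupCol]
    p <- 2 * stats::pt(-abs(stat), df = df)
    st <- out$status[tested]
    st[!fit$converged] <- "not_converged"
    out$log2fc[tested] <- lfc
    out$se[tested] <- se
    out$stat[tested] <- stat
    out$p[tested] <- p
    out$status[tested] <- st
    ok <- out$status == "tested"
    out$padj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
    S4Vectors::metadata(out) <- list(comparison = cmp$label, df = df,
                                     alpha = alpha,
                                     cellType = cmp$cellType,
                                     batchAdjusted = cmp$batchAdjusted)
    out
}

#' Pooled dispersion for one condition
#'
#' Method-of-moments dispersion estimated once from all four strains of a
#' (cell type, treatment) condition (groups = strains), rather than from
#' the two groups of a single comparison.  The extra replication roughly
#' doubles the degrees of freedom behind the estimate; the returned vector
#' carries them as \code{attr(, "df")} and \code{\link{deTest}} uses them
#' for its t reference.
#'
#' @param x a \linkS4class{FactorialCounts}.
#' @param cellType,treatment the condition.
#' @param floor dispersion floor.
#' @return Named per-gene dispersion vector with a \code{"df"} attribute.
#' @export
conditionDispersion <- function(x, cellType, treatment, floor = 1e-8) {
    stopifnot(is(x, "FactorialCounts"))
    cd <- SummarizedExperiment::colData(x)
    sel <- cd$cell_type == cellType & cd$treatment == treatment
    if (!any(sel)) stop("no samples for condition ", cellType, ",", treatment)
    y <- SummarizedExperiment::assay(x, "counts")[, sel, drop = FALSE]
    grp <- as.character(cd$strain[sel])
    sf <- computeSizeFactors(y)
    norm <- sweep(y, 2L, sf, "/")
    disp <- estimateDispersion(norm, grp, floor = floor)
    names(disp) <- rownames(y)
    attr(disp, "df") <- ncol(y) - length(unique(grp))
    disp
}

#' Convert differential-expression results into regulation calls
#'
#' A gene is called \code{up} if log2FC > \code{lfcThreshold} and \code{down}
#' if log2FC < -\code{lfcThreshold} (strict inequalities), gated by the
#' chosen significance rule; everything else (including genes not tested or
#' not converged) is \code{none}.
#'
#' @param de a \code{DataFrame} from \code{\link{deTest}}.
#' @param lfcThreshold positive log2 fold-change threshold.
#' @param alpha significance cutoff for the gate.
#' @param gate significance gate applied on top of the fold-change rule:
#'   \code{"nominal"} (default) requires one-sided nominal evidence in the
#'   call's direction (one-sided t p-value < \code{alpha}), suppressing
#'   spurious fold changes of near-zero-count genes without the
#'   multiplicity penalty that masks strong effects in small-replicate
#'   designs; \code{"adjusted"} requires the two-sided BH-adjusted
#'   \code{padj < alpha}; \code{"none"} applies the literal
#'   fold-change-only rule.  A logical is accepted for convenience
#'   (\code{TRUE} = \code{"adjusted"}, \code{FALSE} = \code{"none"}).
#' @return \code{data.frame} with columns \code{gene_id}, \code{log2fc},
#'   \code{padj}, \code{status}, \code{call}.
#' @export
classifyRegulated <- function(de, lfcThreshold = 1, alpha = 0.05,
                              gate = c("nominal", "adjusted", "none")) {
    stopifnot(lfcThreshold > 0)
    if (is.logical(gate)) gate <- if (gate) "adjusted" else "none"
    gate <- match.arg(gate)
    ok <- de$status == "tested"
    if (gate == "nominal") {
        df <- S4Vectors::metadata(de)$df
        if (is.null(df))
            stop("nominal gate needs the t df in metadata(de)$df")
        pDown <- stats::pt(de$stat, df = df)
        sigDown <- ok & !is.na(pDown) & pDown < alpha
        sigUp <- ok & !is.na(pDown) & (1 - pDown) < alpha
    } else if (gate == "adjusted") {
        sig <- ok & !is.na(de$padj) & de$padj < alpha
        sigDown <- sigUp <- sig
    } else {
        sigDown <- sigUp <- ok
    }
    call <- rep("none", nrow(de))
    call[sigUp & de$log2fc > lfcThreshold] <- "up"
    call[sigDown & de$log2fc < -lfcThreshold] <- "down"
    data.frame(gene_id = de$gene_id, log2fc = de$log2fc, padj = de$padj,
               status = de$status, call = call, stringsAsFactors = FALSE)
}
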