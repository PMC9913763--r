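## Gene-group enrichment by the one-sided Fisher (hypergeometric tail)
## test, MSB-responsiveness cross-tabulation of the dependent sets, and
## simple overlap statistics.

.hyperP <- function(overlap, groupSize, querySize, universeSize) {
    ## P(X >= overlap), X ~ Hypergeometric(universeSize, groupSize, querySize)
    stats::phyper(overlap - 1, groupSize, universeSize - groupSize,
                  querySize, lower.tail = FALSE)
}

#' Fisher's exact enrichment of gene groups in a query set
#'
#' One-sided (enrichment) Fisher test per group: the p-value is the
#' hypergeometric tail P(X >= overlap) for drawing \code{querySize} genes
#' from a universe containing \code{groupSize} group members.  BH
#' adjustment is applied across the supplied groups.
#'
#' @param query character vector of gene IDs (must lie in the universe).
#' @param groups named list of gene-ID vectors (e.g. from
#'   \code{\link{readGMT}}); each group is intersected with the universe.
#' @param universe character vector of background gene IDs.
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"}.
#' @return data.frame with columns \code{group_name}, \code{overlap},
#'   \code{query_size}, \code{group_size}, \code{universe_size},
#'   \code{odds_ratio}, \code{p}, \code{padj}, ordered as supplied.
#' @examples
#' fisherEnrichment(paste0("g", 1:5),
#'                  list(grp = paste0("g", 1:4)), paste0("g", 1:20))
#' @export
fisherEnrichment <- function(query, groups, universe,
                             alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    query <- unique(as.character(query))
    if (!length(query)) stop("empty query set")
    out <- setdiff(query, universe)
    if (length(out))
        stop("query gene(s) outside the universe: ",
             paste(utils::head(out, 5), collapse = ", "))
    N <- length(universe); n <- length(query)
    rows <- lapply(names(groups), function(nm) {
        grp <- intersect(unique(as.character(groups[[nm]])), universe)
        K <- length(grp)
        k <- length(intersect(query, grp))
        p <- if (alternative == "greater") .hyperP(k, K, n, N)
        else stats::fisher.test(
            matrix(c(k, K - k, n - k, N - K - n + k), 2L),
            alternative = "two.sided")$p.value
        ## sample odds ratio of the 2x2 table
        a <- k; b <- K - k; c <- n - k; d <- N - K - n + k
        or <- if (b * c == 0) Inf else (a * d) / (b * c)
        data.frame(group_name = nm, overlap = k, query_size = n,
                   group_size = K, universe_size = N, odds_ratio = or,
                   p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res
}

#' Cross-tabulate a dependent set with the MSB stress-responsive sets
#'
#' Reports how many genes of a dependent set (Set26 or Set27) are MSB
#' stress-responsive upregulated (Set0+) or downregulated (Set0), each with
#' a one-sided Fisher enrichment p-value over the condition's universe.
#'
#' @param dependent character vector of gene IDs (e.g. Set26).
#' @param set0 downregulated MSB stress-responsive genes.
#' @param set0plus upregulated MSB stress-responsive genes.
#' @param universe background gene IDs.
#' @param alpha significance level for the enrichment flags.
#' @return data.frame with one row per direction (\code{up}, \code{down}):
#'   overlap, set sizes, Fisher p and an \code{enriched} flag.
#' @export
msbCrosstab <- function(dependent, set0, set0plus, universe, alpha = 0.05) {
    universe <- unique(as.character(universe))
    dependent <- intersect(unique(dependent), universe)
    row1 <- function(direction, msbSet) {
        msbSet <- intersect(unique(msbSet), universe)
        k <- length(intersect(dependent, msbSet))
        p <- .hyperP(k, length(msbSet), length(dependent), length(universe))
        data.frame(direction = direction, overlap = k,
                   dependent_size = length(dependent),
                   msb_size = length(msbSet),
                   universe_size = length(universe), p = p,
                   enriched = p < alpha, stringsAsFactors = FALSE)
    }
    rbind(row1("up", set0plus), row1("down", set0))
}

#' Overlap between two gene sets with a reference percentage
#'
#' @param setA,setB character vectors of gene IDs.
#' @param reference which set the percentage is computed relative to:
#'   \code{"A"} or \code{"B"}.
#' @return List with \code{n_overlap} and \code{pct} (integer percent,
#'   rounded half-up; NA when the reference set is empty).
#' @examples
#' overlapStats(letters[1:4], letters[3:6], reference = "A")
#' @export
overlapStats <- function(setA, setB, reference = c("A", "B")) {
    reference <- match.arg(reference)
    setA <- unique(setA); setB <- unique(setB)
    n <- length(intersect(setA, setB))
    ref <- if (reference == "A") length(setA) else length(setB)
    pct <- if (ref == 0) NA_real_ else floor(100 * n / ref + 0.5)
    list(n_overlap = n, pct = pct)
}
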