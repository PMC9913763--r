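## The core set algebra: from up/down regulation calls of five strain
## comparisons to the 27 named gene sets and the per-gene dependence category.
##
## Primary membership is a 5-bit pattern (s1, s2, s3, s11, s12): is the gene
## downregulated in
##   s1:  atfA_del    vs control
##   s2:  atfB_del    vs control
##   s3:  double_del  vs control
##   s11: double_del  vs atfB_del
##   s12: double_del  vs atfA_del
## Set13 is definitionally Set3.  The "+" mirror system applies the identical
## algebra to the upregulation calls.

.PRIMARY_COMPARISONS <- c(
    Set1  = "atfA_del_vs_control",
    Set2  = "atfB_del_vs_control",
    Set3  = "double_del_vs_control",
    Set11 = "double_del_vs_atfB_del",
    Set12 = "double_del_vs_atfA_del")

.MSB_CONTROL_COMPARISON <- "MSB_vs_untreated_control"

## Decision table: unique 5-bit down-membership pattern of each category.
.CATEGORY_BITS <- rbind(
    "AA"   = c(1, 0, 1, 1, 0),
    "BB"   = c(0, 1, 1, 0, 1),
    "AB"   = c(1, 1, 1, 0, 0),
    "A/B"  = c(0, 0, 1, 1, 1),
    "A-B1" = c(1, 1, 1, 1, 1),
    "A-B2" = c(1, 0, 1, 1, 1),
    "A-B3" = c(0, 1, 1, 1, 1),
    "A-B4" = c(1, 1, 1, 1, 0),
    "A-B5" = c(1, 1, 1, 0, 1))
colnames(.CATEGORY_BITS) <- c("s1", "s2", "s3", "s11", "s12")
storage.mode(.CATEGORY_BITS) <- "integer"

#' Canonical membership pattern and strain means of a dependence category
#'
#' For each of the nine categories, returns the 5-bit down-membership pattern
#' its defining set formula forces, together with a relative strain-mean
#' pattern (levels \code{high}, \code{mid}, \code{low}; the control strain is
#' always \code{high}) that reproduces exactly that pattern under the
#' |log2FC| > 1 rule when the multipliers are separated by more than 2-fold.
#'
#' @param category one of \code{dependenceCategories()}.
#' @return List with \code{bits} (named 0/1 vector over s1, s2, s3, s11, s12)
#'   and \code{multipliers} (named character over the four strains).
#' @examples
#' canonicalPattern("AA")
#' @export
canonicalPattern <- function(category) {
    if (length(category) != 1L || !category %in% .CATEGORIES)
        stop("unknown dependence category: ", category)
    mult <- switch(category,
        "AA"   = c(control = "high", atfA_del = "low",  atfB_del = "high",
                   double_del = "low"),
        "BB"   = c(control = "high", atfA_del = "high", atfB_del = "low",
                   double_del = "low"),
        "AB"   = c(control = "high", atfA_del = "low",  atfB_del = "low",
                   double_del = "low"),
        "A/B"  = c(control = "high", atfA_del = "high", atfB_del = "high",
                   double_del = "low"),
        "A-B1" = c(control = "high", atfA_del = "mid",  atfB_del = "mid",
                   double_del = "low"),
        "A-B2" = c(control = "high", atfA_del = "mid",  atfB_del = "high",
                   double_del = "low"),
        "A-B3" = c(control = "high", atfA_del = "high", atfB_del = "mid",
                   double_del = "low"),
        "A-B4" = c(control = "high", atfA_del = "low",  atfB_del = "mid",
                   double_del = "low"),
        "A-B5" = c(control = "high", atfA_del = "mid",  atfB_del = "low",
                   double_del = "low"))
    list(bits = .CATEGORY_BITS[category, ], multipliers = mult)
}

#' Assign dependence categories from 5-bit membership patterns
#'
#' Maps each pattern of down-set memberships (s1, s2, s3, s11, s12) to the
#' unique category whose defining formula it satisfies, or \code{"none"}.
#' Exactly 9 of the 32 possible patterns receive a category.
#'
#' @param bits matrix or data.frame with columns \code{s1, s2, s3, s11, s12}
#'   of 0/1 (or logical) flags, one row per gene.
#' @return Character vector of categories (\code{"none"} where no formula
#'   matches), named by rownames of \code{bits} when present.
#' @examples
#' assignCategory(rbind(c(1, 0, 1, 1, 0), c(0, 0, 0, 0, 0)))
#' @export
assignCategory <- function(bits) {
    bits <- as.matrix(bits)
    if (ncol(bits) != 5L)
        stop("bits must have five columns: s1, s2, s3, s11, s12")
    if (!is.null(colnames(bits)) &&
        all(colnames(.CATEGORY_BITS) %in% colnames(bits)))
        bits <- bits[, colnames(.CATEGORY_BITS), drop = FALSE]
    storage.mode(bits) <- "integer"
    if (any(is.na(bits)) || any(bits != 0L & bits != 1L))
        stop("membership bits must be 0/1")
    key <- apply(bits, 1L, paste, collapse = "")
    tab <- stats::setNames(rownames(.CATEGORY_BITS),
                           apply(.CATEGORY_BITS, 1L, paste, collapse = ""))
    out <- unname(tab[key])
    out[is.na(out)] <- "none"
    names(out) <- rownames(bits)
    out
}

#' Build the primary gene sets of one condition
#'
#' Converts regulation calls of the five strain comparisons (and optionally
#' the control-strain MSB comparison) into the primary sets Set1, Set2, Set3,
#' Set11, Set12 (downregulated) and their "+" mirrors (upregulated), plus
#' Set0/Set0+ when the MSB comparison is supplied.
#'
#' @param regulation named list of regulation tables (as returned by
#'   \code{\link{classifyRegulated}}); required names are
#'   \code{atfA_del_vs_control}, \code{atfB_del_vs_control},
#'   \code{double_del_vs_control}, \code{double_del_vs_atfB_del},
#'   \code{double_del_vs_atfA_del}; optional \code{MSB_vs_untreated_control}.
#' @param condition condition label stored in the result.
#' @param universe gene universe; by default the genes with status
#'   \code{"tested"} in every supplied comparison.  Genes outside the
#'   universe are excluded from all sets.
#' @return A \linkS4class{SetSystem} with the primary sets.
#' @export
buildPrimarySets <- function(regulation, condition = "",
                             universe = NULL) {
    need <- .PRIMARY_COMPARISONS
    miss <- setdiff(need, names(regulation))
    if (length(miss))
        stop("missing regulation calls for comparison(s): ",
             paste(miss, collapse = ", "))
    used <- regulation[intersect(c(need, .MSB_CONTROL_COMPARISON),
                                 names(regulation))]
    for (nm in names(used)) {
        r <- used[[nm]]
        if (!all(c("gene_id", "call") %in% colnames(r)))
            stop("regulation table '", nm,
                 "' lacks gene_id and call columns")
    }
    if (is.null(universe)) {
        tested <- lapply(used, function(r) {
            if ("status" %in% colnames(r))
                r$gene_id[r$status == "tested"]
            else r$gene_id
        })
        universe <- Reduce(intersect, tested)
    }
    universe <- as.character(universe)
    sets <- list()
    pick <- function(r, what)
        intersect(r$gene_id[r$call == what], universe)
    for (i in seq_along(need)) {
        r <- regulation[[need[i]]]
        nm <- names(need)[i]
        sets[[nm]] <- pick(r, "down")
        sets[[paste0(nm, "+")]] <- pick(r, "up")
    }
    if (.MSB_CONTROL_COMPARISON %in% names(regulation)) {
        r <- regulation[[.MSB_CONTROL_COMPARISON]]
        sets[["Set0"]]  <- pick(r, "down")
        sets[["Set0+"]] <- pick(r, "up")
    }
    new("SetSystem", sets = sets, condition = condition, universe = universe)
}

#' Build a SetSystem directly from membership bits
#'
#' Constructs the primary down-sets of a condition from an explicit table of
#' 5-bit membership patterns, one row per gene.  Useful for worked examples
#' and for replaying published per-category breakdowns through the algebra.
#'
#' @param membership data.frame with a \code{gene_id} column and 0/1 columns
#'   \code{s1, s2, s3, s11, s12}.
#' @param condition condition label.
#' @return A \linkS4class{SetSystem} with Set1, Set2, Set3, Set11, Set12 and
#'   empty "+" mirrors.
#' @examples
#' m <- data.frame(gene_id = "g1", s1 = 1, s2 = 0, s3 = 1, s11 = 1, s12 = 0)
#' deriveSets(setSystemFromMembership(m))
#' @export
setSystemFromMembership <- function(membership, condition = "") {
    cols <- c("s1", "s2", "s3", "s11", "s12")
    if (!all(c("gene_id", cols) %in% colnames(membership)))
        stop("membership needs columns gene_id, ", paste(cols, collapse = ", "))
    if (anyDuplicated(membership$gene_id))
        stop("duplicate gene IDs in membership table")
    ids <- as.character(membership$gene_id)
    sets <- list()
    map <- c(s1 = "Set1", s2 = "Set2", s3 = "Set3", s11 = "Set11",
             s12 = "Set12")
    for (cl in cols) {
        sets[[map[[cl]]]] <- ids[membership[[cl]] == 1]
        sets[[paste0(map[[cl]], "+")]] <- character()
    }
    new("SetSystem", sets = sets, condition = condition, universe = ids)
}

## Evaluate the derived-set formulas over one polarity ("" = down, "+" = up).
.deriveOne <- function(sets, suffix) {
    g <- function(nm) sets[[paste0(nm, suffix)]]
    s1 <- g("Set1"); s2 <- g("Set2"); s3 <- g("Set3")
    s11 <- g("Set11"); s12 <- g("Set12")
    out <- list()
    out[[paste0("Set4",  suffix)]] <- setdiff(s1, union(s2, s3))
    out[[paste0("Set5",  suffix)]] <- setdiff(s2, union(s1, s3))
    out[[paste0("Set6",  suffix)]] <- setdiff(s3, union(s1, s2))
    out[[paste0("Set7",  suffix)]] <- setdiff(intersect(s1, s2), s3)
    out[[paste0("Set8",  suffix)]] <- setdiff(intersect(s1, s3), s2)
    out[[paste0("Set9",  suffix)]] <- setdiff(intersect(s2, s3), s1)
    out[[paste0("Set10", suffix)]] <- intersect(intersect(s1, s2), s3)
    s13 <- s3                       # Set13 = Set3 by definition
    out[[paste0("Set13", suffix)]] <- s13
    out[[paste0("Set14", suffix)]] <- setdiff(s11, union(s12, s13))
    out[[paste0("Set15", suffix)]] <- setdiff(s12, union(s11, s13))
    out[[paste0("Set16", suffix)]] <- setdiff(s13, union(s11, s12))
    out[[paste0("Set17", suffix)]] <- setdiff(intersect(s11, s12), s13)
    out[[paste0("Set18", suffix)]] <- setdiff(intersect(s11, s13), s12)
    out[[paste0("Set19", suffix)]] <- setdiff(intersect(s12, s13), s11)
    out[[paste0("Set20", suffix)]] <- intersect(intersect(s11, s12), s13)
    out
}

.dependOne <- function(sets, suffix) {
    g <- function(nm) sets[[paste0(nm, suffix)]]
    out <- list()
    out[[paste0("Set21", suffix)]] <- intersect(g("Set8"),  g("Set18"))
    out[[paste0("Set22", suffix)]] <- intersect(g("Set9"),  g("Set19"))
    out[[paste0("Set23", suffix)]] <- intersect(g("Set10"), g("Set16"))
    out[[paste0("Set24", suffix)]] <- intersect(g("Set20"), g("Set6"))
    ## the five A-B sub-sets, in the printed order of the Set25 union terms
    ab <- list(intersect(g("Set10"), g("Set20")),
               intersect(g("Set8"),  g("Set20")),
               intersect(g("Set9"),  g("Set20")),
               intersect(g("Set18"), g("Set10")),
               intersect(g("Set19"), g("Set10")))
    names(ab) <- paste0("A-B", 1:5, suffix)
    out <- c(out, ab)
    out[[paste0("Set25", suffix)]] <- Reduce(union, ab)
    out[[paste0("Set26", suffix)]] <-
        Reduce(union, list(out[[paste0("Set21", suffix)]],
                           out[[paste0("Set23", suffix)]],
                           out[[paste0("Set24", suffix)]],
                           out[[paste0("Set25", suffix)]]))
    out[[paste0("Set27", suffix)]] <-
        Reduce(union, list(out[[paste0("Set22", suffix)]],
                           out[[paste0("Set23", suffix)]],
                           out[[paste0("Set24", suffix)]],
                           out[[paste0("Set25", suffix)]]))
    out
}

#' Derive the composite gene sets from the primary sets
#'
#' Evaluates the literal formulas Set4 = Set1 \\ (Set2 u Set3) ... Set20 =
#' Set11 n Set12 n Set13 (with Set13 = Set3) over the down sets, and the
#' same formulas over the "+" mirrors when present.
#'
#' @param system a \linkS4class{SetSystem} containing the primary sets.
#' @return The \code{SetSystem} extended with Set4..Set10 and Set13..Set20
#'   (and mirrors).
#' @export
deriveSets <- function(system) {
    stopifnot(is(system, "SetSystem"))
    sets <- geneSets(system)
    need <- names(.PRIMARY_COMPARISONS)
    miss <- setdiff(need, names(sets))
    if (length(miss))
        stop("primary set(s) missing: ", paste(miss, collapse = ", "))
    sets <- c(sets, .deriveOne(sets, ""))
    if (all(paste0(need, "+") %in% names(sets)))
        sets <- c(sets, .deriveOne(sets, "+"))
    initialize(system, sets = sets)
}

#' Dependence sets and per-gene category labels
#'
#' Computes Set21..Set25 (the category sets), the five A-B sub-sets, and the
#' unions Set26 (AtfA-dependent) and Set27 (AtfB-dependent), for the down
#' system and, when present, the "+" mirror system.  Each gene in the
#' universe receives at most one category per polarity.
#'
#' @param system a \linkS4class{SetSystem} from \code{\link{deriveSets}}.
#' @return List with \code{system} (the extended \code{SetSystem}) and
#'   \code{categories}, a \code{DataFrame} with columns \code{gene_id},
#'   \code{category} (down system) and, when mirrors exist,
#'   \code{category_up}.
#' @export
dependentSets <- function(system) {
    stopifnot(is(system, "SetSystem"))
    sets <- geneSets(system)
    need <- c("Set6", "Set8", "Set9", "Set10", "Set16", "Set18", "Set19",
              "Set20")
    if (!all(need %in% names(sets)))
        stop("derived sets missing; run deriveSets() first")
    sets <- c(sets, .dependOne(sets, ""))
    hasUp <- all(paste0(need, "+") %in% names(sets))
    if (hasUp)
        sets <- c(sets, .dependOne(sets, "+"))
    system <- initialize(system, sets = sets)
    .checkPartition(system, "")
    if (hasUp) .checkPartition(system, "+")
    lab <- function(suffix) {
        v <- stats::setNames(rep("none", length(system@universe)),
                             system@universe)
        for (cat in .CATEGORIES) {
            nm <- switch(cat, "AA" = "Set21", "BB" = "Set22", "AB" = "Set23",
                         "A/B" = "Set24", paste0(cat))  # A-B1..5 stored as is
            v[sets[[paste0(nm, suffix)]]] <- cat
        }
        unname(v)
    }
    categories <- S4Vectors::DataFrame(gene_id = system@universe,
                                       category = lab(""))
    if (hasUp) categories$category_up <- lab("+")
    list(system = system, categories = categories)
}

## Internal invariant check: Set21..Set25 pairwise disjoint, Set26/Set27 are
## the stated unions, and A-B1..A-B5 partition Set25.
.checkPartition <- function(system, suffix) {
    s <- geneSets(system)
    g <- function(nm) s[[paste0(nm, suffix)]]
    cats <- lapply(paste0("Set", 21:25), g)
    n <- sum(lengths(cats))
    if (length(Reduce(union, cats)) != n)
        stop("internal error: Set21..Set25", suffix, " are not disjoint")
    if (length(g("Set26")) != length(g("Set21")) + length(g("Set23")) +
        length(g("Set24")) + length(g("Set25")))
        stop("internal error: Set26", suffix, " is not the disjoint union ",
             "of Set21, Set23, Set24, Set25")
    if (length(g("Set27")) != length(g("Set22")) + length(g("Set23")) +
        length(g("Set24")) + length(g("Set25")))
        stop("internal error: Set27", suffix, " partition violated")
    ab <- lapply(paste0("A-B", 1:5), g)
    if (sum(lengths(ab)) != length(g("Set25")) ||
        !setequal(Reduce(union, ab), g("Set25")))
        stop("internal error: A-B1..A-B5", suffix,
             " do not partition Set25", suffix)
    invisible(TRUE)
}

#' MSB stress-responsive genes
#'
#' Union of genes regulated in the MSB vs untreated comparison, either of the
#' control strain only or of any strain, per polarity.
#'
#' @param regulation named list of regulation tables for the per-strain MSB
#'   comparisons; names are strain labels.
#' @param strains \code{"control"} or \code{"any"}.
#' @param direction \code{"down"}, \code{"up"} or \code{"both"}.
#' @return Character vector of gene IDs.
#' @export
msbResponsive <- function(regulation, strains = c("any", "control"),
                          direction = c("both", "down", "up")) {
    strains <- match.arg(strains)
    direction <- match.arg(direction)
    use <- if (strains == "control") "control" else names(regulation)
    miss <- setdiff(use, names(regulation))
    if (length(miss))
        stop("missing MSB regulation calls for strain(s): ",
             paste(miss, collapse = ", "))
    want <- switch(direction, both = c("up", "down"), down = "down",
                   up = "up")
    out <- character()
    for (nm in use) {
        r <- regulation[[nm]]
        out <- union(out, r$gene_id[r$call %in% want])
    }
    out
}
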