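# The set algebra: primary sets, derived-set formulas, category assignment.

test_that("derived sets follow the literal formulas on hand-built inputs", {
    m <- data.frame(
        gene_id = paste0("g", 1:5),
        s1 = c(1, 0, 1, 1, 0),   # Set1 = {g1,g3,g4}
        s2 = c(0, 1, 1, 1, 0),   # Set2 = {g2,g3,g4}
        s3 = c(0, 0, 1, 1, 1),   # Set3 = {g3,g4,g5}
        s11 = c(0, 0, 0, 1, 0),  # Set11 = {g4}
        s12 = c(0, 0, 0, 1, 0))  # Set12 = {g4}
    sys <- deriveSets(setSystemFromMembership(m))
    s <- geneSets(sys)
    expect_setequal(s$Set4, "g1")
    expect_setequal(s$Set5, "g2")
    expect_setequal(s$Set6, "g5")
    expect_setequal(s$Set10, c("g3", "g4"))
    expect_identical(sort(s$Set13), sort(s$Set3))
    expect_setequal(s$Set16, c("g3", "g5"))
    expect_setequal(s$Set20, "g4")
    expect_length(s$Set7, 0)
})

test_that("assignCategory matches brute-force formula evaluation on all 32 patterns", {
    grid <- expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1, s11 = 0:1, s12 = 0:1)
    got <- assignCategory(grid)
    # oracle: drop a single gene with the pattern into the formulas and see
    # which category set it lands in
    oracleCat <- function(bits) {
        g <- "the_gene"
        pick <- function(b) if (b == 1) g else character()
        sets <- oracleSets(pick(bits[1]), pick(bits[2]), pick(bits[3]),
                           pick(bits[4]), pick(bits[5]))
        catSets <- c(AA = "Set21", BB = "Set22", AB = "Set23", `A/B` = "Set24",
                     `A-B1` = "A-B1", `A-B2` = "A-B2", `A-B3` = "A-B3",
                     `A-B4` = "A-B4", `A-B5` = "A-B5")
        hit <- names(catSets)[vapply(catSets,
                                     function(nm) g %in% sets[[nm]],
                                     logical(1))]
        if (length(hit) == 0) "none"
        else if (length(hit) == 1) hit
        else stop("pattern satisfies several categories")
    }
    want <- apply(as.matrix(grid), 1, oracleCat)
    expect_identical(unname(got), unname(want))
    # exactly nine patterns are categorized and the map is injective
    hits <- got[got != "none"]
    expect_length(hits, 9)
    expect_setequal(hits, dependenceCategories())
})

test_that("canonical multipliers reproduce the canonical bits as noiseless log2 ratios", {
    em <- c(high = 1, mid = 0.25, low = 0.0625)
    for (cat in dependenceCategories()) {
        pat <- canonicalPattern(cat)
        mu <- em[pat$multipliers]
        names(mu) <- names(pat$multipliers)
        lfc <- c(s1 = log2(mu[["atfA_del"]] / mu[["control"]]),
                 s2 = log2(mu[["atfB_del"]] / mu[["control"]]),
                 s3 = log2(mu[["double_del"]] / mu[["control"]]),
                 s11 = log2(mu[["double_del"]] / mu[["atfB_del"]]),
                 s12 = log2(mu[["double_del"]] / mu[["atfA_del"]]))
        bits <- as.integer(lfc < -1)
        expect_identical(bits, unname(pat$bits),
                         info = paste("category", cat))
        expect_identical(unname(assignCategory(rbind(bits))), cat)
    }
    expect_error(canonicalPattern("AA/BB"), "unknown")
})

test_that("buildPrimarySets maps calls to sets and errors on missing comparisons", {
    reg <- function(genes, call) data.frame(
        gene_id = paste0("g", 1:4),
        status = "tested",
        call = ifelse(paste0("g", 1:4) %in% genes, call, "none"))
    regs <- list(atfA_del_vs_control = reg("g1", "down"),
                 atfB_del_vs_control = reg(character(), "down"),
                 double_del_vs_control = reg(character(), "down"),
                 double_del_vs_atfB_del = reg(character(), "down"),
                 double_del_vs_atfA_del = reg(character(), "down"))
    sys <- buildPrimarySets(regs, condition = "c")
    expect_setequal(geneSets(sys)$Set1, "g1")
    expect_length(geneSets(sys)$Set2, 0)
    # an up call lands in the mirror, not the down set
    regs$atfA_del_vs_control$call[1] <- "up"
    sys <- buildPrimarySets(regs)
    expect_length(geneSets(sys)$Set1, 0)
    expect_setequal(geneSets(sys)$`Set1+`, "g1")
    # control MSB comparison feeds Set0
    regs$MSB_vs_untreated_control <- reg("g3", "down")
    sys <- buildPrimarySets(regs)
    expect_setequal(geneSets(sys)$Set0, "g3")
    expect_error(buildPrimarySets(regs[-2]), "atfB_del_vs_control")
})

test_that("genes not tested in a required comparison are excluded from the universe", {
    reg <- function(st) data.frame(gene_id = c("g1", "g2"),
                                   status = st, call = c("down", "down"))
    regs <- list(atfA_del_vs_control = reg(c("tested", "not_tested")),
                 atfB_del_vs_control = reg(c("tested", "tested")),
                 double_del_vs_control = reg(c("tested", "tested")),
                 double_del_vs_atfB_del = reg(c("tested", "tested")),
                 double_del_vs_atfA_del = reg(c("tested", "tested")))
    sys <- buildPrimarySets(regs)
    expect_setequal(setUniverse(sys), "g1")
    expect_setequal(geneSets(sys)$Set2, "g1")
})

test_that("dependence partition invariants hold on random membership tables", {
    set.seed(42)
    for (rep in 1:5) {
        m <- data.frame(gene_id = sprintf("g%04d", 1:400),
                        s1 = rbinom(400, 1, 0.4), s2 = rbinom(400, 1, 0.4),
                        s3 = rbinom(400, 1, 0.5), s11 = rbinom(400, 1, 0.4),
                        s12 = rbinom(400, 1, 0.4))
        dep <- dependentSets(deriveSets(setSystemFromMembership(m)))
        s <- geneSets(dep$system)
        cats <- lapply(paste0("Set", 21:25), function(nm) s[[nm]])
        expect_identical(length(Reduce(union, cats)), sum(lengths(cats)))
        expect_identical(length(s$Set26),
                         length(s$Set21) + length(s$Set23) +
                         length(s$Set24) + length(s$Set25))
        expect_identical(length(s$Set27),
                         length(s$Set22) + length(s$Set23) +
                         length(s$Set24) + length(s$Set25))
        ab <- lapply(paste0("A-B", 1:5), function(nm) s[[nm]])
        expect_setequal(Reduce(union, ab), s$Set25)
        # labels agree with direct per-gene pattern classification
        bits <- as.matrix(m[, c("s1", "s2", "s3", "s11", "s12")])
        want <- assignCategory(bits)
        got <- dep$categories$category[match(m$gene_id,
                                             dep$categories$gene_id)]
        expect_identical(unname(got), unname(want))
    }
})

test_that("published condition breakdowns flow through the algebra to the printed totals", {
    for (nm in names(tableBreakdowns)) {
        bd <- tableBreakdowns[[nm]]
        counts <- c(bd$A, bd$B["BB"])
        dep <- systemFromCounts(counts, condition = nm)
        expect_identical(length(geneSets(dep$system)$Set26),
                         as.integer(sum(bd$A)), info = nm)
        expect_identical(length(geneSets(dep$system)$Set27),
                         as.integer(sum(bd$B)), info = nm)
    }
})

test_that("msbResponsive unions strains and directions correctly", {
    reg <- function(down, up) data.frame(
        gene_id = paste0("g", 1:4), status = "tested",
        call = ifelse(paste0("g", 1:4) %in% down, "down",
                      ifelse(paste0("g", 1:4) %in% up, "up", "none")))
    regs <- list(control = reg("g1", "g2"), atfA_del = reg("g3", character()))
    expect_setequal(msbResponsive(regs, "control"), c("g1", "g2"))
    expect_setequal(msbResponsive(regs, "any"), c("g1", "g2", "g3"))
    expect_setequal(msbResponsive(regs, "any", "down"), c("g1", "g3"))
})
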