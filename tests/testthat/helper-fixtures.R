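# Shared fixtures built in code.

# Independent oracle for the set algebra: evaluates every defining formula
# literally over an explicit gene universe, with no reference to the
# package's derivation code.  Used to cross-check deriveSets/dependentSets
# and assignCategory.
oracleSets <- function(s1, s2, s3, s11, s12) {
    s13 <- s3
    sets <- list(
        Set1 = s1, Set2 = s2, Set3 = s3, Set11 = s11, Set12 = s12,
        Set4 = setdiff(s1, union(s2, s3)),
        Set5 = setdiff(s2, union(s1, s3)),
        Set6 = setdiff(s3, union(s1, s2)),
        Set7 = setdiff(intersect(s1, s2), s3),
        Set8 = setdiff(intersect(s1, s3), s2),
        Set9 = setdiff(intersect(s2, s3), s1),
        Set10 = intersect(intersect(s1, s2), s3),
        Set13 = s13,
        Set14 = setdiff(s11, union(s12, s13)),
        Set15 = setdiff(s12, union(s11, s13)),
        Set16 = setdiff(s13, union(s11, s12)),
        Set17 = setdiff(intersect(s11, s12), s13),
        Set18 = setdiff(intersect(s11, s13), s12),
        Set19 = setdiff(intersect(s12, s13), s11),
        Set20 = intersect(intersect(s11, s12), s13))
    sets$Set21 <- intersect(sets$Set8, sets$Set18)
    sets$Set22 <- intersect(sets$Set9, sets$Set19)
    sets$Set23 <- intersect(sets$Set10, sets$Set16)
    sets$Set24 <- intersect(sets$Set20, sets$Set6)
    ab <- list(`A-B1` = intersect(sets$Set10, sets$Set20),
               `A-B2` = intersect(sets$Set8, sets$Set20),
               `A-B3` = intersect(sets$Set9, sets$Set20),
               `A-B4` = intersect(sets$Set18, sets$Set10),
               `A-B5` = intersect(sets$Set19, sets$Set10))
    sets <- c(sets, ab)
    sets$Set25 <- Reduce(union, ab)
    sets$Set26 <- Reduce(union, sets[c("Set21", "Set23", "Set24", "Set25")])
    sets$Set27 <- Reduce(union, sets[c("Set22", "Set23", "Set24", "Set25")])
    sets
}

# Membership table with one gene per occurrence of each category count,
# using the canonical bit patterns.
membershipFromCounts <- function(counts) {
    cats <- rep(names(counts), counts)
    bits <- do.call(rbind, lapply(cats, function(cat)
        canonicalPattern(cat)$bits))
    data.frame(gene_id = sprintf("gene%05d", seq_along(cats)),
               category = cats, bits, check.names = FALSE)
}

# Run a membership table through the full algebra.
systemFromCounts <- function(counts, condition = "test") {
    m <- membershipFromCounts(counts)
    dependentSets(deriveSets(setSystemFromMembership(m, condition)))
}

# A tiny hand-made FactorialCounts for API tests: 2 strains x untreated,
# nReps replicates, constant counts.
tinyExperiment <- function(counts) {
    sheet <- data.frame(sample_id = colnames(counts),
                        strain = rep(c("control", "atfA_del"),
                                     each = ncol(counts) / 2),
                        treatment = "untreated", cell_type = "mycelium",
                        batch = "b1",
                        replicate = rep(seq_len(ncol(counts) / 2), 2))
    FactorialCounts(counts, sheet)
}

# Score the categories recovered for one condition against the truth.
scoreRecovery <- function(truth, categories) {
    calls <- data.frame(gene_id = categories$gene_id,
                        category = categories$category,
                        stringsAsFactors = FALSE)
    missing <- setdiff(truth$gene_id, calls$gene_id)
    if (length(missing))
        calls <- rbind(calls,
                       data.frame(gene_id = missing, category = "none"))
    calls <- calls[!calls$gene_id %in%
                       truth$gene_id[truth$is_knockout_marker], ]
    evaluateRecovery(truth, calls)
}

# Published per-category breakdowns of the four conditions (AtfA side
# includes AA; AtfB side includes BB; shared categories identical).
tableBreakdowns <- list(
    mycelium_untreated = list(
        A = c(AA = 236, AB = 16, `A/B` = 40, `A-B1` = 1, `A-B2` = 3,
              `A-B4` = 33),
        B = c(BB = 3, AB = 16, `A/B` = 40, `A-B1` = 1, `A-B2` = 3,
              `A-B4` = 33)),
    mycelium_msb = list(
        A = c(AA = 232, AB = 2, `A/B` = 4, `A-B3` = 2),
        B = c(BB = 1, AB = 2, `A/B` = 4, `A-B3` = 2)),
    conidium_untreated = list(
        A = c(AA = 1079, AB = 80, `A/B` = 84, `A-B1` = 13, `A-B2` = 75,
              `A-B3` = 4, `A-B4` = 161),
        B = c(BB = 22, AB = 80, `A/B` = 84, `A-B1` = 13, `A-B2` = 75,
              `A-B3` = 4, `A-B4` = 161)),
    conidium_msb = list(
        A = c(AA = 989, AB = 41, `A/B` = 8, `A-B1` = 2, `A-B2` = 12,
              `A-B4` = 91),
        B = c(BB = 1, AB = 41, `A/B` = 8, `A-B1` = 2, `A-B2` = 12,
              `A-B4` = 91)))
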