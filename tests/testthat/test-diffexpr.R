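# Normalization, dispersion, the NB Wald engine and regulation calls.

test_that("size factors follow the median-of-ratios definition", {
    m <- rbind(c(10, 20), c(100, 200))
    expect_equal(computeSizeFactors(m), c(1 / sqrt(2), sqrt(2)),
                 tolerance = 1e-12)
    # identical columns give unit factors
    m2 <- matrix(rep(c(5, 50, 500), 3), ncol = 3)
    expect_equal(unname(computeSizeFactors(m2)), rep(1, 3))
    # brute-force oracle on a 3x3 matrix
    m3 <- rbind(c(12, 36, 20), c(5, 18, 9), c(100, 310, 150))
    geo <- exp(rowMeans(log(m3)))
    want <- apply(m3 / geo, 2, median)
    expect_equal(computeSizeFactors(m3), want)
    # scaling one column by 3 scales its ratio column by 3 through the
    # geometric mean only
    m4 <- m3; m4[, 2] <- m4[, 2] * 3
    geo4 <- exp(rowMeans(log(m4)))
    expect_equal(computeSizeFactors(m4), apply(m4 / geo4, 2, median))
    expect_error(computeSizeFactors(rbind(c(0, 5), c(3, 0))), "no gene")
})

test_that("method-of-moments dispersion matches its closed form", {
    # mean 100, within-group variance 600 -> alpha = 0.05
    g1 <- c(100 - sqrt(300), 100 + sqrt(300))   # var 600, mean 100
    m <- rbind(rep(g1, 2))
    expect_equal(unname(estimateDispersion(m, c("a", "a", "b", "b"))),
                 (600 - 100) / 100^2)
    # zero variance floors
    m0 <- rbind(rep(50, 4))
    expect_equal(unname(estimateDispersion(m0, c("a", "a", "b", "b"))), 1e-8)
    # Poisson data at high replication stays near zero
    set.seed(1)
    mp <- matrix(rpois(200 * 50, 500), nrow = 200)
    a <- estimateDispersion(mp, rep("a", 50))
    expect_gt(mean(a < 0.01), 0.95)
})

test_that("deTest recovers a noiseless four-fold change exactly", {
    counts <- cbind(matrix(100L, 5, 3), matrix(400L, 5, 3))
    rownames(counts) <- paste0("g", 1:5)
    colnames(counts) <- paste0("s", 1:6)
    fc <- tinyExperiment(counts)
    cmp <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "mycelium")
    de <- deTest(fc, cmp)
    # with every gene shifted 4x, median-of-ratios normalization absorbs
    # the shift entirely: the estimated fold change is 1
    expect_equal(de$log2fc, rep(0, 5), tolerance = 1e-6)
    # a mixed matrix keeps normalization neutral and exposes the signal
    counts2 <- rbind(cbind(matrix(100L, 3, 3), matrix(400L, 3, 3)),
                     cbind(matrix(400L, 3, 3), matrix(100L, 3, 3)))
    rownames(counts2) <- paste0("g", 1:6)
    colnames(counts2) <- paste0("s", 1:6)
    de2 <- deTest(tinyExperiment(counts2), cmp)
    expect_equal(de2$log2fc, rep(c(2, -2), each = 3), tolerance = 0.05)
})

test_that("all-zero genes are not tested and excluded from the BH denominator", {
    set.seed(3)
    counts <- matrix(rpois(60, 100), 10, 6,
                     dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
    counts[4, ] <- 0L
    fc <- tinyExperiment(counts)
    cmp <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "mycelium")
    de <- deTest(fc, cmp)
    expect_identical(de$status[4], "not_tested")
    expect_true(is.na(de$padj[4]))
    ok <- de$status == "tested"
    expect_equal(de$padj[ok], p.adjust(de$p[ok], "BH"))
    # BH keeps padj >= p and monotone in p-rank
    o <- order(de$p[ok])
    expect_true(all(de$padj[ok] >= de$p[ok] - 1e-15))
    expect_true(all(diff(de$padj[ok][o]) >= -1e-15))
})

test_that("swapping numerator and reference negates log2fc and keeps p", {
    set.seed(7)
    mu <- rep(c(50, 200, 1000), length.out = 30)
    counts <- matrix(rnbinom(30 * 6, mu = rep(mu, 6), size = 20), 30, 6,
                     dimnames = list(paste0("g", 1:30), paste0("s", 1:6)))
    fc <- tinyExperiment(counts)
    fwd <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "mycelium")
    rev <- comparison(list(strain = "control", treatment = "untreated"),
                      list(strain = "atfA_del", treatment = "untreated"),
                      "mycelium")
    d1 <- deTest(fc, fwd)
    d2 <- deTest(fc, rev)
    expect_lt(max(abs(d1$log2fc + d2$log2fc)), 1e-9)
    expect_equal(d1$p, d2$p, tolerance = 1e-6)
})

test_that("log2 fold changes agree with DESeq2 on simulated data", {
    skip_if_not_installed("DESeq2")
    sim <- simulateExperiment(simConfig(nGenes = 400, seed = 5,
                                        depthJitterSd = 0))
    fc <- sim$experiment
    cmp <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "mycelium")
    mine <- deTest(fc, cmp)
    cd <- SummarizedExperiment::colData(fc)
    sel <- cd$treatment == "untreated" & cd$strain %in% c("control", "atfA_del")
    cnt <- SummarizedExperiment::assay(fc, "counts")[, sel]
    col <- data.frame(strain = factor(as.character(cd$strain[sel]),
                                      c("control", "atfA_del")))
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, col, ~strain)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    ref <- DESeq2::results(dds, contrast = c("strain", "atfA_del", "control"))
    both <- mine$status == "tested" & !is.na(ref$log2FoldChange) &
        mine$base_mean > 5 & is.finite(mine$log2fc) & abs(mine$log2fc) < 15
    expect_gt(cor(mine$log2fc[both], ref$log2FoldChange[both]), 0.98)
    # size factors match DESeq2's median-of-ratios
    expect_equal(unname(computeSizeFactors(cnt)),
                 unname(DESeq2::sizeFactors(dds)), tolerance = 1e-6)
})

test_that("regulation calls respect strict thresholds and the gate modes", {
    de <- S4Vectors::DataFrame(
        gene_id = paste0("g", 1:5),
        base_mean = 100,
        log2fc = c(-1.2, -1.0, 2.4, 0.5, -3),
        se = 0.2,
        stat = c(-6, -5, 3.0, 2.5, -15),
        p = c(1e-4, 1e-3, 0.02, 0.04, 1e-8),
        padj = c(0.01, 0.02, 0.30, 0.30, 1e-6),
        status = "tested")
    S4Vectors::metadata(de) <- list(df = 4)
    gated <- classifyRegulated(de, gate = "adjusted")
    expect_identical(gated$call, c("down", "none", "none", "none", "down"))
    ungated <- classifyRegulated(de, gate = "none")
    expect_identical(ungated$call, c("down", "none", "up", "none", "down"))
    # log2fc = -1 exactly is never a call (strict inequality)
    expect_identical(ungated$call[2], "none")
    nominal <- classifyRegulated(de, gate = "nominal")
    # g3: one-sided p = 0.02/..; stat 3.0 on t4 -> one-sided p ~0.02 < 0.05
    expect_identical(nominal$call, c("down", "none", "up", "none", "down"))
    # logical convenience forms
    expect_identical(classifyRegulated(de, gate = TRUE)$call, gated$call)
    expect_identical(classifyRegulated(de, gate = FALSE)$call, ungated$call)
})

test_that("batch-adjusted fits remove a gene-specific batch effect", {
    set.seed(11)
    # batch b2 covers two control samples only, so a per-gene batch shift
    # confounds with the strain contrast unless the model absorbs it
    G <- 90
    batchGene <- rep(c(4, 1, 1), length.out = G)
    signal <- seq_len(G) <= 20             # minority of genes carry the 4x
    mu <- matrix(100, G, 6)
    mu[signal, 4:6] <- 400
    inB2 <- c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
    mu[, inB2] <- mu[, inB2] * batchGene
    counts <- matrix(rnbinom(G * 6, mu = mu, size = 50), G, 6,
                     dimnames = list(paste0("g", 1:G), paste0("s", 1:6)))
    sheet <- data.frame(sample_id = colnames(counts),
                        strain = rep(c("control", "atfA_del"), each = 3),
                        treatment = "untreated", cell_type = "conidium",
                        batch = ifelse(inB2, "b2", "b1"),
                        replicate = rep(1:3, 2))
    fc <- FactorialCounts(counts, sheet)
    adj <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "conidium", batchAdjusted = TRUE)
    unadj <- comparison(list(strain = "atfA_del", treatment = "untreated"),
                        list(strain = "control", treatment = "untreated"),
                        "conidium", batchAdjusted = FALSE)
    deA <- deTest(fc, adj)
    deU <- deTest(fc, unadj)
    shifted <- batchGene == 4
    expect_lt(median(abs(deA$log2fc[signal] - 2)), 0.3)
    expect_lt(median(abs(deA$log2fc[!signal])), 0.3)
    # without the batch term, the shift leaks into the strain contrast of
    # the batch-affected null genes
    expect_lt(median(deU$log2fc[shifted & !signal]), -0.8)
    expect_lt(median(abs(deA$log2fc[shifted & !signal])), 0.3)
    # requesting batch adjustment without batches errors
    sheet$batch <- "b1"
    fc1 <- FactorialCounts(counts, sheet)
    expect_error(deTest(fc1, adj), "fewer than 2 batches")
})

test_that("missing comparison groups give descriptive errors", {
    counts <- matrix(10L, 4, 6, dimnames = list(paste0("g", 1:4),
                                                paste0("s", 1:6)))
    fc <- tinyExperiment(counts)
    cmp <- comparison(list(strain = "atfB_del", treatment = "untreated"),
                      list(strain = "control", treatment = "untreated"),
                      "mycelium")
    expect_error(deTest(fc, cmp), "numerator")
})
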