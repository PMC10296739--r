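test_that("target-map parsing handles all three dialects and dedups sites", {
    dir <- withr::local_tempdir()
    # targetscan-style: repeated sites for one pair collapse to one edge
    ts <- file.path(dir, "ts.txt")
    writeLines(c("Gene Symbol\tRepresentative miRNA\tSite Type",
                 "Foxg1\thsa-miR-9-5p\t8mer",
                 "FOXG1\thsa-miR-9-5p\t7mer-m8",
                 "foxg1 \thsa-miR-9-5p\t7mer-A1",
                 "BDNF\thsa-miR-543\t8mer"), ts)
    tm <- parseTargetMap(ts, "targetscan7")
    expect_equal(nEdges(tm), 2)
    expect_setequal(targetsOf(tm, "hsa-miR-9-5p"), "FOXG1")
    rep <- attr(tm, "report")
    expect_equal(rep$rows_read, 4)
    expect_equal(rep$rows_dropped_duplicate, 2)
    # mirwalk-style csv
    mw <- file.path(dir, "mw.csv")
    writeLines(c("mirnaid,refseqid,genesymbol,position",
                 "hsa-miR-9-5p,NM_1,FOXG1,3UTR",
                 "hsa-miR-9-5p,NM_2,NR2E1,CDS"), mw)
    tm2 <- parseTargetMap(mw, "mirwalk3")
    expect_equal(nEdges(tm2), 2)
    expect_equal(algorithm(tm2), "mirwalk3")
    # generic two-column toy equals the hand-built relation
    gen <- file.path(dir, "gen.tsv")
    writeLines(c("mirna\tgene", "m1\tG1", "m1\tG2", "m2\tG1", "m2\tG3",
                 "m3\tG4"), gen)
    tm3 <- parseTargetMap(gen, "generic2col")
    expect_identical(
        targetEdges(tm3),
        data.frame(mirna = c("m1", "m1", "m2", "m2", "m3"),
                   gene = c("G1", "G2", "G1", "G3", "G4"),
                   stringsAsFactors = FALSE))
    # mirna filter restricts edges and reports drops
    tm4 <- parseTargetMap(gen, "generic2col", mirnaFilter = "m1")
    expect_equal(nEdges(tm4), 2)
    expect_equal(attr(tm4, "report")$rows_dropped_filter, 3)
    # empty file with valid header warns, does not fail
    empty <- file.path(dir, "empty.tsv")
    writeLines("mirna\tgene", empty)
    expect_warning(tm5 <- parseTargetMap(empty, "generic2col"), "empty")
    expect_equal(nEdges(tm5), 0)
    # malformed headers name the missing column
    bad <- file.path(dir, "bad.txt")
    writeLines(c("foo\tbar", "x\ty"), bad)
    expect_error(parseTargetMap(bad, "targetscan7"), "miRNA")
    expect_error(parseTargetMap(bad, "generic2col"), "header")
})

test_that("pair correlations use the exact t-transform", {
    n <- 10
    x <- matrix(seq_len(n), 1, dimnames = list("m1", paste0("s", 1:n)))
    map <- TargetMap(c("m1", "m1", "m1"), c("G1", "G2", "G3"), "toy")
    y <- rbind(G1 = 2 * x[1, ] + 1,                     # perfect positive
               G2 = -(2 * x[1, ] + 1),                  # perfect negative
               G3 = c(2, 1, 4, 3, 7, 5, 9, 6, 10, 8))   # partial
    colnames(y) <- colnames(x)
    pc <- correlatePairs(x, y, map, "m1")
    expect_equal(pc$r[pc$gene == "G1"], 1)
    expect_equal(pc$p[pc$gene == "G1"], 0)
    # negation flips the sign, not the p-value
    expect_equal(pc$r[pc$gene == "G2"], -1)
    expect_equal(pc$sign[pc$gene == "G2"], "negative")
    # numeric-integration oracle for the two-sided t tail
    r3 <- pc$r[pc$gene == "G3"]
    t3 <- r3 * sqrt((n - 2) / (1 - r3^2))
    oracle <- 2 * integrate(function(u) dt(u, df = n - 2), abs(t3),
                            Inf, rel.tol = 1e-12)$value
    expect_equal(pc$p[pc$gene == "G3"], oracle, tolerance = 1e-8)
    expect_equal(pc$p[pc$gene == "G3"],
                 cor.test(x[1, ], y["G3", ])$p.value, tolerance = 1e-12)
    # genes without expression are skipped and counted
    map2 <- TargetMap(c("m1", "m1"), c("G1", "NOWHERE"), "toy")
    pc2 <- correlatePairs(x, y, map2, "m1")
    expect_equal(nrow(pc2), 1)
    expect_equal(attr(pc2, "skipped"), 1)
    # zero-variance gene is flagged with undefined p
    y2 <- rbind(y, GFLAT = rep(5, n))
    map3 <- TargetMap("m1", "GFLAT", "toy")
    pc3 <- correlatePairs(x, y2, map3, "m1")
    expect_true(pc3$flagged)
    expect_true(is.na(pc3$p))
    expect_error(correlatePairs(x[, 1:2, drop = FALSE], y, map, "m1"),
                 "shared samples")
})

test_that("p-value histograms respect the binning conventions", {
    pairs <- data.frame(
        p = c(0.01, 0.05, 0.049, 0.20, 0.999, 1.0, 0.0001),
        sign = c("positive", "positive", "negative", "negative",
                 "positive", "negative", "negative"))
    h <- binPValues(pairs, "coarse")
    expect_equal(nrow(h), 20)
    # p = 0.05 falls in the second half-open bin
    expect_equal(h$n_positive[2], 1)
    # p = 1 is kept in the last (closed) bin
    expect_equal(h$n_negative[20], 1)
    # conservation: every defined p lands in exactly one bin
    expect_equal(sum(h$n_positive + h$n_negative), nrow(pairs))
    hf <- binPValues(pairs, "fine")
    expect_equal(nrow(hf), 20)
    expect_equal(hf$bin_hi[20], 0.0025)
    expect_equal(sum(hf$n_positive + hf$n_negative),
                 sum(pairs$p < 0.0025))
    expect_equal(hf$n_negative[1], 1)  # 0.0001 in [0, 0.000125)
    # hand tally on the coarse scale: 0.01, 0.049, 0.0001 in [0, 0.05)
    expect_equal(h$n_positive[1] + h$n_negative[1], 3)
})

test_that("independent target counts are distinct-miRNA counts", {
    # gene G1 targeted by 3 list members (one via multiple sites) -> 3
    tm <- TargetMap(c("m1", "m1", "m2", "m3", "m4", "m1"),
                    c("G1", "G1", "G1", "G1", "G2", "G3"), "toy")
    genes <- c("G1", "G2", "G3", "G9")
    cnt <- countTargets(tm, c("m1", "m2", "m3"), genes)
    expect_equal(unname(cnt), c(3L, 0L, 1L, 0L))  # G9 retained at 0
    expect_equal(unname(countTargets(tm, character(), genes)), rep(0L, 4))
    # brute-force oracle on a random toy map
    set.seed(5)
    bigM <- TargetMap(sample(paste0("m", 1:6), 60, TRUE),
                      sample(paste0("G", 1:9), 60, TRUE), "toy")
    lst <- c("m1", "m3", "m5")
    uni <- paste0("G", 1:9)
    brute <- vapply(uni, function(g) {
        e <- targetEdges(bigM)
        length(unique(e$mirna[e$gene == g & e$mirna %in% lst]))
    }, integer(1))
    expect_equal(countTargets(bigM, lst, uni), brute)
    # duplicating sites in the source never changes the count
    e <- targetEdges(bigM)
    dup <- TargetMap(rep(e$mirna, 3), rep(e$gene, 3), "toy")
    expect_equal(countTargets(dup, lst, uni), brute)
})

test_that("per-category fold-change summaries match hand averages", {
    counts <- data.frame(
        gene_id = paste0("G", 1:8),
        count_de = c(0, 0, 1, 1, 1, 2, 2, 4),
        count_control = c(0, 1, 0, 1, 2, 2, 1, 4),
        log2fc = c(0.1, -0.1, -0.2, -0.4, -0.3, -0.5, -0.7, -0.9))
    g <- groupFoldChange(counts, "de")
    expect_equal(g$summary$count, c(0, 1, 2, 4))
    expect_equal(g$summary$n_genes, c(2, 3, 2, 1))
    expect_equal(g$summary$mean_fc, c(0, -0.3, -0.6, -0.9))
    expect_equal(g$summary$se_fc[1],
                 sd(c(0.1, -0.1)) / sqrt(2))
    expect_equal(g$test$r, cor(counts$count_de, counts$log2fc))
    # constant fold changes: correlation undefined, flagged
    constant <- transform(counts, log2fc = -0.2)
    expect_true(groupFoldChange(constant, "de")$test$flagged)
    expect_equal(groupFoldChange(constant, "de")$summary$mean_fc,
                 rep(-0.2, 4))
})

test_that("residual fold changes subtract control from DE per category", {
    counts <- data.frame(
        gene_id = paste0("G", 1:8),
        count_de = c(0, 0, 1, 1, 1, 2, 2, 4),
        count_control = c(0, 1, 0, 1, 2, 2, 1, 4),
        log2fc = c(0.1, -0.1, -0.2, -0.4, -0.3, -0.5, -0.7, -0.9))
    sDe <- groupFoldChange(counts, "de")$summary
    sCt <- groupFoldChange(counts, "control")$summary
    res <- residualFoldChange(sDe, sCt)
    # hand subtraction for the shared categories
    ctMeans <- c("0" = mean(c(0.1, -0.2)), "1" = mean(c(-0.1, -0.4, -0.7)),
                 "2" = mean(c(-0.3, -0.5)), "4" = -0.9)
    expect_equal(res$residual,
                 sDe$mean_fc[match(res$count, sDe$count)] -
                 unname(ctMeans[as.character(res$count)]))
    # identical maps give all-zero residuals
    same <- transform(counts, count_control = count_de)
    r0 <- residualFoldChange(groupFoldChange(same, "de")$summary,
                             groupFoldChange(same, "control")$summary)
    expect_equal(r0$residual, rep(0, nrow(r0)))
    # disjoint category sets are an error
    a <- data.frame(count = c(0, 1), n_genes = 1, mean_fc = 0, sd_fc = 0,
                    se_fc = 0)
    b <- transform(a, count = c(5, 6))
    expect_error(residualFoldChange(a, b), "no target-count category")
})

test_that("the four-plus-hit t-test matches the closed-form Welch oracle", {
    counts <- data.frame(
        gene_id = paste0("G", 1:6),
        count_de = c(5, 6, 7, 0, 0, 0),
        count_control = c(0, 0, 0, 4, 5, 9),
        log2fc = c(-1, -2, -3, 1, 2, 3))
    out <- compareFoldChangeTTest(counts, minHits = 4)
    x <- c(-1, -2, -3); y <- c(1, 2, 3)
    se <- sqrt(var(x) / 3 + var(y) / 3)
    tOracle <- (mean(x) - mean(y)) / se
    dfOracle <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
    expect_equal(out$t, tOracle, tolerance = 1e-12)
    expect_equal(out$p, 2 * pt(-abs(tOracle), dfOracle), tolerance = 1e-12)
    expect_equal(out$mean_de, -2)
    expect_equal(out$mean_control, 2)
    # identical (overlapping) groups: t = 0, p = 1
    same <- data.frame(gene_id = paste0("G", 1:4), count_de = 4:7,
                       count_control = 4:7, log2fc = c(-1, 0, 1, 2))
    out2 <- compareFoldChangeTTest(same)
    expect_equal(out2$t, 0)
    expect_equal(out2$p, 1)
    expect_error(compareFoldChangeTTest(counts, minHits = 8), ">= 2 genes")
})

test_that("count-overlap correlation behaves at the identities", {
    counts <- data.frame(gene_id = paste0("G", 1:6),
                         count_de = c(0, 1, 2, 3, 4, 5),
                         count_control = c(0, 1, 2, 3, 4, 5),
                         log2fc = 0)
    expect_equal(mapOverlapCorrelation(counts), 1)
    flat <- transform(counts, count_control = 2)
    expect_true(is.na(mapOverlapCorrelation(flat)))
    expect_true(attr(mapOverlapCorrelation(flat), "flagged"))
    expect_error(mapOverlapCorrelation(counts[1:2, ]), ">= 3")
})
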