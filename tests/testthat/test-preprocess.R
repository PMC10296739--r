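test_that("detection p-value matches exact rank enumeration and directions", {
    # complete separation: exact one-sided rank tail at n1 = n2 = 4
    probe <- c(100, 110, 120, 130); bg <- c(1, 2, 3, 4)
    p <- detectionPValue(probe, bg)
    expect_equal(p, enumRankSumP(probe, bg * 1.015), tolerance = 1e-12)
    expect_equal(p, 1 / choose(8, 4), tolerance = 1e-12)
    # partially overlapping configuration, still enumerable
    probe2 <- c(5, 9, 14, 20); bg2 <- c(4, 8, 15, 30)
    expect_equal(detectionPValue(probe2, bg2, tau = 0),
                 enumRankSumP(probe2, bg2), tolerance = 1e-12)
    # all probes below background: no evidence of expression
    expect_gte(detectionPValue(c(1, 2, 3, 4), c(100, 110, 120, 130)), 0.5)
    # identical multisets are symmetric (tau = 0 isolates the rank test)
    expect_equal(detectionPValue(c(5, 6, 7, 8), c(5, 6, 7, 8), tau = 0),
                 0.5, tolerance = 0.15)
    # rank-based: invariant under common positive rescaling
    expect_equal(detectionPValue(probe2, bg2),
                 detectionPValue(probe2 * 37.5, bg2 * 37.5))
    expect_error(detectionPValue(c(1, 2, 3), bg), ">= 4")
    expect_error(detectionPValue(probe, c(1, 2, 3), probeSetId = "ps77"),
                 "ps77")
})

test_that("expression filter applies the at-least-k-arrays rule", {
    p <- matrix(1, 3, 23, dimnames = list(c("a", "b", "c"), NULL))
    p["a", 1:6] <- 0.01   # significant in exactly 6 of 23 arrays
    p["b", 1:5] <- 0.01   # significant in 5
    p["c", ] <- 0         # saturated
    expect_equal(filterExpressed(p, minArrays = 6), c("a", "c"))
    # boundary p == alpha does not count as detected
    p["b", 6] <- 0.05
    expect_false("b" %in% filterExpressed(p, minArrays = 6))
    expect_warning(out <- filterExpressed(p[0, , drop = FALSE]), "empty")
    expect_identical(out, character())
    expect_error(filterExpressed(p, minArrays = 24), "exceeds")
})

test_that("quantile normalization matches the hand-worked reference", {
    m <- cbind(s1 = c(1, 3), s2 = c(2, 4))
    # sorted columns are (1,3) and (2,4); reference = (1.5, 3.5)
    expect_equal(unname(quantileNormalize(m)),
                 cbind(c(1.5, 3.5), c(1.5, 3.5)))
    # identical columns are a fixed point
    m2 <- cbind(a = c(5, 1, 7), b = c(5, 1, 7))
    expect_equal(quantileNormalize(m2), m2)
    # defining property: all columns share the same sorted values,
    # and within-column rank order is preserved
    set.seed(1)
    m3 <- matrix(rexp(60), 12, 5)
    qn <- quantileNormalize(m3)
    ref <- sort(qn[, 1])
    for (j in 2:5) expect_equal(sort(qn[, j]), ref)
    for (j in 1:5) expect_equal(order(qn[, j]), order(m3[, j]))
    expect_error(quantileNormalize(m3[, 1, drop = FALSE]), ">= 2")
    m3[1, 1] <- NA
    expect_error(quantileNormalize(m3), "missing")
})

test_that("median polish recovers additive structure and resists outliers", {
    r <- c(0, 1, 2); c0 <- c(10, 11, 12, 13)
    add <- outer(r, c0, "+")
    colnames(add) <- paste0("s", 1:4)
    # additive data: zero residuals, sample effects recovered up to a
    # constant (the split between overall and probe effects is arbitrary)
    fitted <- medianPolishSummarize(add)
    expect_equal(unname(diff(fitted)), diff(c0), tolerance = 1e-9)
    # single probe passes through
    one <- matrix(c(3, 4, 5), 1, dimnames = list("p", paste0("s", 1:3)))
    expect_equal(medianPolishSummarize(one), c(s1 = 3, s2 = 4, s3 = 5))
    # shifting one probe row is absorbed by probe/overall terms: the
    # summary changes by at most a constant
    shifted <- add; shifted[2, ] <- shifted[2, ] + 7
    d <- medianPolishSummarize(shifted) - medianPolishSummarize(add)
    expect_equal(unname(d), rep(d[[1]], 4), tolerance = 1e-9)
    # one gross outlier barely moves the summary; oracle = independent
    # row/column median sweeps run to convergence
    out <- add; out[2, 3] <- out[2, 3] + 100
    sweepOracle <- function(m, iter = 200) {
        overall <- 0; re <- rep(0, nrow(m)); ce <- rep(0, ncol(m))
        for (i in seq_len(iter)) {
            rm <- apply(m, 1, median); m <- m - rm; re <- re + rm
            d <- median(ce); ce <- ce - d; overall <- overall + d
            cm <- apply(m, 2, median); m <- sweep(m, 2, cm); ce <- ce + cm
            d <- median(re); re <- re - d; overall <- overall + d
        }
        overall + ce
    }
    got <- medianPolishSummarize(out, maxIter = 100, tol = 1e-9)
    expect_equal(unname(got), unname(sweepOracle(out)), tolerance = 1e-6)
    ctr <- function(x) x - mean(x)  # compare up to the overall constant
    expect_lt(max(abs(ctr(got) - ctr(medianPolishSummarize(add)))),
              0.01 + 1e-9)
    bad <- add; bad[1, 1] <- NA
    expect_error(medianPolishSummarize(bad), "finite")
})

test_that("species filter and sequence dedup follow the funnel rules", {
    ann <- data.frame(
        feature_id = c("p1", "p2", "p3", "p4", "p5"),
        species = c("hsa", "mml", "ptr", "mmu", "hsa"),
        mirbase_name = c("hsa-miR-9-5p", "mml-miR-9-5p", "ptr-miR-9",
                         "mmu-miR-9-5p", "hsa-miR-100"),
        sequence = c("UCUUUGGUUAUCUAGCU", "ucuuuggUUAUCUAGCU",
                     "TCTTTGGTTATCTAGCT",   # same sequence, T for U
                     "UCUUUGGUUAUCUAGCU",   # rodent: dropped regardless
                     "AACCCGUAGAUCCGAAC"),
        stringsAsFactors = FALSE)
    out <- annotateAndDedupe(ann$feature_id, ann)
    # human/ape/OWM probes with one shared sequence collapse to the human name
    expect_equal(nrow(out$features), 2)
    expect_true("hsa-miR-9-5p" %in% out$features$canonical_name)
    expect_equal(out$features$n_merged[out$features$canonical_name ==
                                       "hsa-miR-9-5p"], 3)
    expect_false(any(grepl("mmu", out$features$canonical_name)))
    # funnel counts are monotone non-increasing
    expect_equal(out$funnel$retained, c(5, 4, 2))
    expect_true(all(diff(out$funnel$retained) <= 0))
    # disjoint sequences, all allowed: identity
    ann2 <- ann[c(1, 5), ]
    expect_equal(nrow(annotateAndDedupe(ann2$feature_id, ann2)$features), 2)
    # tie-break without a human name: lexicographically smallest
    ann3 <- ann[2:3, ]
    out3 <- annotateAndDedupe(ann3$feature_id, ann3)
    expect_equal(out3$features$canonical_name, "mml-miR-9-5p")
    expect_error(annotateAndDedupe(c("p1", "zz"), ann), "zz")
})

test_that("probe-level tables flow through the RMA stages", {
    pl <- simulateProbeLevel(smallConfig(seed = 10), probesPerSet = 5)
    out <- rmaPreprocess(pl$probes, pl$background)
    expect_equal(dim(out$expr), c(60, 23))
    expect_true(all(is.finite(out$expr)))
    # quantile normalization makes array distributions identical
    ref <- sort(out$expr[, 1])
    # present sets summarize higher than absent ones
    present <- pl$truth$present[match(rownames(out$expr),
                                      pl$truth$probe_set_id)]
    expect_gt(mean(out$expr[present, ]) - mean(out$expr[!present, ]), 1)
    expect_equal(colnames(out$detectionP), colnames(out$expr))
    q <- out$quality
    expect_setequal(q$sample_id, pl$design$sample_id)
    expect_true(all(c("mean", "pc1", "pc2") %in% colnames(q)))
})
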