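#' Parse a miRNA target-prediction file into a TargetMap
#'
#' Supports three dialects: `targetscan7` (tab-delimited with a
#' representative-miRNA and a gene-symbol column; site-level columns are
#' ignored), `mirwalk3` (CSV with `mirnaid` and `genesymbol` columns) and
#' `generic2col` (tab-delimited `mirna<TAB>gene` with that header). Multiple
#' predicted sites for the same pair collapse to one edge: the analysis
#' counts distinct targeting miRNAs, never total sites.
#'
#' @param path file path.
#' @param format one of `"targetscan7"`, `"mirwalk3"`, `"generic2col"`.
#' @param mirnaFilter optional character vector; edges whose miRNA is not in
#'   the set are dropped.
#' @param algorithm tag stored on the map (defaults to `format`).
#' @return [TargetMap-class] with attribute `report` (rows read / dropped as
#'   duplicate sites / dropped by filter / edges kept).
#' @export
parseTargetMap <- function(path,
                           format = c("targetscan7", "mirwalk3", "generic2col"),
                           mirnaFilter = NULL, algorithm = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    pick <- function(df, candidates, what) {
        norm <- tolower(gsub("[^a-z0-9]", "", tolower(colnames(df))))
        hit <- which(norm %in% candidates)
        if (!length(hit))
            stop("malformed ", format, " file: missing ", what,
                 " column (expected one of: ",
                 paste(candidates, collapse = ", "), ")")
        df[[hit[1]]]
    }
    if (format == "targetscan7") {
        df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
        mir <- pick(df, c("representativemirna", "mirna"), "representative miRNA")
        gene <- pick(df, c("genesymbol", "targetgene"), "gene symbol")
    } else if (format == "mirwalk3") {
        df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
        mir <- pick(df, c("mirnaid", "mirna"), "mirnaid")
        gene <- pick(df, c("genesymbol", "gene"), "genesymbol")
    } else {
        df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
        norm <- tolower(colnames(df))
        if (ncol(df) < 2 || norm[1] != "mirna" || norm[2] != "gene")
            stop("malformed generic2col file: header must be 'mirna<TAB>gene'")
        mir <- df[[1]]; gene <- df[[2]]
    }
    nRead <- length(mir)
    nFiltered <- 0L
    if (!is.null(mirnaFilter)) {
        keep <- trimws(mir) %in% mirnaFilter
        nFiltered <- sum(!keep)
        mir <- mir[keep]; gene <- gene[keep]
    }
    tm <- TargetMap(mir, gene,
                    algorithm = if (is.null(algorithm)) format else algorithm)
    if (nRead == 0L)
        warning("empty target file (valid header, no rows): ", path)
    attr(tm, "report") <- data.frame(
        rows_read = nRead,
        rows_dropped_filter = nFiltered,
        rows_dropped_duplicate = nRead - nFiltered - nEdges(tm),
        edges_kept = nEdges(tm))
    tm
}

#' Correlate miRNAs with their predicted target genes
#'
#' Pearson correlation between each listed miRNA and each of its predicted
#' targets with expression data, over the samples shared by the two
#' matrices. Two-sided p-values come from the exact t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Predicted targets absent from the mRNA matrix are tallied in a skip
#' report, not silently dropped; zero-variance vectors yield a flagged
#' record with undefined p.
#'
#' @param mirnaExpr log2 miRNA matrix or [MirExperiment-class].
#' @param mrnaExpr log2 mRNA matrix (genes x samples; gene rownames are
#'   matched after symbol canonicalization).
#' @param map [TargetMap-class].
#' @param mirnaList miRNAs to profile (must be rows of `mirnaExpr`).
#' @return data.frame (`mirna`, `gene`, `r`, `p`, `n`, `sign`, `flagged`)
#'   with attribute `skipped` = number of (miRNA, gene) pairs whose gene had
#'   no expression data.
#' @export
correlatePairs <- function(mirnaExpr, mrnaExpr, map, mirnaList) {
    if (is(mirnaExpr, "MirExperiment")) mirnaExpr <- exprMatrix(mirnaExpr)
    mrnaExpr <- as.matrix(mrnaExpr)
    rownames(mrnaExpr) <- toupper(trimws(rownames(mrnaExpr)))
    shared <- intersect(colnames(mirnaExpr), colnames(mrnaExpr))
    if (length(shared) < 3)
        stop("need >= 3 shared samples, found ", length(shared))
    missing <- setdiff(mirnaList, rownames(mirnaExpr))
    if (length(missing))
        stop("miRNAs not in expression matrix: ",
             paste(head(missing, 5), collapse = ", "))
    e <- targetEdges(map)
    e <- e[e$mirna %in% mirnaList, , drop = FALSE]
    inExpr <- e$gene %in% rownames(mrnaExpr)
    skipped <- sum(!inExpr)
    e <- e[inExpr, , drop = FALSE]
    n <- length(shared)
    if (!nrow(e)) {
        out <- data.frame(mirna = character(), gene = character(),
                          r = numeric(), p = numeric(), n = integer(),
                          sign = character(), flagged = logical())
        attr(out, "skipped") <- skipped
        return(out)
    }
    mi <- mirnaExpr[unique(e$mirna), shared, drop = FALSE]
    ge <- mrnaExpr[unique(e$gene), shared, drop = FALSE]
    sdMi <- apply(mi, 1, sd); sdGe <- apply(ge, 1, sd)
    R <- suppressWarnings(cor(t(mi), t(ge)))
    r <- R[cbind(match(e$mirna, rownames(mi)), match(e$gene, rownames(ge)))]
    flagged <- sdMi[match(e$mirna, rownames(mi))] == 0 |
        sdGe[match(e$gene, rownames(ge))] == 0
    r[flagged] <- NA_real_
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- ifelse(abs(r) >= 1, 0, 2 * pt(-abs(tstat), df = n - 2))
    p[flagged] <- NA_real_
    out <- data.frame(mirna = e$mirna, gene = e$gene, r = r, p = p, n = n,
                      sign = ifelse(is.na(r) | r >= 0, "positive", "negative"),
                      flagged = flagged,
                      row.names = NULL, stringsAsFactors = FALSE)
    out$sign[is.na(r)] <- NA_character_
    attr(out, "skipped") <- skipped
    out
}

#' Histogram of correlation p-values split by sign
#'
#' `coarse`: 20 half-open bins of width 0.05 over `[0, 1]`, the last bin
#' closed at 1. `fine`: the sub-0.0025 cross-section split into 20 equal
#' half-open bins of width 0.000125. Counts are split into positive and
#' negative correlations; pairs with undefined p are excluded.
#'
#' @param pairs data.frame from [correlatePairs()].
#' @param mode `"coarse"` or `"fine"`.
#' @return data.frame (`bin_lo`, `bin_hi`, `n_positive`, `n_negative`).
#' @export
binPValues <- function(pairs, mode = c("coarse", "fine")) {
    mode <- match.arg(mode)
    ok <- !is.na(pairs$p)
    p <- pairs$p[ok]; s <- pairs$sign[ok]
    if (mode == "coarse") {
        breaks <- seq(0, 1, by = 0.05)
        idx <- pmin(findInterval(p, breaks), 20L)  # p = 1 closes the last bin
    } else {
        breaks <- seq(0, 0.0025, length.out = 21)
        keep <- p < 0.0025
        p <- p[keep]; s <- s[keep]
        idx <- pmin(findInterval(p, breaks), 20L)
    }
    data.frame(
        bin_lo = breaks[-21], bin_hi = breaks[-1],
        n_positive = tabulate(idx[s == "positive"], 20L),
        n_negative = tabulate(idx[s == "negative"], 20L))
}

#' Count distinct list-miRNAs targeting each gene
#'
#' For every gene of the universe, the number of distinct miRNAs from
#' `mirnaList` that target it in the map — the independent target count.
#' Genes not appearing in any edge get a count of 0 and are retained.
#'
#' @param map [TargetMap-class].
#' @param mirnaList character vector of miRNA ids.
#' @param geneUniverse genes with mRNA fold-change data.
#' @return named integer vector over `geneUniverse`.
#' @export
countTargets <- function(map, mirnaList, geneUniverse) {
    geneUniverse <- toupper(trimws(geneUniverse))
    e <- targetEdges(map)
    e <- e[e$mirna %in% mirnaList & e$gene %in% geneUniverse, , drop = FALSE]
    tab <- table(factor(e$gene, levels = geneUniverse))
    setNames(as.integer(tab), geneUniverse)
}

#' Assemble the target-count table for the DE and control lists
#'
#' Combines, over one target map, the independent target counts of the
#' DE-miRNA list and of the matched non-DE control list with the per-gene
#' mRNA log2 fold changes.
#'
#' @param map [TargetMap-class].
#' @param deList,controlList miRNA id vectors.
#' @param foldChanges data.frame (`gene_id`, `log2fc`).
#' @return data.frame (`gene_id`, `count_de`, `count_control`, `log2fc`).
#' @export
buildTargetCountTable <- function(map, deList, controlList, foldChanges) {
    genes <- toupper(trimws(foldChanges$gene_id))
    data.frame(gene_id = genes,
               count_de = countTargets(map, deList, genes),
               count_control = countTargets(map, controlList, genes),
               log2fc = foldChanges$log2fc,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean fold change per target-count category
#'
#' Groups genes by how many distinct list-miRNAs target them and summarizes
#' the mRNA fold change per category (n, mean, standard error of the mean =
#' sd/sqrt(n)); empty categories are omitted. Also tests the per-gene
#' association between count and fold change (Pearson, on genes, not on
#' category means).
#'
#' @param counts data.frame from [buildTargetCountTable()].
#' @param which `"de"` or `"control"`: which list's counts to group on.
#' @return list with `summary` (data.frame `count`, `n_genes`, `mean_fc`,
#'   `sd_fc`, `se_fc`) and `test` (list `r`, `p`, `estimate_slope`, or
#'   flagged when the correlation is undefined).
#' @export
groupFoldChange <- function(counts, which = c("de", "control")) {
    which <- match.arg(which)
    k <- counts[[paste0("count_", which)]]
    fc <- counts$log2fc
    grp <- split(fc, k)
    summary <- data.frame(
        count = as.integer(names(grp)),
        n_genes = lengths(grp),
        mean_fc = vapply(grp, mean, 0),
        sd_fc = vapply(grp, sd, 0),
        row.names = NULL)
    summary$se_fc <- summary$sd_fc / sqrt(summary$n_genes)
    test <- if (sd(k) == 0 || sd(fc) == 0) {
        list(r = NA_real_, p = NA_real_, estimate_slope = NA_real_,
             flagged = TRUE)
    } else {
        ct <- cor.test(k, fc, method = "pearson")
        list(r = unname(ct$estimate), p = ct$p.value,
             estimate_slope = unname(ct$estimate) * sd(fc) / sd(k),
             flagged = FALSE)
    }
    list(summary = summary, test = test)
}

#' Residual fold change between DE-list and control-list categories
#'
#' For each target-count category populated on both sides, the mean fold
#' change of genes targeted that many times by the DE list minus the mean
#' fold change of genes targeted that many times by the control list.
#' Predominantly negative residuals indicate repression specific to the DE
#' list despite the strong overlap in predicted targets.
#'
#' @param summaryDe,summaryControl `summary` data.frames from
#'   [groupFoldChange()] computed on the same gene universe.
#' @return data.frame (`count`, `mean_fc_de`, `mean_fc_control`,
#'   `residual`), with attribute `omitted` listing categories present on
#'   only one side.
#' @export
residualFoldChange <- function(summaryDe, summaryControl) {
    shared <- intersect(summaryDe$count, summaryControl$count)
    if (!length(shared))
        stop("no target-count category is populated in both summaries")
    omitted <- sort(setdiff(union(summaryDe$count, summaryControl$count),
                            shared))
    de <- summaryDe[match(shared, summaryDe$count), ]
    ct <- summaryControl[match(shared, summaryControl$count), ]
    out <- data.frame(count = shared,
                      mean_fc_de = de$mean_fc,
                      mean_fc_control = ct$mean_fc,
                      residual = de$mean_fc - ct$mean_fc,
                      row.names = NULL)
    attr(out, "omitted") <- omitted
    out
}

#' Welch t-test between heavily targeted DE-list and control-list genes
#'
#' Compares the mRNA fold changes of genes targeted at least `minHits` times
#' by the DE list against those targeted at least `minHits` times by the
#' control list (the groups may overlap: a gene can be a frequent target of
#' both). Two-sided Welch (unequal-variance) t-test.
#'
#' @param counts data.frame from [buildTargetCountTable()].
#' @param minHits minimum independent target count (default 4).
#' @return list (`mean_de`, `mean_control`, `n_de`, `n_control`, `t`, `p`).
#' @export
compareFoldChangeTTest <- function(counts, minHits = 4) {
    de <- counts$log2fc[counts$count_de >= minHits]
    ct <- counts$log2fc[counts$count_control >= minHits]
    if (length(de) < 2 || length(ct) < 2)
        stop("need >= 2 genes in each >=", minHits, "-hit group (have ",
             length(de), " and ", length(ct), ")")
    tt <- t.test(de, ct, var.equal = FALSE)
    list(mean_de = mean(de), mean_control = mean(ct),
         n_de = length(de), n_control = length(ct),
         t = unname(tt$statistic), p = tt$p.value)
}

#' Correlation between DE-list and control-list target counts
#'
#' Plain Pearson correlation between the two per-gene independent target
#' counts over the shared gene universe — the overlap statistic showing that
#' frequent targets of the DE list are also frequent targets of the control
#' list.
#'
#' @param counts data.frame from [buildTargetCountTable()].
#' @return Pearson r, or `NA` with attribute `flagged = TRUE` when either
#'   count vector has zero variance.
#' @export
mapOverlapCorrelation <- function(counts) {
    if (nrow(counts) < 3) stop("need >= 3 genes")
    if (sd(counts$count_de) == 0 || sd(counts$count_control) == 0) {
        r <- NA_real_
        attr(r, "flagged") <- TRUE
        return(r)
    }
    cor(counts$count_de, counts$count_control)
}
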