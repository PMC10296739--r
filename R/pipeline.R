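#' Configuration for the end-to-end pipeline
#'
#' Bundles the input paths and thresholds of a full run. Expression is a
#' pre-summarized log2 matrix (the usual entry point when starting from a
#' series-matrix-style table); probe-level input goes through
#' [rmaPreprocess()] separately before being handed to the pipeline.
#'
#' @param expression path to the expression TSV (see [readExpressionMatrix()]).
#' @param design path to the design TSV.
#' @param annotation optional annotation TSV path.
#' @param mrnaFoldChange optional path to the paired mRNA fold-change TSV;
#'   when absent, the integration stage is skipped with a notice.
#' @param targetMaps named character vector of target-map paths (names are
#'   algorithm tags).
#' @param targetMapFormats formats per map (recycled; default
#'   `"generic2col"`).
#' @param pThresh,lfcThresh DE selection thresholds (defaults 0.05, 1).
#' @param kControl size of the non-DE control list (default 24).
#' @param interactionAlpha interaction-exclusion threshold for the control
#'   list (default 0.05).
#' @param minHits hit threshold of the group t-test (default 4).
#' @param clusterChrom chromosome for [clusterStats()]; `NULL` picks the
#'   chromosome carrying the most DE-up features (>= 2).
#' @param seed integer recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param outDir output directory.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression, design, annotation = NULL,
                           mrnaFoldChange = NULL,
                           targetMaps = character(),
                           targetMapFormats = "generic2col",
                           pThresh = 0.05, lfcThresh = 1, kControl = 24,
                           interactionAlpha = 0.05, minHits = 4,
                           clusterChrom = NULL, seed = 1L,
                           outDir = tempfile("mirTally_run")) {
    paths <- c(expression = expression, design = design,
               annotation = annotation, mrnaFoldChange = mrnaFoldChange,
               targetMaps)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    if (pThresh <= 0 || pThresh >= 1 || lfcThresh < 0 ||
        interactionAlpha <= 0 || interactionAlpha >= 1 ||
        kControl < 1 || minHits < 0)
        stop("threshold out of range")
    if (length(targetMaps) && is.null(names(targetMaps)))
        stop("targetMaps must be a named vector (algorithm tags)")
    structure(list(
        expression = expression, design = design, annotation = annotation,
        mrnaFoldChange = mrnaFoldChange,
        targetMaps = targetMaps,
        targetMapFormats = rep_len(targetMapFormats,
                                   max(length(targetMaps), 1L)),
        pThresh = pThresh, lfcThresh = lfcThresh, kControl = kControl,
        interactionAlpha = interactionAlpha, minHits = minHits,
        clusterChrom = clusterChrom, seed = as.integer(seed),
        outDir = outDir), class = "PipelineConfig")
}

#' Convenience: pipeline configuration for a fixture directory
#'
#' @param dir a directory written by [writeFixture()].
#' @param ... overrides passed to [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
fixturePipelineConfig <- function(dir, ...) {
    mapFiles <- list.files(dir, pattern = "^targets_.*\\.tsv$",
                           full.names = TRUE)
    names(mapFiles) <- sub("^targets_(.*)\\.tsv$", "\\1", basename(mapFiles))
    fcPath <- file.path(dir, "mrna_foldchange.tsv")
    pipelineConfig(
        expression = file.path(dir, "expression.tsv"),
        design = file.path(dir, "design.tsv"),
        annotation = file.path(dir, "annotation.tsv"),
        mrnaFoldChange = if (file.exists(fcPath)) fcPath else NULL,
        targetMaps = mapFiles, ...)
}

#' Run the full integrated analysis
#'
#' Executes the stage chain differential expression -> integration (once per
#' target map) -> co-expression on a pre-summarized expression matrix, and
#' writes every intermediate table plus a run log to `config$outDir`.
#' Re-running with an identical configuration reproduces byte-identical
#' outputs. When the mRNA fold-change table is absent the integration stage
#' is skipped with an explicit notice; earlier outputs are still emitted.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) the report bundle: a list with `de`, `controlList`,
#'   `results`, `integration` (per map: count table, group summaries,
#'   residuals, t-test, overlap r), `coexpr`, `quality`, `notices`, `files`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    notices <- character()
    emit <- function(x, f, rn = FALSE) {
        write.table(x, file.path(config$outDir, f), sep = "\t",
                    quote = FALSE, row.names = rn, col.names = TRUE)
        f
    }
    files <- character()

    expr <- readExpressionMatrix(config$expression)
    design <- readSampleDesign(config$design)
    annotation <- if (!is.null(config$annotation))
        readAnnotation(config$annotation) else NULL
    me <- MirExperiment(expr, design, annotation)

    quality <- arrayQualityReport(exprMatrix(me))
    files <- c(files, emit(quality, "array_quality.tsv"))

    # differential expression
    res <- fitTwoFactorAnova(me)
    res$q_alcohol <- as.numeric(storeyQValues(res$p_alcohol))
    res$q_age <- as.numeric(storeyQValues(res$p_age))
    res$q_interaction <- as.numeric(storeyQValues(res$p_interaction))
    de <- selectDE(res, pThresh = config$pThresh,
                   lfcThresh = config$lfcThresh, factor = "alcohol")
    res <- de$results
    controlList <- selectControlList(res, k = config$kControl,
                                     interactionAlpha = config$interactionAlpha)
    files <- c(files, emit(res, "de_results.tsv"))
    writeLines(de$up, file.path(config$outDir, "de_up.txt"))
    writeLines(de$down, file.path(config$outDir, "de_down.txt"))
    writeLines(controlList, file.path(config$outDir, "control_list.txt"))
    files <- c(files, "de_up.txt", "de_down.txt", "control_list.txt")

    # integration, per target map
    integration <- list()
    stats <- list(n_features = nrow(res),
                  n_de_up = length(de$up), n_de_down = length(de$down),
                  expected_null_count = expectedNullCount(nrow(res),
                                                          config$pThresh))
    if (is.null(config$mrnaFoldChange)) {
        notices <- c(notices,
                     "integration skipped: no mRNA fold-change table supplied")
    } else if (!length(de$up)) {
        notices <- c(notices, "integration skipped: empty DE-up list")
    } else {
        fc <- readFoldChangeTable(config$mrnaFoldChange)
        for (i in seq_along(config$targetMaps)) {
            tag <- names(config$targetMaps)[i]
            map <- parseTargetMap(config$targetMaps[[i]],
                                  format = config$targetMapFormats[i],
                                  algorithm = tag)
            counts <- buildTargetCountTable(map, de$up, controlList, fc)
            gDe <- groupFoldChange(counts, "de")
            gCt <- groupFoldChange(counts, "control")
            resid <- residualFoldChange(gDe$summary, gCt$summary)
            tt <- compareFoldChangeTTest(counts, minHits = config$minHits)
            ovl <- mapOverlapCorrelation(counts)
            files <- c(files,
                       emit(counts, paste0("target_counts_", tag, ".tsv")),
                       emit(gDe$summary, paste0("group_fc_de_", tag, ".tsv")),
                       emit(gCt$summary, paste0("group_fc_control_", tag, ".tsv")),
                       emit(resid, paste0("residuals_", tag, ".tsv")))
            integration[[tag]] <- list(
                counts = counts, groupDe = gDe, groupControl = gCt,
                residuals = resid, ttest = tt, overlap_r = as.numeric(ovl))
            stats[[tag]] <- list(
                count_fc_r = gDe$test$r, count_fc_p = gDe$test$p,
                mean_fc_de = tt$mean_de, mean_fc_control = tt$mean_control,
                ttest_t = tt$t, ttest_p = tt$p,
                overlap_r = as.numeric(ovl),
                frac_negative_residuals = mean(resid$residual < 0))
        }
    }

    # co-expression of the DE-up list
    coexpr <- NULL
    if (length(de$up) >= 2) {
        cm <- correlationMatrix(me, de$up)
        ord <- pcOrder(cm)
        files <- c(files, emit(as.data.frame(cm), "correlation_matrix.tsv",
                               rn = TRUE))
        writeLines(ord, file.path(config$outDir, "pc_order.txt"))
        files <- c(files, "pc_order.txt")
        cluster <- NULL
        if (!is.null(annotation)) {
            chrom <- config$clusterChrom
            if (is.null(chrom)) {
                upAnn <- annotation[annotation$feature_id %in% de$up, ]
                tab <- sort(table(upAnn$chrom), decreasing = TRUE)
                if (length(tab) && tab[1] >= 2) chrom <- names(tab)[1]
            }
            if (!is.null(chrom)) {
                cluster <- tryCatch(
                    clusterStats(me, annotation, chrom, featureList = de$up),
                    error = function(e) NULL)
                if (!is.null(cluster)) {
                    jsonlite::write_json(cluster,
                        file.path(config$outDir, "cluster_report.json"),
                        auto_unbox = TRUE, digits = NA)
                    files <- c(files, "cluster_report.json")
                    stats$cluster_mean_r <- cluster$mean_r
                }
            }
        }
        coexpr <- list(corr = cm, order = ord, cluster = cluster)
    } else {
        notices <- c(notices, "co-expression skipped: fewer than 2 DE-up features")
    }

    log <- list(package = "mirTally",
                version = as.character(packageVersion("mirTally")),
                seed = config$seed,
                thresholds = config[c("pThresh", "lfcThresh", "kControl",
                                      "interactionAlpha", "minHits")],
                notices = notices, files = sort(files))
    jsonlite::write_json(stats, file.path(config$outDir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(log, file.path(config$outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(de = de[c("up", "down")], controlList = controlList,
                   results = res, integration = integration, coexpr = coexpr,
                   quality = quality, stats = stats, notices = notices,
                   files = sort(c(files, "stats.json", "run_log.json"))))
}
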