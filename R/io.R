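#' Write a synthetic (or real) paired dataset to a fixture directory
#'
#' Emits the plain-text interchange formats consumed by the pipeline
#' readers: `expression.tsv` (features x samples, tab-delimited, header =
#' sample ids), `design.tsv`, `annotation.tsv`, one `targets_<algo>.tsv`
#' per map (two-column `mirna<TAB>gene` with header), `mrna_foldchange.tsv`
#' and `truth.json`. Reading the directory back with [readFixture()]
#' round-trips exactly.
#'
#' @param dataset a list as returned by [simulatePairedData()].
#' @param dir output directory; created if missing.
#' @return data.frame manifest (`file`, `rows`), invisibly-ordered by file.
#' @export
writeFixture <- function(dataset, dir) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || file.access(dir, 2) != 0)
        stop("cannot write to directory: ", dir)
    tsv <- function(x, f, rn = FALSE) {
        write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                    row.names = rn, col.names = TRUE)
        nrow(x)
    }
    expr <- exprMatrix(dataset$mirna)
    exprDf <- data.frame(feature_id = rownames(expr), expr,
                         check.names = FALSE, stringsAsFactors = FALSE)
    manifest <- data.frame(file = character(), rows = integer())
    add <- function(f, r) rbind(manifest, data.frame(file = f, rows = r))
    manifest <- add("expression.tsv", tsv(exprDf, "expression.tsv"))
    manifest <- add("design.tsv", tsv(dataset$design, "design.tsv"))
    manifest <- add("annotation.tsv", tsv(dataset$annotation, "annotation.tsv"))
    for (m in dataset$maps) {
        f <- paste0("targets_", algorithm(m), ".tsv")
        e <- targetEdges(m)
        manifest <- add(f, tsv(data.frame(mirna = e$mirna, gene = e$gene), f))
    }
    manifest <- add("mrna_foldchange.tsv",
                    tsv(dataset$mrnaFoldChange, "mrna_foldchange.tsv"))
    truth <- dataset$truth
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- add("truth.json", length(truth))
    rownames(manifest) <- NULL
    manifest
}

#' Read back a fixture directory written by writeFixture
#'
#' @param dir the fixture directory.
#' @return a list with the same shape as [simulatePairedData()] output
#'   (`truth` is `NULL` when `truth.json` is absent).
#' @export
readFixture <- function(dir) {
    expr <- readExpressionMatrix(file.path(dir, "expression.tsv"))
    design <- readSampleDesign(file.path(dir, "design.tsv"))
    annotation <- readAnnotation(file.path(dir, "annotation.tsv"))
    mapFiles <- list.files(dir, pattern = "^targets_.*\\.tsv$")
    maps <- lapply(mapFiles, function(f) {
        tag <- sub("^targets_(.*)\\.tsv$", "\\1", f)
        parseTargetMap(file.path(dir, f), format = "generic2col",
                       algorithm = tag)
    })
    names(maps) <- sub("^targets_(.*)\\.tsv$", "\\1", mapFiles)
    fcPath <- file.path(dir, "mrna_foldchange.tsv")
    fc <- if (file.exists(fcPath)) readFoldChangeTable(fcPath) else NULL
    tPath <- file.path(dir, "truth.json")
    truth <- if (file.exists(tPath)) jsonlite::read_json(tPath, simplifyVector = TRUE) else NULL
    list(mirna = MirExperiment(expr, design, annotation),
         mrnaFoldChange = fc, design = design, annotation = annotation,
         maps = maps, truth = truth)
}

#' Readers for the tab-delimited interchange formats
#'
#' `readExpressionMatrix()` reads a features x samples table whose first
#' column holds feature ids; `readSampleDesign()` a `sample_id` / `age` /
#' `exposure` table; `readAnnotation()` the feature annotation;
#' `readFoldChangeTable()` a `gene_id` / `log2fc` table.
#'
#' @param path file path.
#' @return matrix or data.frame as described.
#' @name readers
NULL

#' @rdname readers
#' @export
readExpressionMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
}

#' @rdname readers
#' @export
readSampleDesign <- function(path) {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "age", "exposure")
    miss <- setdiff(need, colnames(d))
    if (length(miss))
        stop("design file missing column(s): ", paste(miss, collapse = ", "))
    d[need]
}

#' @rdname readers
#' @export
readAnnotation <- function(path) {
    a <- read.delim(path, stringsAsFactors = FALSE)
    if (!"feature_id" %in% colnames(a))
        stop("annotation file missing column: feature_id")
    if ("chrom" %in% colnames(a)) a$chrom <- as.character(a$chrom)
    a
}

#' @rdname readers
#' @export
readFoldChangeTable <- function(path) {
    fc <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "log2fc")
    miss <- setdiff(need, colnames(fc))
    if (length(miss))
        stop("fold-change file missing column(s): ", paste(miss, collapse = ", "))
    fc$gene_id <- toupper(trimws(fc$gene_id))
    fc[need]
}
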