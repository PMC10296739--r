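#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame make_zero_col_DFrame
#' @importFrom stats cor sd median quantile rnorm runif rpois rgamma pf pt
#'   setNames smooth.spline predict t.test cor.test wilcox.test p.adjust
#'   model.matrix contr.sum prcomp complete.cases aggregate
#' @importFrom utils read.delim read.csv write.table packageVersion head
NULL

#' Container for a log2 miRNA expression experiment
#'
#' `MirExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with the constraints the
#' downstream analysis relies on: a single finite `log2expr` assay, unique
#' feature identifiers, and a two-factor sample design (`age` with levels
#' `5mo`/`2yr`, `exposure` with levels `control`/`PAE`) stored in `colData`.
#' Feature annotation (species tag, miRBase-style name, mature sequence,
#' genomic coordinates) lives in `rowData` when available.
#'
#' @slot .. inherited from `SummarizedExperiment`; no additional slots.
#'
#' @aliases MirExperiment-class
#' @exportClass MirExperiment
setClass("MirExperiment", contains = "SummarizedExperiment")

setValidity("MirExperiment", function(object) {
    msg <- character()
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    else {
        a <- SummarizedExperiment::assay(object, "log2expr")
        if (!is.numeric(a) || any(!is.finite(a)))
            msg <- c(msg, "assay 'log2expr' must be finite numeric")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature ids are not allowed")
    cd <- SummarizedExperiment::colData(object)
    for (fac in c("age", "exposure")) {
        if (!fac %in% colnames(cd)) {
            msg <- c(msg, sprintf("colData must contain '%s'", fac))
        }
    }
    if (all(c("age", "exposure") %in% colnames(cd))) {
        if (!all(cd$age %in% c("5mo", "2yr")))
            msg <- c(msg, "age levels must be '5mo'/'2yr'")
        if (!all(cd$exposure %in% c("control", "PAE")))
            msg <- c(msg, "exposure levels must be 'control'/'PAE'")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MirExperiment
#'
#' @param expr numeric matrix of log2 expression, features x samples, with
#'   row and column names.
#' @param design data.frame with columns `sample_id`, `age` (`5mo`/`2yr`) and
#'   `exposure` (`control`/`PAE`); rows are matched to `colnames(expr)` by
#'   `sample_id`.
#' @param annotation optional data.frame of feature annotation with a
#'   `feature_id` column matching `rownames(expr)`.
#'
#' @return A [MirExperiment-class] object.
#' @examples
#' expr <- matrix(rnorm(12, 8), 3, 4,
#'                dimnames = list(paste0("miR-", 1:3), paste0("s", 1:4)))
#' des <- data.frame(sample_id = paste0("s", 1:4),
#'                   age = rep(c("5mo", "2yr"), each = 2),
#'                   exposure = rep(c("control", "PAE"), 2))
#' me <- MirExperiment(expr, des)
#' @export
MirExperiment <- function(expr, design, annotation = NULL) {
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("'expr' must have row and column names")
    if (!all(c("sample_id", "age", "exposure") %in% colnames(design)))
        stop("'design' needs columns sample_id, age, exposure")
    if (!setequal(design$sample_id, colnames(expr)))
        stop("design sample_ids do not match expression columns")
    design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(
        age = as.character(design$age),
        exposure = as.character(design$exposure),
        row.names = colnames(expr))
    rd <- NULL
    if (!is.null(annotation)) {
        if (!"feature_id" %in% colnames(annotation))
            stop("'annotation' needs a feature_id column")
        i <- match(rownames(expr), annotation$feature_id)
        if (anyNA(i))
            stop("annotation missing for: ",
                 paste(head(rownames(expr)[is.na(i)], 5), collapse = ", "))
        rd <- S4Vectors::DataFrame(annotation[i, , drop = FALSE],
                                   row.names = rownames(expr))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = expr),
        colData = cd,
        rowData = if (is.null(rd)) S4Vectors::make_zero_col_DFrame(nrow(expr)) else rd)
    new("MirExperiment", se)
}

#' Map of predicted miRNA-to-gene targeting relations
#'
#' A deduplicated relation from miRNA identifiers to predicted target gene
#' symbols, tagged with the prediction algorithm it came from. Gene symbols
#' are canonicalized (whitespace-trimmed, uppercased) at construction; one
#' edge means "this algorithm predicts at least one site", never a site
#' count.
#'
#' @slot algorithm single character tag, e.g. `"targetscan7"`.
#' @slot edges data.frame with character columns `mirna` and `gene`;
#'   duplicate pairs are disallowed.
#'
#' @aliases TargetMap-class
#' @exportClass TargetMap
setClass("TargetMap",
         slots = c(algorithm = "character", edges = "data.frame"))

setValidity("TargetMap", function(object) {
    msg <- character()
    if (length(object@algorithm) != 1L || is.na(object@algorithm))
        msg <- c(msg, "algorithm must be a single string")
    e <- object@edges
    if (!all(c("mirna", "gene") %in% colnames(e)))
        msg <- c(msg, "edges must have columns 'mirna' and 'gene'")
    else if (nrow(e) > 1) {
        o <- order(e$mirna, e$gene, method = "radix")
        m <- e$mirna[o]; g <- e$gene[o]
        if (any(m[-1] == m[-length(m)] & g[-1] == g[-length(g)]))
            msg <- c(msg, "duplicate (mirna, gene) pairs are not allowed")
        if (!identical(e$gene, toupper(trimws(e$gene))))
            msg <- c(msg, "gene symbols must be canonical (trimmed, uppercase)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TargetMap
#'
#' @param mirna,gene character vectors of equal length; one predicted
#'   miRNA-target pair per element. Duplicate pairs (multiple predicted
#'   sites) collapse to a single edge.
#' @param algorithm character tag identifying the prediction source.
#'
#' @return A [TargetMap-class] object.
#' @examples
#' tm <- TargetMap(c("miR-9-5p", "miR-9-5p", "miR-543"),
#'                 c("FOXG1", "foxg1 ", "BDNF"), "toy")
#' nEdges(tm)  # 2: the duplicated FOXG1 site collapses
#' @export
TargetMap <- function(mirna, gene, algorithm = "generic") {
    stopifnot(length(mirna) == length(gene))
    mirna <- trimws(as.character(mirna))
    gene <- toupper(trimws(as.character(gene)))
    keep <- nzchar(mirna) & nzchar(gene)
    mirna <- mirna[keep]; gene <- gene[keep]
    o <- order(mirna, gene, method = "radix")
    mirna <- mirna[o]; gene <- gene[o]
    if (length(mirna) > 1) {
        dup <- c(FALSE, mirna[-1] == mirna[-length(mirna)] &
                        gene[-1] == gene[-length(gene)])
        mirna <- mirna[!dup]; gene <- gene[!dup]
    }
    e <- data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
    new("TargetMap", algorithm = as.character(algorithm), edges = e)
}
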