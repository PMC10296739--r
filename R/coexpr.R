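#' Pairwise correlation matrix of selected features
#'
#' Symmetric Pearson correlation matrix of the listed features' expression
#' profiles, unit diagonal. A zero-variance feature is an error (its
#' correlation is undefined) and is reported by name.
#'
#' @param expr [MirExperiment-class] or log2 matrix.
#' @param featureList features to include (default: all rows).
#' @return symmetric numeric matrix with entries in `[-1, 1]`.
#' @export
correlationMatrix <- function(expr, featureList = NULL) {
    if (is(expr, "MirExperiment")) expr <- exprMatrix(expr)
    expr <- as.matrix(expr)
    if (ncol(expr) < 3) stop("need >= 3 samples")
    if (is.null(featureList)) featureList <- rownames(expr)
    missing <- setdiff(featureList, rownames(expr))
    if (length(missing))
        stop("features not in matrix: ", paste(head(missing, 5), collapse = ", "))
    m <- expr[featureList, , drop = FALSE]
    sds <- apply(m, 1, sd)
    if (any(sds == 0))
        stop("zero-variance feature(s): ",
             paste(head(featureList[sds == 0], 5), collapse = ", "))
    cor(t(m))
}

#' Order features by their first-principal-component loading
#'
#' Sorts the features by their loading on the first eigenvector of the
#' correlation matrix, the ordering used to reveal block structure in a
#' co-expression heatmap. The eigenvector sign is fixed so that its
#' largest-magnitude entry is positive, and loading ties are broken by
#' feature id, making the ordering deterministic and invariant to input
#' permutation.
#'
#' @param corrMatrix symmetric correlation matrix with dimnames.
#' @return character vector: feature ids in decreasing-loading order.
#' @export
pcOrder <- function(corrMatrix) {
    corrMatrix <- as.matrix(corrMatrix)
    if (!isSymmetric(unname(corrMatrix), tol = 1e-8))
        stop("correlation matrix must be symmetric")
    v <- eigen(corrMatrix, symmetric = TRUE)$vectors[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    ids <- rownames(corrMatrix)
    # round before ordering so exact symmetry ties resolve by feature id,
    # not by eigen-solver noise
    ids[order(-round(v, 8), ids)]
}

#' Genomic co-expression cluster statistics
#'
#' Reports on the miRNAs of a feature list that fall inside one genomic
#' window: member ids, genomic span, and the mean pairwise Pearson
#' correlation of their expression profiles (over all unordered pairs).
#'
#' @param expr [MirExperiment-class] or log2 matrix.
#' @param annotation data.frame with `feature_id`, `chrom`, `start`, `end`.
#' @param chrom chromosome of the window.
#' @param window optional `c(start, end)`; default spans the chromosome.
#' @param featureList optional restriction (e.g. the DE-up list).
#' @return list (`members`, `chrom`, `span_start`, `span_end`, `mean_r`,
#'   `n_members`).
#' @export
clusterStats <- function(expr, annotation, chrom, window = NULL,
                         featureList = NULL) {
    ann <- annotation[annotation$chrom == as.character(chrom), , drop = FALSE]
    if (!is.null(window))
        ann <- ann[ann$start >= window[1] & ann$end <= window[2], , drop = FALSE]
    if (!is.null(featureList))
        ann <- ann[ann$feature_id %in% featureList, , drop = FALSE]
    if (is(expr, "MirExperiment")) expr <- exprMatrix(expr)
    ann <- ann[ann$feature_id %in% rownames(expr), , drop = FALSE]
    if (nrow(ann) < 2)
        stop("fewer than 2 cluster members in the window")
    cm <- correlationMatrix(expr, ann$feature_id)
    meanR <- mean(cm[upper.tri(cm)])
    list(members = ann$feature_id, chrom = as.character(chrom),
         span_start = min(ann$start), span_end = max(ann$end),
         mean_r = meanR, n_members = nrow(ann))
}
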