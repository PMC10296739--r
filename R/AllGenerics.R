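#' Accessors for TargetMap and MirExperiment objects
#'
#' `algorithm()` returns the prediction-algorithm tag, `targetEdges()` the
#' deduplicated edge table, `mirnas()` the distinct miRNA ids in a map,
#' `targetsOf()` the predicted gene set of one miRNA, `nEdges()` the number
#' of distinct (miRNA, gene) pairs. `designFactors()` returns the age /
#' exposure design of a [MirExperiment-class] as a plain data.frame and
#' `exprMatrix()` its log2 expression matrix.
#'
#' @param x a [TargetMap-class] or [MirExperiment-class] object.
#' @param mirna single miRNA id.
#' @return See individual descriptions above.
#' @name accessors
#' @examples
#' tm <- TargetMap(c("a", "a", "b"), c("G1", "G2", "G1"), "toy")
#' algorithm(tm)
#' mirnas(tm)
#' targetsOf(tm, "a")
NULL

#' @rdname accessors
#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))

#' @rdname accessors
#' @export
setGeneric("targetEdges", function(x) standardGeneric("targetEdges"))

#' @rdname accessors
#' @export
setGeneric("mirnas", function(x) standardGeneric("mirnas"))

#' @rdname accessors
#' @export
setGeneric("targetsOf", function(x, mirna) standardGeneric("targetsOf"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("designFactors", function(x) standardGeneric("designFactors"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
setMethod("algorithm", "TargetMap", function(x) x@algorithm)

#' @rdname accessors
setMethod("targetEdges", "TargetMap", function(x) x@edges)

#' @rdname accessors
setMethod("mirnas", "TargetMap", function(x) unique(x@edges$mirna))

#' @rdname accessors
setMethod("targetsOf", "TargetMap", function(x, mirna) {
    x@edges$gene[x@edges$mirna == mirna]
})

#' @rdname accessors
setMethod("nEdges", "TargetMap", function(x) nrow(x@edges))

setMethod("show", "TargetMap", function(object) {
    cat("TargetMap [", object@algorithm, "]: ",
        nEdges(object), " edges, ",
        length(mirnas(object)), " miRNAs, ",
        length(unique(object@edges$gene)), " genes\n", sep = "")
})

#' @rdname accessors
setMethod("designFactors", "MirExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    data.frame(sample_id = rownames(cd),
               age = cd$age, exposure = cd$exposure,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("exprMatrix", "MirExperiment", function(x) {
    SummarizedExperiment::assay(x, "log2expr")
})

setMethod("show", "MirExperiment", function(object) {
    d <- designFactors(object)
    tab <- table(d$age, d$exposure)
    cat("MirExperiment: ", nrow(object), " features x ", ncol(object),
        " samples (log2 scale)\n", sep = "")
    cat("design cells:",
        paste(sprintf("%s/%s=%d", rownames(tab)[row(tab)],
                      colnames(tab)[col(tab)], tab), collapse = " "), "\n")
})
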