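#' MAS5-style detection p-value for one probe set in one sample
#'
#' Rank-based one-sided test of whether a probe set's intensities exceed the
#' background-probe distribution. On a perfect-match-only platform there are
#' no mismatch probes, so the detection call is a one-sided Wilcoxon rank-sum
#' test of the probe intensities against the background intensities inflated
#' by a small relative offset `tau`; small p-values indicate expression above
#' background. The statistic depends on ranks only, so it is invariant under
#' any common positive rescaling of probe and background values.
#'
#' @param probeValues numeric vector (>= 4) of raw probe intensities for the
#'   probe set in one sample.
#' @param backgroundValues numeric vector (>= 4) of background-probe
#'   intensities in the same sample.
#' @param tau small positive relative offset the probes must beat
#'   (default 0.015).
#' @param probeSetId optional id used in error messages.
#' @return one-sided p-value in `[0, 1]`.
#' @examples
#' detectionPValue(c(100, 110, 120, 130), c(1, 2, 3, 4))  # strong signal
#' @export
detectionPValue <- function(probeValues, backgroundValues, tau = 0.015,
                            probeSetId = NULL) {
    id <- if (is.null(probeSetId)) "" else paste0(" [", probeSetId, "]")
    if (length(probeValues) < 4)
        stop("need >= 4 probe values", id)
    if (length(backgroundValues) < 4)
        stop("need >= 4 background values", id)
    if (any(probeValues <= 0) || any(backgroundValues <= 0))
        stop("intensities must be positive", id)
    suppressWarnings(
        wilcox.test(probeValues, backgroundValues * (1 + tau),
                    alternative = "greater", exact = NULL)$p.value)
}

#' Detection p-values for a whole probe-level table
#'
#' Applies [detectionPValue()] to every probe set and sample.
#'
#' @param probes data.frame with columns `probe_set_id`, `probe_index`, then
#'   one intensity column per sample (the layout written by
#'   [simulateProbeLevel()]).
#' @param background matrix of background-probe intensities, one column per
#'   sample (column order matching `probes`).
#' @param tau passed to [detectionPValue()].
#' @return matrix of p-values, probe sets x samples.
#' @export
detectionCalls <- function(probes, background, tau = 0.015) {
    sampleCols <- setdiff(colnames(probes), c("probe_set_id", "probe_index"))
    if (!length(sampleCols)) stop("no sample columns in probe table")
    sets <- split(seq_len(nrow(probes)), probes$probe_set_id)
    p <- matrix(NA_real_, length(sets), length(sampleCols),
                dimnames = list(names(sets), sampleCols))
    for (s in seq_along(sampleCols)) {
        bg <- background[, s]
        col <- probes[[sampleCols[s]]]
        for (i in seq_along(sets))
            p[i, s] <- detectionPValue(col[sets[[i]]], bg, tau,
                                       probeSetId = names(sets)[i])
    }
    p
}

#' Filter features by detection across arrays
#'
#' Retains a feature when it is detected (`p < alpha`) in at least
#' `minArrays` arrays; the paper-style rule is "expressed in at least 6
#' arrays at p < 0.05". Output order follows the input order.
#'
#' @param detectionP matrix of detection p-values, features x samples.
#' @param minArrays minimum number of arrays with detection (default 6).
#' @param alpha detection threshold (default 0.05).
#' @return character vector of retained feature ids.
#' @export
filterExpressed <- function(detectionP, minArrays = 6, alpha = 0.05) {
    if (!nrow(detectionP)) {
        warning("empty detection table: nothing to retain")
        return(character())
    }
    if (minArrays > ncol(detectionP))
        stop("minArrays exceeds the number of samples")
    nDetected <- rowSums(detectionP < alpha)
    rownames(detectionP)[nDetected >= minArrays]
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column onto the common reference distribution (the
#' cross-column mean of sorted values); ties within a column receive the mean
#' of the reference values at their rank positions. Column-wise rank order is
#' preserved. Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat numeric matrix, features x samples, >= 2 samples, no missing
#'   values.
#' @return normalized matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3), b = c(2, 4)))  # both columns 1.5, 3.5
#' @export
quantileNormalize <- function(mat) {
    mat <- as.matrix(mat)
    if (ncol(mat) < 2) stop("need >= 2 samples")
    if (anyNA(mat)) stop("missing values are not supported")
    out <- limma::normalizeQuantiles(mat, ties = TRUE)
    dimnames(out) <- dimnames(mat)
    out
}

#' Median-polish summarization of one probe set
#'
#' Fits the additive model `value[i, j] ~ overall + probe[i] + sample[j]` by
#' Tukey median polish (via [stats::medpolish()]) and returns the per-sample
#' summary `overall + sample[j]`, the RMA summarization step. Input is
#' expected on the log2 scale.
#'
#' @param probeLevel numeric matrix, probes x samples, for one probe set.
#' @param maxIter maximum sweep iterations (default 10).
#' @param tol convergence tolerance on the residual improvement
#'   (default 0.01).
#' @return named numeric vector of per-sample log2 expression.
#' @export
medianPolishSummarize <- function(probeLevel, maxIter = 10, tol = 0.01) {
    probeLevel <- as.matrix(probeLevel)
    if (any(!is.finite(probeLevel))) stop("non-finite probe-level values")
    if (nrow(probeLevel) == 1L)
        return(setNames(as.numeric(probeLevel[1, ]), colnames(probeLevel)))
    fit <- stats::medpolish(probeLevel, eps = tol, maxiter = maxIter,
                            trace.iter = FALSE, na.rm = FALSE)
    setNames(fit$overall + fit$col, colnames(probeLevel))
}

#' RMA-style preprocessing of a probe-level table
#'
#' Runs the canonical stage order: optional normexp background correction,
#' quantile normalization, log2, per-probe-set median polish. Also computes
#' detection p-values against the background probes (on the raw scale, as
#' detection is defined there).
#'
#' @param probes probe-level table as in [detectionCalls()].
#' @param background background-probe matrix (required for detection; also
#'   used by nothing else).
#' @param backgroundCorrect logical; apply normexp background correction
#'   before normalization (default `FALSE`).
#' @param tau detection offset.
#' @return list with `expr` (probe sets x samples log2 matrix),
#'   `detectionP` (same shape), and `quality` (see [arrayQualityReport()]).
#' @export
rmaPreprocess <- function(probes, background, backgroundCorrect = FALSE,
                          tau = 0.015) {
    sampleCols <- setdiff(colnames(probes), c("probe_set_id", "probe_index"))
    m <- as.matrix(probes[, sampleCols, drop = FALSE])
    if (any(m <= 0)) stop("raw intensities must be positive")
    detectionP <- detectionCalls(probes, background, tau = tau)
    if (backgroundCorrect)
        m <- limma::backgroundCorrect.matrix(m, method = "normexp",
                                             verbose = FALSE)
    m <- log2(quantileNormalize(m))
    sets <- split(seq_len(nrow(probes)), probes$probe_set_id)
    expr <- t(vapply(sets, function(i)
        medianPolishSummarize(m[i, , drop = FALSE]),
        numeric(length(sampleCols))))
    colnames(expr) <- sampleCols
    list(expr = expr, detectionP = detectionP,
         quality = arrayQualityReport(expr))
}

#' Per-array quality report
#'
#' Summary statistics used to screen for outlier arrays (a judgment call the
#' analyst makes; nothing is excluded automatically): per-array mean, median,
#' quartiles of expression and the first two principal-component coordinates
#' of the sample cloud.
#'
#' @param expr log2 expression matrix, features x samples.
#' @return data.frame with one row per array.
#' @export
arrayQualityReport <- function(expr) {
    expr <- as.matrix(expr)
    q <- t(apply(expr, 2, quantile, probs = c(0.25, 0.5, 0.75)))
    pcs <- if (nrow(expr) >= 2) {
        p <- prcomp(t(expr), center = TRUE, scale. = FALSE)
        k <- min(2, ncol(p$x))
        cbind(p$x[, seq_len(k), drop = FALSE],
              matrix(NA_real_, ncol(expr), 2 - k))
    } else matrix(NA_real_, ncol(expr), 2)
    data.frame(sample_id = colnames(expr),
               mean = colMeans(expr),
               q25 = q[, 1], median = q[, 2], q75 = q[, 3],
               pc1 = pcs[, 1], pc2 = pcs[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Species tags admitted by the default probe filter
#'
#' miRBase-style species prefixes for humans, apes and Old World monkeys;
#' probes from any other species are excluded by [annotateAndDedupe()]
#' unless a different allowed set is supplied.
#'
#' @return character vector of species prefixes.
#' @export
primateSpeciesTags <- function() {
    c("hsa",                                  # human
      "ptr", "ppa", "ggo", "ppy", "ssy",      # great + lesser apes
      "mml", "mne", "sla", "age", "pha", "pbi")  # Old World monkeys
}

#' Species filtering and sequence-level deduplication
#'
#' The uniqueness funnel: (1) drop features whose species tag is outside the
#' allowed set; (2) group the rest by identical mature sequence (U/T
#' normalized, case-insensitive); (3) emit one feature per group, named by
#' the human (`hsa-`) miRBase name when one exists, otherwise the
#' lexicographically smallest name; (4) report the funnel counts.
#'
#' @param retainedIds feature ids surviving the expression filter.
#' @param annotation data.frame with columns `feature_id`, `species`,
#'   `mirbase_name`, `sequence`.
#' @param allowedSpecies character vector of admitted species tags.
#' @return list with `features` (data.frame `feature_id`, `canonical_name`,
#'   `sequence`, `n_merged`; `feature_id` is the representative probe) and
#'   `funnel` (data.frame `step`, `retained`).
#' @export
annotateAndDedupe <- function(retainedIds, annotation,
                              allowedSpecies = primateSpeciesTags()) {
    i <- match(retainedIds, annotation$feature_id)
    if (anyNA(i))
        stop("missing annotation for: ",
             paste(head(retainedIds[is.na(i)], 10), collapse = ", "))
    ann <- annotation[i, , drop = FALSE]
    n0 <- nrow(ann)
    ann <- ann[ann$species %in% allowedSpecies, , drop = FALSE]
    n1 <- nrow(ann)
    seqKey <- toupper(gsub("U", "T", ann$sequence, ignore.case = TRUE))
    if (any(!nzchar(seqKey))) stop("empty sequence in annotation")
    groups <- split(seq_len(nrow(ann)), seqKey)
    rep1 <- lapply(groups, function(g) {
        nm <- ann$mirbase_name[g]
        human <- grepl("^hsa-", nm)
        pick <- if (any(human)) g[human][order(nm[human])][1]
                else g[order(nm)][1]
        data.frame(feature_id = ann$feature_id[pick],
                   canonical_name = ann$mirbase_name[pick],
                   sequence = ann$sequence[pick],
                   n_merged = length(g), stringsAsFactors = FALSE)
    })
    feats <- do.call(rbind, rep1)
    feats <- feats[order(feats$canonical_name), , drop = FALSE]
    rownames(feats) <- NULL
    funnel <- data.frame(
        step = c("expressed", "species_filtered", "unique_sequence"),
        retained = c(n0, n1, nrow(feats)), stringsAsFactors = FALSE)
    list(features = feats, funnel = funnel)
}
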