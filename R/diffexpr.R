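#' Per-feature two-factor unbalanced ANOVA
#'
#' Fits the full-factorial model `expr ~ age * exposure` to every feature by
#' least squares under sum-to-zero contrasts and reports Type III F tests
#' for the two main effects and the interaction (for these one-degree-of-
#' freedom terms the Type III model-comparison F equals the squared Wald t
#' of the coefficient in the full model). Fold changes are contrasts of
#' unweighted cell means, so sample imbalance does not bias them:
#' `log2fc_alcohol` is the mean of the two PAE cell means minus the mean of
#' the two control cell means, and `log2fc_age` the 2yr marginal minus the
#' 5mo marginal.
#'
#' Features with zero residual variance get `p = 0` when the corresponding
#' effect is nonzero and `p = 1` otherwise, and are flagged in
#' `zero_variance`.
#'
#' @param expr [MirExperiment-class] or log2 matrix (features x samples).
#' @param design data.frame (`sample_id`, `age`, `exposure`); ignored when
#'   `expr` is a `MirExperiment`. Every design cell needs >= 2 samples.
#' @return data.frame with columns `feature_id`, `log2fc_alcohol`,
#'   `log2fc_age`, `p_alcohol`, `p_age`, `p_interaction`, `se_alcohol`,
#'   `zero_variance`. q-values and DE classes are added by
#'   [storeyQValues()] / [selectDE()].
#' @examples
#' ds <- simulatePairedData(synthConfig(nMirna = 30, nGene = 0,
#'                                      targetsPerMirna = 0, seed = 2))
#' res <- fitTwoFactorAnova(ds$mirna)
#' head(res)
#' @export
fitTwoFactorAnova <- function(expr, design = NULL) {
    if (is(expr, "MirExperiment")) {
        design <- designFactors(expr)
        mat <- exprMatrix(expr)
    } else {
        mat <- as.matrix(expr)
        if (is.null(design)) stop("'design' required for a plain matrix")
        design <- design[match(colnames(mat), design$sample_id), , drop = FALSE]
        if (anyNA(design$sample_id))
            stop("design does not cover all expression columns")
    }
    if (any(!is.finite(mat))) stop("non-finite expression values")
    age <- factor(design$age, levels = c("5mo", "2yr"))
    exposure <- factor(design$exposure, levels = c("control", "PAE"))
    cells <- table(age, exposure)
    if (any(cells < 2))
        stop("every design cell needs >= 2 samples (no residual df otherwise)")

    X <- model.matrix(~ age * exposure,
                      data = data.frame(age, exposure),
                      contrasts.arg = list(age = "contr.sum",
                                           exposure = "contr.sum"))
    XtXinv <- solve(crossprod(X))
    B <- mat %*% t(XtXinv %*% t(X))          # features x 4 coefficients
    rss <- rowSums((mat - B %*% t(X))^2)
    dfRes <- ncol(mat) - ncol(X)
    sigma2 <- rss / dfRes
    vd <- diag(XtXinv)

    # unweighted cell means
    cellMean <- function(a, e) rowMeans(mat[, age == a & exposure == e,
                                            drop = FALSE])
    mC5 <- cellMean("5mo", "control"); mP5 <- cellMean("5mo", "PAE")
    mC2 <- cellMean("2yr", "control"); mP2 <- cellMean("2yr", "PAE")
    lfcAlc <- (mP5 + mP2) / 2 - (mC5 + mC2) / 2
    lfcAge <- (mC2 + mP2) / 2 - (mC5 + mP5) / 2

    zv <- sigma2 < 1e-12
    pOf <- function(k) {
        Fst <- B[, k]^2 / (sigma2 * vd[k])
        p <- pf(Fst, 1, dfRes, lower.tail = FALSE)
        p[zv] <- ifelse(abs(B[zv, k]) > 1e-8, 0, 1)
        p
    }
    # column order from model.matrix: (Intercept), age1, exposure1, age1:exposure1
    seAlc <- sqrt(sigma2 * vd[3]) * 2  # contrast = -2 * exposure1 coefficient
    data.frame(feature_id = rownames(mat),
               log2fc_alcohol = lfcAlc, log2fc_age = lfcAge,
               p_alcohol = pOf(3), p_age = pOf(2), p_interaction = pOf(4),
               se_alcohol = seAlc,
               zero_variance = zv,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Storey q-values with smoothed null-proportion estimate
#'
#' Converts p-values to q-values. The null proportion `pi0` is estimated as
#' `mean(p > lambda) / (1 - lambda)` over a lambda grid, smoothed with a
#' natural cubic smoothing spline (df = 3) and evaluated at the largest
#' lambda, then clamped to `(0, 1]`; estimates above 1 (or failed fits) fall
#' back to `pi0 = 1`, where the procedure reduces exactly to
#' Benjamini-Hochberg. `q_i = min over p_j >= p_i of pi0 * m * p_j /
#' rank(p_j)`, capped at 1; the mapping is order-preserving.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param lambda grid for the pi0 estimate (default `seq(0, 0.90, 0.05)`).
#' @param pi0 optional fixed null proportion, bypassing estimation
#'   (e.g. `pi0 = 1` for plain BH).
#' @return numeric vector of q-values with attribute `pi0`.
#' @examples
#' storeyQValues(c(0.01, 0.02, 0.03, 0.9), pi0 = 1)  # BH: 0.04 0.04 0.04 0.9
#' @export
storeyQValues <- function(p, lambda = seq(0, 0.90, by = 0.05), pi0 = NULL) {
    if (!length(p)) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (is.null(pi0)) {
        pi0Grid <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
        pi0 <- tryCatch({
            fit <- smooth.spline(lambda, pi0Grid, df = 3)
            predict(fit, x = max(lambda))$y
        }, error = function(e) 1)
        if (!is.finite(pi0) || pi0 > 1) pi0 <- 1
        pi0 <- max(pi0, .Machine$double.eps)
    } else {
        if (pi0 <= 0 || pi0 > 1) stop("pi0 must be in (0, 1]")
    }
    o <- order(p, decreasing = TRUE)
    r <- rank(p, ties.method = "max")
    q <- numeric(m)
    q[o] <- pmin(1, cummin(pi0 * m * p[o] / r[o]))
    attr(q, "pi0") <- pi0
    q
}

#' Select differentially expressed features
#'
#' Applies the printed selection rule strictly: `p < pThresh` and
#' `|log2fc| > lfcThresh` (both strict inequalities). Returns the up- and
#' down-regulated lists sorted by ascending p and stamps `de_class` on the
#' result table.
#'
#' @param results data.frame from [fitTwoFactorAnova()].
#' @param pThresh p-value threshold (default 0.05).
#' @param lfcThresh absolute log2-fold-change threshold (default 1).
#' @param factor which main effect to classify on: `"alcohol"` or `"age"`.
#' @return list with `up`, `down` (character vectors of feature ids, sorted
#'   by ascending p) and `results` (input with a `de_class` column).
#' @export
selectDE <- function(results, pThresh = 0.05, lfcThresh = 1,
                     factor = c("alcohol", "age")) {
    factor <- match.arg(factor)
    p <- results[[paste0("p_", factor)]]
    lfc <- results[[paste0("log2fc_", factor)]]
    if (is.null(p) || is.null(lfc))
        stop("results lack the columns for factor '", factor, "'")
    up <- p < pThresh & lfc > lfcThresh
    down <- p < pThresh & lfc < -lfcThresh
    results$de_class <- ifelse(up, "up", ifelse(down, "down", "none"))
    ord <- function(sel) results$feature_id[sel][order(p[sel])]
    list(up = ord(up), down = ord(down), results = results)
}

#' Select the matched non-DE control list
#'
#' Builds the negative-control miRNA list for the residual fold-change
#' analysis: after excluding features with a strong interaction effect
#' (`p_interaction < interactionAlpha`), the `k` features with the highest
#' main-effect p-values (approaching 1) are taken, tie-broken by feature id.
#'
#' @param results data.frame from [fitTwoFactorAnova()].
#' @param k list size (default 24).
#' @param interactionAlpha interaction-effect exclusion threshold
#'   (default 0.05).
#' @param factor main effect whose p-values are ranked (default alcohol).
#' @return character vector of `k` feature ids.
#' @export
selectControlList <- function(results, k = 24, interactionAlpha = 0.05,
                              factor = c("alcohol", "age")) {
    factor <- match.arg(factor)
    eligible <- results[results$p_interaction >= interactionAlpha, , drop = FALSE]
    if (nrow(eligible) < k)
        stop("only ", nrow(eligible), " features eligible after the ",
             "interaction filter; ", k, " requested")
    p <- eligible[[paste0("p_", factor)]]
    o <- order(-p, eligible$feature_id)
    eligible$feature_id[o][seq_len(k)]
}

#' Expected number of sub-threshold tests under the global null
#'
#' `floor(alpha * nTests)`: the count of p-values below `alpha` one would
#' expect if the factor had no effect on any feature, e.g. 30 for 613 tests
#' at alpha = 0.05.
#'
#' @param nTests number of tests (>= 0).
#' @param alpha significance level in (0, 1).
#' @return integer.
#' @examples
#' expectedNullCount(613, 0.05)  # 30
#' @export
expectedNullCount <- function(nTests, alpha = 0.05) {
    if (nTests < 0) stop("nTests must be >= 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
    as.integer(floor(alpha * nTests))
}
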