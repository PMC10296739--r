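# Small configurations used across test files. Sizes are kept small so the
# suite runs quickly; the acceptance tests use the full default conditions.

smallConfig <- function(seed = 42, ...) {
    synthConfig(nMirna = 60, nGene = 300, targetsPerMirna = 30,
                seed = seed, ...)
}

# a tiny balanced design table
toyDesign <- function(nPerCell = 3) {
    cells <- rep(nPerCell, 4)
    data.frame(
        sample_id = paste0("s", seq_len(sum(cells))),
        age = rep(c("5mo", "5mo", "2yr", "2yr"), cells),
        exposure = rep(c("control", "PAE", "control", "PAE"), cells),
        stringsAsFactors = FALSE)
}

# expression matrix with given cell means plus optional noise
toyExpr <- function(design, cellMeans, noise = 0, nFeatures = 1,
                    seed = 1) {
    withr::with_seed(seed, {
        key <- paste(design$age, design$exposure)
        mu <- cellMeans[key]
        m <- matrix(rep(mu, each = nFeatures), nFeatures, nrow(design)) +
            matrix(rnorm(nFeatures * nrow(design), 0, noise),
                   nFeatures, nrow(design))
        dimnames(m) <- list(paste0("f", seq_len(nFeatures)), design$sample_id)
        m
    })
}

# exact one-sided rank-sum tail by enumeration of all rank assignments:
# P(rank sum of group 1 >= observed) over all choose(n1+n2, n1) splits
enumRankSumP <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    obs <- sum(r[seq_along(x)])
    splits <- utils::combn(length(pooled), length(x))
    sums <- apply(splits, 2, function(i) sum(r[i]))
    mean(sums >= obs)
}
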