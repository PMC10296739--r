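#' Configuration for the paired synthetic miRNA/mRNA generator
#'
#' Defines the study conditions the generator emulates: an unbalanced 2x2
#' (age x exposure) design of 23 arrays, a set of planted exposure-responsive
#' miRNAs with a co-expressed genomic cluster among the upregulated ones, and
#' a paired mRNA fold-change table in which each gene is depressed in
#' proportion to how many distinct planted upregulated miRNAs target it.
#'
#' @param nMirna number of miRNA features after filtering (default 613).
#' @param nGene number of genes in the mRNA fold-change universe.
#' @param designCells sample counts for the four cells in the order
#'   5mo-control, 5mo-PAE, 2yr-control, 2yr-PAE (default `c(6, 6, 5, 6)`).
#' @param nDeUp,nDeDown numbers of planted up-/down-regulated miRNAs
#'   (exposure main effect; defaults 24 and 3).
#' @param deLog2fc planted log2 shift of the exposure effect (default 1.5).
#' @param suppressionBeta mean log2 depression of a gene per distinct planted
#'   upregulated miRNA targeting it (default 0.02).
#' @param noiseSd residual standard deviation of the miRNA expression
#'   values on the log2 scale (default 0.25).
#' @param mrnaNoiseSd standard deviation of the per-gene mRNA log2
#'   fold-change noise around its hit-count-determined expectation
#'   (default 0.1, the dispersion implied by the reported group statistics
#'   of the paired transcriptome).
#' @param clusterSize number of planted upregulated miRNAs forming a
#'   genomically clustered, tightly co-expressed sub-group (default 5).
#' @param clusterRho target pairwise Pearson correlation within the cluster,
#'   including the shared exposure shift (default 0.97).
#' @param clusterFactorSd amplitude (log2 sd) of the shared latent factor
#'   driving the cluster's co-expression beyond the exposure effect
#'   (default 0.6); the members' residual noise is solved so that their
#'   total pairwise correlation hits `clusterRho`. The factor is drawn
#'   orthogonal to the design, so it models exposure-independent
#'   co-regulation of the genomic cluster.
#' @param mapOverlap probability that an edge of the primary target map also
#'   appears in the second (replication-algorithm) map (default 0.7).
#' @param targetsPerMirna mean number of distinct predicted targets per
#'   miRNA (default 1000).
#' @param geneWeightShape shape of the Gamma-distributed per-gene
#'   "targetability" weights that make some genes recurrent targets of many
#'   miRNAs (default 0.62; together with `nGene` and `targetsPerMirna` this
#'   is calibrated so the 24 planted miRNAs collectively target ~8200
#'   distinct genes and the DE-vs-control target-count correlation is ~0.7;
#'   see the methods vignette).
#' @param seed integer RNG seed; identical configurations reproduce
#'   bit-identical datasets.
#'
#' @return A validated list of class `SynthConfig`.
#' @seealso [simulatePairedData()], [simulateProbeLevel()], [writeFixture()]
#' @export
synthConfig <- function(nMirna = 613, nGene = 15000,
                        designCells = c(6, 6, 5, 6),
                        nDeUp = 24, nDeDown = 3,
                        deLog2fc = 1.5, suppressionBeta = 0.02,
                        noiseSd = 0.25, mrnaNoiseSd = 0.1,
                        clusterSize = 5, clusterRho = 0.97,
                        clusterFactorSd = 0.6,
                        mapOverlap = 0.7, targetsPerMirna = 1000,
                        geneWeightShape = 0.62,
                        seed = 1L) {
    cfg <- list(nMirna = as.integer(nMirna), nGene = as.integer(nGene),
                designCells = as.integer(designCells),
                nDeUp = as.integer(nDeUp), nDeDown = as.integer(nDeDown),
                deLog2fc = deLog2fc, suppressionBeta = suppressionBeta,
                noiseSd = noiseSd, mrnaNoiseSd = mrnaNoiseSd,
                clusterSize = as.integer(clusterSize),
                clusterRho = clusterRho,
                clusterFactorSd = clusterFactorSd,
                mapOverlap = mapOverlap,
                targetsPerMirna = targetsPerMirna,
                geneWeightShape = geneWeightShape,
                seed = as.integer(seed))
    if (cfg$nMirna < 1 || cfg$nGene < 0)
        stop("feature counts must be positive")
    if (length(cfg$designCells) != 4L)
        stop("designCells must have four entries")
    if (any(cfg$designCells < 1L))
        stop("every design cell must have at least one sample (ANOVA undefined)")
    if (sum(cfg$designCells) < 4L)
        stop("fewer than 4 samples: ANOVA undefined")
    if (cfg$nDeUp < 0 || cfg$nDeDown < 0 ||
        cfg$nDeUp + cfg$nDeDown > cfg$nMirna)
        stop("nDeUp + nDeDown must not exceed nMirna")
    if (cfg$mapOverlap < 0 || cfg$mapOverlap > 1)
        stop("mapOverlap must be in [0, 1]")
    if (cfg$clusterRho <= 0 || cfg$clusterRho >= 1)
        stop("clusterRho must be in (0, 1)")
    if (cfg$clusterFactorSd < 0) stop("clusterFactorSd must be >= 0")
    if (cfg$noiseSd <= 0) stop("noiseSd must be > 0")
    if (cfg$mrnaNoiseSd <= 0) stop("mrnaNoiseSd must be > 0")
    if (cfg$clusterSize > max(cfg$nDeUp, 1L))
        stop("clusterSize cannot exceed nDeUp")
    if (cfg$targetsPerMirna < 0 || cfg$geneWeightShape <= 0)
        stop("targetsPerMirna must be >= 0 and geneWeightShape > 0")
    structure(cfg, class = "SynthConfig")
}

# Sample ids and design table for the four cells.
.synthDesign <- function(cells) {
    lab <- c("CONT5", "PAE5", "CONT2", "PAE2")
    age <- c("5mo", "5mo", "2yr", "2yr")
    exposure <- c("control", "PAE", "control", "PAE")
    data.frame(
        sample_id = unlist(lapply(1:4, function(i)
            paste0(lab[i], "_", seq_len(cells[i])))),
        age = rep(age, cells),
        exposure = rep(exposure, cells),
        stringsAsFactors = FALSE)
}

# Residual sd for cluster members so that their TOTAL pairwise correlation
# (shared exposure shift, variance v_s = fc^2 p(1-p), plus shared factor of
# variance v_f) hits rho: corr = (v_s + v_f) / (v_s + v_f + s_r^2).
.clusterResidSd <- function(rho, fc, pExposed, factorSd) {
    vShared <- fc^2 * pExposed * (1 - pExposed) + factorSd^2
    sqrt(max(vShared * (1 - rho) / rho, 1e-8))
}

# One random target map: independent Bernoulli edges with gene-specific
# probability proportional to the gene's targetability weight, scaled so the
# expected out-degree per miRNA is meanDeg.
.drawMap <- function(mirnaIds, geneIds, edgeProb, tag) {
    nm <- length(mirnaIds); ng <- length(geneIds)
    hit <- which(runif(nm * ng) < rep(edgeProb, each = nm))
    TargetMap(mirnaIds[(hit - 1L) %% nm + 1L],
              geneIds[(hit - 1L) %/% nm + 1L], tag)
}

#' Generate a seeded paired miRNA/mRNA dataset with ground truth
#'
#' Produces a log2 miRNA expression matrix over the 2x2 design, a paired
#' per-gene mRNA log2 fold-change table, feature annotation, two overlapping
#' target-prediction maps (standing in for two distinct prediction
#' algorithms), and a truth record for parameter-recovery testing.
#'
#' Planted upregulated miRNAs receive a `+deLog2fc` shift in exposed (PAE)
#' samples and downregulated ones `-deLog2fc`; the first `clusterSize`
#' upregulated miRNAs additionally share a latent factor (and a common
#' genomic window on chromosome 24) so that their total pairwise correlation
#' is approximately `clusterRho`. Each gene's mRNA log2 fold change is
#' `-suppressionBeta * h(g) + Normal(0, mrnaNoiseSd)` where `h(g)` is the number
#' of distinct planted upregulated miRNAs targeting the gene in the primary
#' map. The second map keeps each primary edge with probability `mapOverlap`
#' and refills the lost out-degree with fresh weighted draws.
#'
#' @param cfg a [synthConfig()] object.
#' @return A list with elements `mirna` ([MirExperiment-class]),
#'   `mrnaFoldChange` (data.frame `gene_id`, `log2fc`), `design`,
#'   `annotation`, `maps` (list of two [TargetMap-class]: `targetscan7`,
#'   `mirwalk3`) and `truth` (planted ids, per-gene hit counts and expected
#'   depression, seed).
#' @examples
#' ds <- simulatePairedData(synthConfig(nMirna = 50, nGene = 200,
#'                                      targetsPerMirna = 20, seed = 7))
#' ds$mirna
#' head(ds$mrnaFoldChange)
#' @export
simulatePairedData <- function(cfg) {
    stopifnot(inherits(cfg, "SynthConfig"))
    withr::with_seed(cfg$seed, .simulatePairedDataImpl(cfg))
}

.simulatePairedDataImpl <- function(cfg) {
    design <- .synthDesign(cfg$designCells)
    n <- nrow(design)
    exposed <- design$exposure == "PAE"

    mirnaIds <- sprintf("mir%04d", seq_len(cfg$nMirna))
    geneIds <- sprintf("GENE%05d", seq_len(cfg$nGene))

    deUp <- if (cfg$nDeUp) sample(mirnaIds, cfg$nDeUp) else character()
    deDown <- if (cfg$nDeDown)
        sample(setdiff(mirnaIds, deUp), cfg$nDeDown) else character()
    clusterIds <- head(deUp, cfg$clusterSize)

    baseline <- runif(cfg$nMirna, 4, 12)
    shift <- numeric(cfg$nMirna)
    shift[match(deUp, mirnaIds)] <- cfg$deLog2fc
    shift[match(deDown, mirnaIds)] <- -cfg$deLog2fc

    eps <- matrix(rnorm(cfg$nMirna * n, 0, cfg$noiseSd), cfg$nMirna, n)
    # cluster members share a latent expression factor beyond the exposure
    # effect; their residual sd is solved so total pairwise corr = clusterRho.
    # The factor models exposure-independent co-regulation, so it is drawn
    # orthogonal to the design (in sample) and standardized.
    if (length(clusterIds) >= 2) {
        sr <- .clusterResidSd(cfg$clusterRho, cfg$deLog2fc,
                              mean(exposed), cfg$clusterFactorSd)
        X <- model.matrix(~ design$age * design$exposure)
        f <- rnorm(n)
        f <- f - X %*% solve(crossprod(X), crossprod(X, f))
        f <- as.numeric(f) / sd(f)
        ci <- match(clusterIds, mirnaIds)
        eps[ci, ] <- cfg$clusterFactorSd *
            matrix(f, length(ci), n, byrow = TRUE) +
            sr * matrix(rnorm(length(ci) * n), length(ci), n)
    }
    expr <- baseline + outer(shift, as.numeric(exposed)) + eps
    dimnames(expr) <- list(mirnaIds, design$sample_id)

    annotation <- .synthAnnotation(mirnaIds, clusterIds)

    # target maps; gene weights shared across miRNAs create recurrent targets
    w <- if (cfg$nGene) rgamma(cfg$nGene, shape = cfg$geneWeightShape) else numeric()
    edgeProb <- if (cfg$nGene)
        pmin(cfg$targetsPerMirna * w / sum(w), 1) else numeric()
    map1 <- .drawMap(mirnaIds, geneIds, edgeProb, "targetscan7")
    map2 <- .resampleMap(map1, mirnaIds, geneIds, edgeProb,
                         cfg$mapOverlap, "mirwalk3")

    hits1 <- .truthHits(map1, deUp, geneIds)
    hits2 <- .truthHits(map2, deUp, geneIds)
    depression <- -cfg$suppressionBeta * hits1
    mrnaFoldChange <- data.frame(
        gene_id = geneIds,
        log2fc = depression + rnorm(cfg$nGene, 0, cfg$mrnaNoiseSd),
        stringsAsFactors = FALSE)

    truth <- list(
        de_up_ids = deUp, de_down_ids = deDown, cluster_ids = clusterIds,
        hit_count = setNames(hits1, geneIds),
        hit_count_map2 = setNames(hits2, geneIds),
        depression = setNames(depression, geneIds),
        suppression_beta = cfg$suppressionBeta,
        de_log2fc = cfg$deLog2fc, seed = cfg$seed)

    list(mirna = MirExperiment(expr, design, annotation),
         mrnaFoldChange = mrnaFoldChange,
         design = design, annotation = annotation,
         maps = list(targetscan7 = map1, mirwalk3 = map2),
         truth = truth)
}

# number of distinct miRNAs from `list` targeting each gene of the universe
.truthHits <- function(map, mirnaList, geneUniverse) {
    e <- targetEdges(map)
    e <- e[e$mirna %in% mirnaList, , drop = FALSE]
    tab <- table(factor(e$gene, levels = geneUniverse))
    as.integer(tab)
}

# Replication-algorithm map: keep each primary edge with probability
# `overlap`, and draw fresh edges over the remaining pairs at rate
# (1 - overlap) * edgeProb so the expected out-degree is preserved.
.resampleMap <- function(map, mirnaIds, geneIds, edgeProb, overlap, tag) {
    e <- targetEdges(map)
    keep <- runif(nrow(e)) < overlap
    nm <- length(mirnaIds); ng <- length(geneIds)
    fresh <- which(runif(nm * ng) < rep((1 - overlap) * edgeProb, each = nm))
    lin1 <- (match(e$gene, geneIds) - 1) * nm + match(e$mirna, mirnaIds)
    fresh <- fresh[!fresh %in% lin1]
    TargetMap(c(e$mirna[keep], mirnaIds[(fresh - 1L) %% nm + 1L]),
              c(e$gene[keep], geneIds[(fresh - 1L) %/% nm + 1L]), tag)
}

.synthAnnotation <- function(mirnaIds, clusterIds) {
    nm <- length(mirnaIds)
    chrom <- as.character(sample(1:29, nm, replace = TRUE))
    # positions below 2 Mb are reserved for the planted cluster window, so
    # that coordinate-based membership (chrom 24, window [0, 2e6)) recovers
    # exactly the planted members
    start <- sample(2e6:5e7, nm)
    ci <- match(clusterIds, mirnaIds)
    if (length(ci)) {
        chrom[ci] <- "24"
        start[ci] <- 1e6 + (seq_along(ci) - 1L) * 2000L
    }
    bases <- c("A", "C", "G", "U")
    seqs <- vapply(seq_len(nm), function(i)
        paste(sample(bases, 22, replace = TRUE), collapse = ""), "")
    data.frame(
        feature_id = mirnaIds,
        species = "hsa",
        mirbase_name = paste0("hsa-miR-", sub("^mir0*", "", mirnaIds)),
        sequence = seqs,
        chrom = chrom, start = start, end = start + 22L,
        strand = sample(c("+", "-"), nm, replace = TRUE),
        stringsAsFactors = FALSE)
}

#' Generate probe-level intensities with background probes
#'
#' Builds a fixture for the detection-call and RMA stages: per-probe raw
#' intensities for a set of probe sets over the configured design, plus a
#' table of background-probe intensities per sample. "Present" probe sets
#' are drawn above the background distribution; "absent" ones from it.
#' Truth labels are recorded.
#'
#' @param cfg a [synthConfig()]; `nMirna`, `designCells`, `seed` are used.
#' @param probesPerSet probes per probe set (>= 4).
#' @param presentFraction fraction of probe sets that carry real signal.
#' @param signalFold median fold elevation of present sets over background.
#' @param nBackground number of background probes per sample.
#' @return list with `probes` (data.frame: `probe_set_id`, `probe_index`,
#'   one column per sample), `background` (matrix background-probes x
#'   samples), `design`, and `truth` (data.frame `probe_set_id`, `present`).
#' @export
simulateProbeLevel <- function(cfg, probesPerSet = 9,
                               presentFraction = 0.5,
                               signalFold = 10, nBackground = 100) {
    stopifnot(inherits(cfg, "SynthConfig"))
    if (probesPerSet < 4) stop("probesPerSet must be >= 4")
    if (presentFraction < 0 || presentFraction > 1)
        stop("presentFraction must be in [0, 1]")
    if (nBackground < 4) stop("nBackground must be >= 4")
    withr::with_seed(cfg$seed, {
        design <- .synthDesign(cfg$designCells)
        n <- nrow(design)
        ids <- sprintf("ps%04d", seq_len(cfg$nMirna))
        present <- runif(cfg$nMirna) < presentFraction
        bgMeanlog <- log(50)
        background <- matrix(
            rlnorm2(nBackground * n, bgMeanlog, 0.4), nBackground, n,
            dimnames = list(NULL, design$sample_id))
        sets <- lapply(seq_len(cfg$nMirna), function(i) {
            ml <- if (present[i]) bgMeanlog + log(signalFold) else bgMeanlog
            probeEff <- rnorm(probesPerSet, 0, 0.2)
            matrix(rlnorm2(probesPerSet * n, ml + probeEff, 0.4),
                   probesPerSet, n)
        })
        probes <- data.frame(
            probe_set_id = rep(ids, each = probesPerSet),
            probe_index = rep(seq_len(probesPerSet), cfg$nMirna),
            do.call(rbind, sets),
            stringsAsFactors = FALSE)
        colnames(probes)[-(1:2)] <- design$sample_id
        list(probes = probes, background = background, design = design,
             truth = data.frame(probe_set_id = ids, present = present,
                                stringsAsFactors = FALSE))
    })
}

# lognormal draws with vector meanlog recycled per row
rlnorm2 <- function(n, meanlog, sdlog) exp(rnorm(n, meanlog, sdlog))
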