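# brute-force Ward (ward.D) agglomeration via the Lance-Williams update,
# written independently of stats::hclust
wardOracle <- function(d) {
    D <- as.matrix(d)
    n <- nrow(D)
    size <- rep(1, n)
    active <- seq_len(n)
    heights <- numeric(n - 1)
    for (step in seq_len(n - 1)) {
        best <- c(NA, NA); bestH <- Inf
        for (a in seq_along(active)) for (b in seq_len(a - 1)) {
            i <- active[a]; j <- active[b]
            if (D[i, j] < bestH) { bestH <- D[i, j]; best <- c(i, j) }
        }
        i <- best[1]; j <- best[2]
        heights[step] <- bestH
        for (k in setdiff(active, c(i, j))) {
            D[i, k] <- D[k, i] <-
                ((size[k] + size[i]) * D[k, i] +
                 (size[k] + size[j]) * D[k, j] -
                 size[k] * D[i, j]) / (size[k] + size[i] + size[j])
        }
        size[i] <- size[i] + size[j]
        active <- setdiff(active, j)
    }
    heights
}

test_that("reference building selects markers and strips confounders", {
    cfg <- smallConfig(markerFold = 12, cellsPerType = 100L)
    ref <- simulateSingleCellReference(cfg)
    rp <- buildReference(ref, topN = 150)
    expect_equal(length(selectedGenes(rp)), 150)
    # marker genes dominate the high-variance panel, for every type
    hitRate <- vapply(S4Vectors::metadata(ref)$markers, function(mk)
        mean(mk %in% selectedGenes(rp)), numeric(1))
    expect_gt(mean(hitRate), 0.8)
    expect_true(all(hitRate > 0.6))
    expect_equal(malignantType(rp), "EAC")
    expect_true(all(rnaContent(rp) > 0))
    # topN >= gene count keeps everything
    rpAll <- buildReference(ref, topN = 1e6)
    expect_equal(length(selectedGenes(rpAll)), nrow(ref))
    # confounder gene IDs are removed from the profile entirely
    counts <- as.matrix(SummarizedExperiment::assay(ref, "counts"))
    rownames(counts)[1:3] <- c("MT-CO1", "RPS9", "TRAV12")
    ref2 <- makeSCRef(counts, cellType(ref), isMalignant(ref))
    rp2 <- buildReference(ref2, topN = 1e6)
    expect_false(any(c("MT-CO1", "RPS9", "TRAV12") %in%
                     rownames(referenceProfiles(rp2))))
    # a type with identical cells has that cell's normalized profile
    cA <- matrix(rep(c(4, 0, 6, 10), 4), nrow = 4)
    cB <- matrix(rpois(8, 30) + 1, nrow = 4)
    toy <- makeSCRef(cbind(cA, cB),
                     cellType = rep(c("EAC", "TNK"), c(4, 2)),
                     malignant = rep(c(TRUE, FALSE), c(4, 2)))
    rownames(toy) <- paste0("g", 1:4)
    rpToy <- buildReference(toy, topN = 4, minCells = 1)
    expect_equal(unname(referenceProfiles(rpToy)[, "EAC"]),
                 c(4, 0, 6, 10) / 20 * 1e4)
    # rare types are dropped with a warning
    expect_warning(buildReference(toy, topN = 4, minCells = 3), "TNK")
})

test_that("NNLS recovers exact fractions on noiseless mixtures", {
    cfg <- smallConfig()
    ref <- simulateSingleCellReference(cfg)
    rp <- buildReference(ref, topN = 300)
    A <- referenceProfiles(rp)
    # pure type
    pure <- A[, "Monocyte", drop = FALSE]
    colnames(pure) <- "s1"
    est <- deconvolveNNLS(pure, rp, minOverlap = 50)
    expect_equal(unname(rnaFraction(est)[1, "Monocyte"]), 1)
    expect_lt(fitResidual(est)[1], 1e-8)
    # 50/50 mixture, exact to 1e-8
    mix <- 0.5 * A[, "EAC"] + 0.5 * A[, "TNK"]
    estM <- deconvolveNNLS(matrix(mix, dimnames = list(rownames(A), "m")),
                           rp, minOverlap = 50)
    expect_equal(unname(rnaFraction(estM)[1, c("EAC", "TNK")]),
                 c(0.5, 0.5), tolerance = 1e-8)
    expect_lt(fitResidual(estM)[1], 1e-8)
    # scale invariance
    est10 <- deconvolveNNLS(matrix(10 * mix,
                                   dimnames = list(rownames(A), "m")),
                            rp, minOverlap = 50)
    expect_equal(rnaFraction(est10), rnaFraction(estM), tolerance = 1e-10)
    expect_error(deconvolveNNLS(pure[1:20, , drop = FALSE], rp),
                 "overlap")
    zero <- matrix(0, nrow(A), 1, dimnames = list(rownames(A), "z"))
    expect_error(deconvolveNNLS(zero, rp, minOverlap = 50), "all-zero")
})

test_that("RNA-to-cell fraction conversion is exact and invertible", {
    expect_equal(rnaToCellFraction(c(0.5, 0.5), c(2, 1)), c(1 / 3, 2 / 3))
    expect_equal(rnaToCellFraction(c(0.3, 0.7), c(5, 5)), c(0.3, 0.7))
    f <- c(0.2, 0.5, 0.3); s <- c(2, 0.5, 1.2)
    cf <- rnaToCellFraction(f, s)
    back <- cf * s / sum(cf * s)      # inverse: multiply by s, renormalize
    expect_equal(back, f, tolerance = 1e-12)
    expect_error(rnaToCellFraction(c(0, 0), c(1, 1)), "zero denominator")
    comp <- makeComposition(matrix(c(0.5, 0.5, 0.2, 0.8), 2, byrow = TRUE,
                                   dimnames = list(c("s1", "s2"),
                                                   c("a", "b"))))
    comp2 <- rnaToCellFraction(comp, c(a = 2, b = 1))
    expect_equal(unname(cellFraction(comp2)[1, ]), c(1 / 3, 2 / 3))
    # cell-fraction scale is closer to the true cell fractions than the
    # RNA fractions are, when types differ in RNA content
    cfg <- smallConfig(seed = 21L)
    ref <- simulateSingleCellReference(cfg)
    rp <- buildReference(ref, topN = 300)
    panel <- simulatePseudobulkPanel(ref, 20, cfg)
    est <- rnaToCellFraction(
        deconvolveNNLS(normalizeLog(panel$bulk), rp, minOverlap = 50), rp)
    tr <- panel$truth$cellFraction
    tt <- colnames(tr)
    rmse <- function(m) sqrt(mean((m[, tt] - tr)^2))
    expect_lt(rmse(cellFraction(est)), rmse(rnaFraction(est)))
})

test_that("benchmark metrics are exact on perfect and reversed predictions", {
    truth <- list(
        rnaFraction = matrix(c(0.6, 0.2, 0.15, 0.05,
                               0.4, 0.3, 0.2, 0.1), 2, byrow = TRUE,
                             dimnames = list(c("s1", "s2"),
                                             c("a", "b", "c", "d"))),
        cellFraction = matrix(c(0.5, 0.3, 0.15, 0.05,
                                0.1, 0.5, 0.25, 0.15), 2, byrow = TRUE,
                              dimnames = list(c("s1", "s2"),
                                              c("a", "b", "c", "d"))))
    panel <- list(bulk = NULL, truth = truth)
    perfect <- function(b) makeComposition(truth$rnaFraction)
    bm <- benchmarkDeconvolution(list(perfect = perfect), panel)
    rna <- bm$perSample[bm$perSample$scale == "rna", ]
    expect_true(all(rna$spearman == 1))
    expect_true(all(rna$nrmse == 0))
    # reversed predictions give Spearman -1 on the RNA scale
    rev1 <- truth$rnaFraction[, 4:1]
    colnames(rev1) <- colnames(truth$rnaFraction)
    bmR <- benchmarkDeconvolution(
        list(rev = function(b) makeComposition(rev1)), panel)
    expect_true(all(bmR$perSample$spearman[
        bmR$perSample$scale == "rna"] == -1))
    # constant predictions are recorded as degenerate / missing
    unif <- matrix(0.25, 2, 4, dimnames = dimnames(truth$rnaFraction))
    bmU <- benchmarkDeconvolution(
        list(unif = function(b) makeComposition(unif)), panel)
    expect_true(all(is.na(bmU$perSample$spearman)))
    expect_true(all(bmU$perSample$degenerate))
})

test_that("NNLS beats a uniform dummy on seeded pseudobulk replicates", {
    wins <- 0L
    for (i in 1:20) {
        cfg <- smallConfig(seed = 300L + i)
        ref <- simulateSingleCellReference(cfg)
        rp <- buildReference(ref, topN = 300)
        panel <- simulatePseudobulkPanel(ref, 10, cfg)
        types <- colnames(panel$truth$rnaFraction)
        nearUnif <- matrix(rep(seq(0.19, 0.21, length.out = length(types)),
                               each = 10) /
                           sum(seq(0.19, 0.21, length.out = length(types))),
                           10, length(types),
                           dimnames = list(rownames(panel$truth$rnaFraction),
                                           types))
        bm <- benchmarkDeconvolution(list(
            nnls = function(b) deconvolveNNLS(normalizeLog(b), rp,
                                              minOverlap = 50),
            dummy = function(b) makeComposition(nearUnif)), panel)
        s <- bm$summary[bm$summary$scale == "rna", ]
        if (s$medianNRMSE[s$method == "nnls"] <
            s$medianNRMSE[s$method == "dummy"]) wins <- wins + 1L
    }
    expect_gte(wins, 19L)
    # benchmark medians do not depend on sample order
    cfg <- smallConfig(seed = 777L)
    ref <- simulateSingleCellReference(cfg)
    rp <- buildReference(ref, topN = 300)
    panel <- simulatePseudobulkPanel(ref, 8, cfg)
    m1 <- benchmarkDeconvolution(list(
        nnls = function(b) deconvolveNNLS(normalizeLog(b), rp,
                                          minOverlap = 50)), panel)
    perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
    panelP <- list(bulk = panel$bulk[, perm],
                   truth = list(rnaFraction = panel$truth$rnaFraction[perm, ],
                                cellFraction = panel$truth$cellFraction[perm, ]))
    m2 <- benchmarkDeconvolution(list(
        nnls = function(b) deconvolveNNLS(normalizeLog(b), rp,
                                          minOverlap = 50)), panelP)
    expect_equal(m1$summary$medianNRMSE, m2$summary$medianNRMSE,
                 tolerance = 1e-12)
})

test_that("TMC extraction floors zeros and tracks spiked monocyte content", {
    comp <- makeComposition(matrix(c(1, 0, 0,
                                     0, 0.5, 0.5,
                                     0.02, 0.49, 0.49), 3, byrow = TRUE,
                                   dimnames = list(paste0("s", 1:3),
                                                   c("Monocyte", "a", "b"))))
    tm <- extractTMC(comp)
    expect_equal(tm$tmc[1], 1)
    expect_equal(tm$log10Tmc[1], 0)
    expect_true(tm$floored[2])
    expect_equal(tm$log10Tmc[2], log10(0.01))  # half smallest nonzero
    expect_error(extractTMC(comp, "Macrophage"), "not found")

    cfg <- smallConfig(seed = 31L)
    ref <- simulateSingleCellReference(cfg)
    rp <- buildReference(ref, topN = 300)
    A <- referenceProfiles(rp)
    bulkProfile <- 0.7 * A[, "EAC"] + 0.3 * A[, "TNK"]
    fr <- c(0, 0.005, 0.01, 0.02, 0.04, 0.08)
    spiked <- simulateSpikeIn(bulkProfile, A[, "Monocyte"], fr)
    est <- deconvolveNNLS(spiked, rp, minOverlap = 50)
    tmc <- extractTMC(est)$tmc
    expect_true(all(diff(tmc) > 0))   # strictly increasing in spike level
    val <- spikeInValidation(spiked, rp, minOverlap = 50)
    expect_equal(val$slope, 1, tolerance = 0.2)
    expect_lt(val$pvalue, 0.01)
    one <- simulateSpikeIn(bulkProfile, A[, "Monocyte"], c(0, 0))
    expect_error(spikeInValidation(one, rp, minOverlap = 50),
                 "distinct spike levels")
})

test_that("compartment clustering recovers separated blobs and matches brute-force Ward", {
    set.seed(14)
    hi <- cbind(Monocyte = runif(5, 0.25, 0.35),
                Macrophage = runif(5, 0.15, 0.2),
                Neutrophil = runif(5, 0.07, 0.08))
    lo <- cbind(Monocyte = runif(5, 0.002, 0.008),
                Macrophage = runif(5, 0.02, 0.04),
                Neutrophil = runif(5, 0.07, 0.08))
    m <- rbind(hi, lo)
    rownames(m) <- paste0("s", 1:10)
    cl <- clusterCompartment(m, k = 2)
    expect_equal(length(unique(cl$clusters[1:5])), 1)
    expect_equal(length(unique(cl$clusters[6:10])), 1)
    expect_false(cl$clusters[1] == cl$clusters[10])
    # permutation of sample order leaves the partition intact
    perm <- sample(10)
    clP <- clusterCompartment(m[perm, ], k = 2)
    agree <- outer(cl$clusters, cl$clusters, "==")
    agreeP <- outer(clP$clusters[rownames(m)], clP$clusters[rownames(m)],
                    "==")
    expect_true(all(agree == agreeP))
    # merge heights match the independent Lance-Williams implementation
    toy <- m[1:6, ]
    clT <- clusterCompartment(toy, k = 2)
    hOracle <- wardOracle(dist(clT$scaled))
    expect_equal(clT$hclust$height, hOracle, tolerance = 1e-9)
    # constant columns are dropped with a warning
    mC <- cbind(m, Flat = 0.1)
    expect_warning(clusterCompartment(mC, k = 2), "constant")
})
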