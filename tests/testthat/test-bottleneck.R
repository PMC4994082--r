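test_that("MutationModel validates and parameterizes the multistep geometric", {
    m <- MutationModel("TPM", 0.7, 30)
    # geometric on {1,2,...} with success prob geomP has variance (1-p)/p^2
    expect_equal((1 - m$geomP) / m$geomP^2, 30)
    expect_error(MutationModel("TPM", 1.2), "pStepwise")
    expect_error(MutationModel("TPM", 0.7, -1), "multistepVar")
    expect_identical(MutationModel("IAM")$kind, "IAM")
})

test_that("IAM simulator matches the Ewens closed form for E(K)", {
    theta <- 2.4; n <- 30L
    set.seed(12)
    sims <- ampliSTR:::cpp_iam_sims(n, theta, 8000L)
    closed <- sum(theta / (theta + 0:(n - 1)))
    expect_lt(abs(mean(sims$k) - closed) / closed, 0.02)
})

test_that("simulateHeq retains the requested allele count deterministically", {
    set.seed(7)
    heq <- simulateHeq(40L, 5L, MutationModel("IAM"), nIter = 400L)
    expect_length(heq, 400L)
    expect_true(all(heq > 0 & heq < 1))
    set.seed(7)
    expect_identical(simulateHeq(40L, 5L, MutationModel("IAM"), nIter = 400L),
                     heq)
    # saturation: k = n forces all-distinct alleles and He near its ceiling
    set.seed(8)
    sat <- simulateHeq(8L, 8L, MutationModel("IAM"), nIter = 100L)
    expect_equal(stats::sd(sat), 0)
    expect_equal(sat[1], 8 / 7 * (1 - 8 * (1 / 8)^2))
    expect_error(simulateHeq(10L, 1L), "single allele")
    expect_error(simulateHeq(10L, 11L), "exceed")
})

test_that("Heq distributions shift upward with the allele count", {
    set.seed(31)
    m <- MutationModel("IAM")
    h3 <- simulateHeq(40L, 3L, m, nIter = 500L)
    h6 <- simulateHeq(40L, 6L, m, nIter = 500L)
    h10 <- simulateHeq(40L, 10L, m, nIter = 500L)
    expect_lt(mean(h3), mean(h6))
    expect_lt(mean(h6), mean(h10))
    # TPM sits below IAM at equal k (stepwise homoplasy evens frequencies
    # less), but stays a valid distribution
    set.seed(32)
    ht <- simulateHeq(40L, 6L, MutationModel("TPM"), nIter = 300L)
    expect_true(all(ht > 0 & ht < 1))
})

test_that("uniform strong excess yields the exact all-positive signed-rank p", {
    # 11 loci, each with 2 alleles at 50/50 in 30 colonies: He_obs ~ 0.51,
    # far above the equilibrium mean for k = 2, so every locus is positive
    # and the one-tailed exact p is 1/2^11
    nInd <- 30L
    a1 <- matrix(1L, 11, nInd); a2 <- matrix(2L, 11, nInd)
    dimnames(a1) <- dimnames(a2) <- list(sprintf("l%02d", 1:11),
                                         sprintf("i%02d", seq_len(nInd)))
    gm <- GenotypeMatrix(a1, a2, site = rep("P", nInd), encoding = "unique_id")
    res <- hetExcessTest(gm, "P", "site", MutationModel("IAM"),
                         nIter = 500L, seed = 10L)
    expect_identical(nrow(res$perLocus), 11L)
    expect_true(all(res$perLocus$dh > 0))
    expect_equal(res$wilcoxonP, 1 / 2^11, tolerance = 1e-9)
})

test_that("mean standardized difference is near zero at equilibrium", {
    set.seed(64)
    dhs <- c()
    for (r in 1:50) {
        a1 <- matrix(NA_integer_, 11, 30); a2 <- a1
        dimnames(a1) <- dimnames(a2) <- list(sprintf("l%02d", 1:11),
                                             sprintf("i%02d", 1:30))
        for (l in 1:11) {
            g <- sampleEquilibriumPopulation(30L, theta = 4)
            a1[l, ] <- g[, 1]; a2[l, ] <- g[, 2]
        }
        gm <- GenotypeMatrix(a1, a2, site = rep("P", 30),
                             encoding = "unique_id")
        res <- suppressWarnings(
            hetExcessTest(gm, "P", "site", MutationModel("IAM"),
                          nIter = 300L, seed = 5000L + r))
        dhs <- c(dhs, mean(res$perLocus$dh))
    }
    expect_lt(abs(mean(dhs)), 0.2)
})

test_that("mode-shift binning and verdicts follow the class rules", {
    # pooled frequencies {0.05, 0.06, 0.39, 0.5}: 100 gene copies over
    # 4 alleles with counts 5, 6, 39, 50
    copies <- rep(1:4, c(5L, 6L, 39L, 50L))
    a1 <- matrix(copies[1:50], 1, 50); a2 <- matrix(copies[51:100], 1, 50)
    dimnames(a1) <- dimnames(a2) <- list("l1", sprintf("i%02d", 1:50))
    gm <- GenotypeMatrix(a1, a2, site = rep("P", 50), encoding = "unique_id")
    ms <- modeShiftTest(gm, "P")
    expect_identical(ms$counts, c(2L, 0L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
    expect_identical(ms$verdict, "L-shaped")
    expect_identical(sum(ms$counts), 4L)
    # all alleles at 0.5: mode-shifted
    gm2 <- makeGm(rep(1L, 10), rep(2L, 10), site = rep("P", 10))
    expect_identical(modeShiftTest(gm2, "P")$verdict, "mode-shifted")
    # no polymorphic loci: undefined verdict
    gm3 <- makeGm(rep(1L, 4), rep(1L, 4), site = rep("P", 4))
    expect_true(is.na(modeShiftTest(gm3, "P")$verdict))
})

test_that("equilibrium populations are L-shaped in most replicates", {
    set.seed(77)
    nL <- 0L
    for (r in 1:100) {
        a1 <- matrix(NA_integer_, 11, 30); a2 <- a1
        dimnames(a1) <- dimnames(a2) <- list(sprintf("l%02d", 1:11),
                                             sprintf("i%02d", 1:30))
        for (l in 1:11) {
            g <- sampleEquilibriumPopulation(30L, theta = 5)
            a1[l, ] <- g[, 1]; a2[l, ] <- g[, 2]
        }
        gm <- GenotypeMatrix(a1, a2, site = rep("P", 30),
                             encoding = "unique_id")
        if (identical(modeShiftTest(gm, "P")$verdict, "L-shaped"))
            nL <- nL + 1L
    }
    expect_gte(nL, 90L)
})

test_that("a severe founder reduction is detected under IAM", {
    # equilibrium source population, then a handful of founders resampled a
    # few generations: allele count collapses faster than heterozygosity
    set.seed(90)
    hits <- 0L; nrep <- 30L
    for (r in seq_len(nrep)) {
        a1 <- matrix(NA_integer_, 11, 40); a2 <- a1
        dimnames(a1) <- dimnames(a2) <- list(sprintf("l%02d", 1:11),
                                             sprintf("i%02d", 1:40))
        for (l in 1:11) {
            src <- as.vector(sampleEquilibriumPopulation(500L, theta = 10))
            founders <- sample(src, 30L)          # ~95% reduction
            # 3 generations of drift at the founder size
            pool <- founders
            for (gen in 1:3) pool <- sample(pool, 30L, replace = TRUE)
            draw <- sample(pool, 80L, replace = TRUE)
            a1[l, ] <- draw[1:40]; a2[l, ] <- draw[41:80]
        }
        gm <- GenotypeMatrix(a1, a2, site = rep("P", 40),
                             encoding = "unique_id")
        res <- suppressWarnings(
            hetExcessTest(gm, "P", "site", MutationModel("IAM"),
                          nIter = 300L, seed = 7000L + r))
        if (res$wilcoxonP < 0.05) hits <- hits + 1L
    }
    expect_gt(hits, nrep / 2)
})
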