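test_that("missing-data filters drop loci first, then individuals", {
    a1 <- matrix(1L, 3, 10,
                 dimnames = list(c("l1", "l2", "l3"), paste0("i", 1:10)))
    a2 <- a1
    a1["l2", 1:2] <- NA; a2["l2", 1:2] <- NA         # 20% missing locus
    gm <- GenotypeMatrix(a1, a2, site = rep("P", 10), encoding = "unique_id")
    out <- applyMissingFilters(gm)
    expect_setequal(rownames(out), c("l1", "l3"))
    # complete matrix unchanged
    gm2 <- GenotypeMatrix(matrix(1L, 2, 4, dimnames = list(c("a", "b"),
                                                           paste0("i", 1:4))),
                          matrix(1L, 2, 4, dimnames = list(c("a", "b"),
                                                           paste0("i", 1:4))),
                          site = rep("P", 4), encoding = "unique_id")
    expect_identical(dim(applyMissingFilters(gm2)), dim(gm2))
    expect_error(applyMissingFilters(gm, maxLocusMissing = 0), "empty")
})

test_that("missing filters equal brute-force evaluation in the stated order", {
    withr::with_seed(8, {
        for (trial in 1:10) {
            a1 <- matrix(sample(c(1L, 2L, NA), 80, replace = TRUE,
                                prob = c(.4, .4, .2)), 8, 10,
                         dimnames = list(paste0("l", 1:8), paste0("i", 1:10)))
            a2 <- a1
            gm <- GenotypeMatrix(a1, a2, site = rep(c("P", "Q"), each = 5),
                                 encoding = "unique_id")
            keepL <- rowMeans(is.na(a1)) < 0.15
            if (!any(keepL)) next
            keepI <- colMeans(is.na(a1[keepL, , drop = FALSE])) < 0.35
            out <- applyMissingFilters(gm)
            expect_identical(rownames(out), rownames(a1)[keepL])
            expect_identical(colnames(out), colnames(a1)[keepI])
        }
    })
})

test_that("diversity indices reproduce the Nei-Chesser hand evaluation", {
    # one population, genotypes AA, AB, AB, BB
    gm <- makeGm(c(1L, 1L, 1L, 2L), c(1L, 2L, 2L, 2L), site = rep("P", 4))
    d <- perLocusTable(diversityIndices(gm))
    expect_equal(d$HO, 0.5)
    expect_equal(round(d$HS, 4), 0.5833)
})

test_that("differentiation indices hit their boundary cases", {
    # identical allele frequencies in two populations (the Nei-Chesser
    # small-sample corrections leave an O(1/n) remainder, hence the tolerance)
    gm0 <- makeGm(rep(c(1L, 2L), 50), rep(c(2L, 1L), 50),
                  site = rep(c("P", "Q"), each = 50))
    ov <- overallIndices(diversityIndices(gm0))
    expect_lt(abs(ov["GST"]), 0.05)
    expect_lt(abs(ov["D"]), 0.05)
    # populations fixed for different alleles
    gm1 <- makeGm(rep(c(1L, 2L), each = 6), rep(c(1L, 2L), each = 6),
                  site = rep(c("P", "Q"), each = 6))
    ov1 <- overallIndices(diversityIndices(gm1))
    expect_equal(unname(ov1["GSTp"]), 1)
    expect_equal(unname(ov1["D"]), 1)
})

test_that("AMOVA components match an independent nested-ANOVA oracle", {
    # 6-individual, 2-population, 1-locus toy
    a1 <- c(1L, 1L, 2L, 2L, 3L, 1L)
    a2 <- c(1L, 2L, 2L, 3L, 3L, 1L)
    pop <- rep(c("P", "Q"), each = 3)
    gm <- makeGm(a1, a2, site = pop)
    am <- amovaFstats(gm, permutations = 0L)
    orc <- wcAnovaOracle(a1, a2, pop)
    expect_equal(unname(am$components), unname(orc[c("A", "B", "C")]),
                 tolerance = 1e-12)
    expect_equal(am$fst, unname(orc["fst"]))
    expect_equal(am$fis, unname(orc["fis"]))
    # and on random multiallelic matrices
    withr::with_seed(19, {
        for (trial in 1:10) {
            b1 <- sample(1:5, 30, TRUE); b2 <- sample(1:5, 30, TRUE)
            pp <- rep(c("P", "Q", "R"), each = 10)
            expect_equal(amovaFstats(makeGm(b1, b2, site = pp),
                                     permutations = 0L)$fst,
                         unname(wcAnovaOracle(b1, b2, pp)["fst"]))
        }
    })
})

test_that("AMOVA boundary cases and permutation behaviour", {
    gmFix <- makeGm(rep(c(1L, 2L), each = 6), rep(c(1L, 2L), each = 6),
                    site = rep(c("P", "Q"), each = 6))
    expect_equal(amovaFstats(gmFix, permutations = 0L)$fst, 1)
    expect_lte(amovaFstats(makeGm(rep(c(1L, 2L), 6), rep(c(2L, 1L), 6),
                                  site = rep(c("P", "Q"), each = 6)),
                           permutations = 0L)$fst, 0 + 1e-9)
    expect_error(amovaFstats(makeGm(1:4, 1:4,
                                    site = c("P", "P", "P", "Q")),
                             permutations = 0L), "fewer than 2")
    # permutation p reproducible under a fixed seed, small for fixed split
    p1 <- amovaFstats(gmFix, permutations = 99L, seed = 3L)$pFst
    p2 <- amovaFstats(gmFix, permutations = 99L, seed = 3L)$pFst
    expect_identical(p1, p2)
    expect_lte(p1, 0.05)
})

test_that("standardized FST reaches its limits and bounds FST", {
    # no shared alleles: F'ST = 1
    gmPriv <- makeGm(rep(c(1L, 2L, 3L, 4L), each = 4),
                     rep(c(2L, 1L, 4L, 3L), each = 4),
                     site = rep(c("P", "Q"), each = 8))
    expect_equal(standardizedFst(gmPriv, permutations = 0L)$fstStd, 1)
    # identical populations: F'ST ~ 0
    gmSame <- makeGm(rep(c(1L, 2L), 8), rep(c(2L, 1L), 8),
                     site = rep(c("P", "Q"), 8))
    expect_lt(abs(standardizedFst(gmSame, permutations = 0L)$fstStd), 0.1)
    # island-model data: F'ST >= FST whenever within-pop diversity exists
    cfg <- SimConfig(seed = 61L)
    truth <- simulateTruth(cfg)
    gm <- truthGenotypes(truth, cfg, "unique_id")
    st <- standardizedFst(gm, permutations = 0L)
    expect_gte(st$fstStd, st$fst)
    expect_lte(st$fstStd, 1 + 1e-9)
})

test_that("pairwise differentiation is self-consistent and symmetric in roles", {
    withr::with_seed(33, {
        a1 <- sample(1:4, 36, TRUE); a2 <- sample(1:4, 36, TRUE)
        pop <- rep(c("P", "Q", "R"), each = 12)
        # make R divergent
        a1[pop == "R"] <- a1[pop == "R"] + 4L
        a2[pop == "R"] <- a2[pop == "R"] + 4L
    })
    gm <- makeGm(a1, a2, site = pop)
    pw <- pairwiseDifferentiation(gm, "site", permutations = 59L, seed = 2L)
    vals <- pairwiseValues(pw)
    for (pair in list(c("P", "Q"), c("P", "R"), c("Q", "R"))) {
        sub <- gm[, siteLabels(gm) %in% pair]
        st <- standardizedFst(sub, "site", permutations = 0L)
        expect_equal(vals[pair[1], pair[2]], st$fstStd)
    }
    # duplicated site: F'ST ~ 0 with a large p; fixed split: p at its floor
    gmDup <- makeGm(rep(c(1L, 2L), 10), rep(c(2L, 1L), 10),
                    site = rep(c("P", "Q"), each = 10))
    pwDup <- pairwiseDifferentiation(gmDup, "site", permutations = 99L)
    expect_lt(abs(pairwiseValues(pwDup)["P", "Q"]), 0.1)
    expect_gt(pairwiseValues(pwDup)["Q", "P"], 0.05)
    gmFix <- makeGm(rep(c(1L, 2L), each = 10), rep(c(1L, 2L), each = 10),
                    site = rep(c("P", "Q"), each = 10))
    pwFix <- pairwiseDifferentiation(gmFix, "site", permutations = 99L)
    expect_equal(pairwiseValues(pwFix)["P", "Q"], 1)
    expect_lte(pairwiseValues(pwFix)["Q", "P"], 1 / 100 + 1e-9)
})

test_that("Monte-Carlo exact test agrees with hypergeometric enumeration", {
    # complete separation: 10xA/0xB vs 0xA/10xB
    gmSep <- makeGm(rep(c(1L, 2L), each = 5), rep(c(1L, 2L), each = 5),
                    site = rep(c("P", "Q"), each = 5))
    res <- exactTest(gmSep, steps = 5000L, seed = 4L)
    expect_lt(res$combined$p, 0.001)
    # single locus 2x2 table: MC p within 0.01 of exact enumeration
    withr::with_seed(21, {
        a1 <- c(rep(1L, 8), rep(2L, 2), rep(1L, 3), rep(2L, 7))
        a2 <- c(rep(1L, 7), rep(2L, 3), rep(1L, 4), rep(2L, 6))
    })
    pop <- rep(c("P", "Q"), each = 10)
    gm <- makeGm(a1, a2, site = pop)
    res2 <- exactTest(gm, steps = 20000L, seed = 6L)
    # enumeration over the 2x2 hypergeometric with fixed margins
    tab <- table(rep(pop, 2), c(a1, a2))
    m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
    x <- max(0, k - n):min(k, m)
    probs <- dhyper(x, m, n, k)
    pExact <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) + 1e-12])
    expect_lt(abs(res2$perLocus$p - pExact), 0.01)
})

test_that("rarefied allelic richness satisfies its identities", {
    # g = N: richness equals the observed allele count
    withr::with_seed(55, {
        for (trial in 1:100) {
            nInd <- sample(3:12, 1)
            a1 <- sample(1:5, nInd, TRUE); a2 <- sample(1:5, nInd, TRUE)
            gm <- makeGm(a1, a2, site = rep("P", nInd))
            ar <- allelicRichness(gm, rarefactionColonies = nInd,
                                  includeTotal = FALSE)
            expect_equal(ar[1, 1], length(unique(c(a1, a2))))
        }
    })
    # hand case: N = 10 copies, counts {9, 1}, g = 2 -> 1.2
    gm <- makeGm(c(1L, 1L, 1L, 1L, 2L), rep(1L, 5), site = rep("P", 5))
    expect_equal(allelicRichness(gm, 1L, FALSE)[1, 1], 1.2)
    # monotone non-decreasing in g
    gm2 <- makeGm(c(1L, 1L, 2L, 2L, 3L, 3L), c(1L, 2L, 2L, 3L, 3L, 3L),
                  site = rep("P", 6))
    ar <- vapply(1:6, function(g) allelicRichness(gm2, g / 2,
                                                  FALSE)[1, 1], numeric(1))
    expect_true(all(diff(ar[c(2, 4, 6)]) >= -1e-12))
    # insufficient copies are flagged, not extrapolated
    expect_true(is.na(allelicRichness(gm2, 10L, FALSE)[1, 1]))
})

test_that("D and GST vanish together and F'ST stays in [0,1]", {
    withr::with_seed(91, {
        for (trial in 1:8) {
            a1 <- sample(1:4, 40, TRUE); a2 <- sample(1:4, 40, TRUE)
            pop <- rep(c("P", "Q"), each = 20)
            ov <- overallIndices(diversityIndices(makeGm(a1, a2, site = pop)))
            expect_identical(unname(abs(ov["D"]) < 1e-12),
                             unname(abs(ov["GST"]) < 1e-12))
            st <- standardizedFst(makeGm(a1, a2, site = pop),
                                  permutations = 0L)
            expect_gte(st$fstStd, -0.25)   # sampling noise around 0
            expect_lte(st$fstStd, 1 + 1e-9)
        }
    })
})

test_that("exact-test p-values are roughly uniform under the null", {
    withr::with_seed(404, {
        ps <- numeric(200)
        for (r in seq_along(ps)) {
            a1 <- sample(1:3, 24, TRUE, prob = c(.5, .3, .2))
            a2 <- sample(1:3, 24, TRUE, prob = c(.5, .3, .2))
            gm <- makeGm(a1, a2, site = rep(c("P", "Q"), each = 12))
            res <- exactTest(gm, steps = 400L, seed = 9000L + r)
            ps[r] <- res$perLocus$p
        }
    })
    expect_gt(mean(ps), 0.40)
    expect_lt(mean(ps), 0.65)
    expect_gt(mean(ps < 0.05), 0.0)   # some mass in the tail...
    expect_lt(mean(ps < 0.05), 0.12)  # ...but close to the nominal 5%
})
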