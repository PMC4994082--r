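#' Drop loci and individuals with excessive missing data
#'
#' Loci with a missing-call fraction at or above `maxLocusMissing` are dropped
#' first; individuals missing at or above `maxIndividualMissing` of the
#' retained loci are dropped second.
#'
#' @param gm a [GenotypeMatrix].
#' @param maxLocusMissing locus threshold (default 0.15: keep loci with less
#'   than 15% missing data).
#' @param maxIndividualMissing individual threshold (default 0.35).
#' @return the filtered [GenotypeMatrix]; dropped labels are recorded in
#'   `metadata(x)$dropped`.
#' @export
applyMissingFilters <- function(gm, maxLocusMissing = 0.15,
                                maxIndividualMissing = 0.35) {
    stopifnot(is(gm, "GenotypeMatrix"))
    miss <- is.na(assay(gm, "allele1"))
    lociFrac <- rowMeans(miss)
    keepLoci <- lociFrac < maxLocusMissing
    if (!any(keepLoci))
        stop("all loci exceed the missing-data threshold; empty result")
    dropped <- list(loci = rownames(gm)[!keepLoci])
    gm2 <- gm[keepLoci, ]
    indFrac <- colMeans(is.na(assay(gm2, "allele1")))
    keepInd <- indFrac < maxIndividualMissing
    dropped$individuals <- colnames(gm2)[!keepInd]
    out <- gm2[, keepInd]
    md <- metadata(out)
    md$dropped <- dropped
    metadata(out) <- md
    out
}

# per-locus Nei & Chesser (1983) small-sample diversity estimators
.neiChesserLocus <- function(a1, a2, pop) {
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]; pop <- pop[ok]
    pops <- unique(pop)
    r <- length(pops)
    if (!length(a1) || r < 1L) return(NULL)
    pi <- match(pop, pops)
    n_i <- tabulate(pi, r)
    K <- max(c(a1, a2))
    cnt <- matrix(tabulate(c(a1 + K * (pi - 1L), a2 + K * (pi - 1L)), K * r),
                  K, r)
    p <- sweep(cnt, 2L, 2L * n_i, "/")
    hoPop <- vapply(seq_len(r), function(j)
        mean(a1[pi == j] != a2[pi == j]), numeric(1))
    HO <- mean(hoPop)
    ntil <- r / sum(1 / n_i)                    # harmonic mean sample size
    meanSumP2 <- mean(colSums(p^2))
    HS <- ntil / (ntil - 1) * (1 - meanSumP2 - HO / (2 * ntil))
    pbar <- rowMeans(p)
    HT <- 1 - sum(pbar^2) + HS / (ntil * r)
    nAll <- sum(rowSums(cnt) > 0L)
    NE <- 1 / sum(pbar^2)
    poly <- nAll > 1L
    if (r >= 2L && poly) {
        GST <- (HT - HS) / HT
        GSTp <- GST * (r - 1 + HS) / ((r - 1) * (1 - HS))
        HTp <- HS + (HT - HS) * r / (r - 1)
        D <- (r / (r - 1)) * (HT - HS) / (1 - HS)
    } else {
        GST <- GSTp <- D <- NA_real_
        HTp <- if (r >= 2L) HS + (HT - HS) * r / (r - 1) else NA_real_
    }
    c(N = nAll, NE = NE, HO = HO, HS = HS, HT = HT, HTp = HTp,
      GST = GST, GSTp = GSTp, D = D, polymorphic = as.numeric(poly))
}

#' Diversity indices (Nei-Chesser estimators)
#'
#' Per-locus and multilocus observed heterozygosity (HO), within-population
#' expected heterozygosity (HS, the paper's HE), total heterozygosity (HT)
#' and its population-number-corrected form (H'T), effective number of
#' alleles (NE), Nei's GST, Hedrick's standardized G'ST and Jost's D, using
#' the Nei & Chesser small-sample corrections with the harmonic mean of
#' per-population sample sizes. Multilocus values are unweighted locus
#' averages; monomorphic loci are flagged and excluded from the ratio
#' statistics.
#'
#' @param gm a [GenotypeMatrix] with >= 2 populations for between-population
#'   indices.
#' @param level group individuals by `"site"` or `"island"`.
#' @return a [DiversityResult].
#' @export
diversityIndices <- function(gm, level = c("site", "island")) {
    level <- match.arg(level)
    pop <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    rows <- lapply(rownames(gm), function(ln) {
        v <- .neiChesserLocus(a1[ln, ], a2[ln, ], pop)
        if (is.null(v)) NULL else c(locus = ln, v)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    perLocus <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    for (cn in setdiff(names(perLocus), "locus"))
        perLocus[[cn]] <- as.numeric(perLocus[[cn]])
    perLocus$polymorphic <- perLocus$polymorphic > 0
    overall <- c(
        N = mean(perLocus$N), NE = mean(perLocus$NE),
        HO = mean(perLocus$HO), HS = mean(perLocus$HS),
        HT = mean(perLocus$HT), HTp = mean(perLocus$HTp, na.rm = TRUE),
        GST = mean(perLocus$GST, na.rm = TRUE),
        GSTp = mean(perLocus$GSTp, na.rm = TRUE),
        D = mean(perLocus$D, na.rm = TRUE))
    new("DiversityResult", perLocus = perLocus, overall = overall,
        nPopulations = length(unique(pop)),
        pValues = c(fst = NA_real_, fst_std = NA_real_, fis = NA_real_,
                    gst_std = NA_real_))
}

# Weir & Cockerham (1984) variance components for one locus, summed over
# alleles; returns c(A, B, C) or NULL when fewer than 2 populations have data
.wcLocus <- function(a1, a2, pi, r, n_i) {
    use <- n_i > 0L
    if (sum(use) < 2L) return(NULL)
    if (!all(use)) {
        keepPop <- which(use)
        sel <- pi %in% keepPop
        a1 <- a1[sel]; a2 <- a2[sel]
        pi <- match(pi[sel], keepPop)
        n_i <- n_i[keepPop]
        r <- length(keepPop)
    }
    nsum <- sum(n_i)
    nbar <- nsum / r
    if (nbar <= 1) return(NULL)
    nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
    K <- max(c(a1, a2))
    cnt <- matrix(tabulate(c(a1 + K * (pi - 1L), a2 + K * (pi - 1L)), K * r),
                  K, r)
    het <- a1 != a2
    hcnt <- matrix(tabulate(c(a1[het] + K * (pi[het] - 1L),
                              a2[het] + K * (pi[het] - 1L)), K * r), K, r)
    p <- sweep(cnt, 2L, 2L * n_i, "/")
    h <- sweep(hcnt, 2L, n_i, "/")
    pbar <- as.vector(p %*% n_i) / nsum
    s2 <- as.vector((p - pbar)^2 %*% n_i) / ((r - 1) * nbar)
    hbar <- as.vector(h %*% n_i) / nsum
    aa <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    bb <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    c(A = sum(aa), B = sum(bb), C = sum(cc))
}

# locus-wise data extraction shared by the AMOVA paths
.locusData <- function(gm, level) {
    pop <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    pops <- unique(pop)
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    lapply(rownames(gm), function(ln) {
        ok <- which(!is.na(a1[ln, ]))
        list(locus = ln, idx = ok, a1 = a1[ln, ok], a2 = a2[ln, ok],
             pi = match(pop[ok], pops))
    })
}

.wcFstats <- function(locusData, r, popIdxAll = NULL) {
    A <- B <- C <- 0
    for (ld in locusData) {
        pi <- if (is.null(popIdxAll)) ld$pi else popIdxAll[ld$idx]
        n_i <- tabulate(pi, r)
        v <- .wcLocus(ld$a1, ld$a2, pi, r, n_i)
        if (is.null(v)) next
        A <- A + v["A"]; B <- B + v["B"]; C <- C + v["C"]
    }
    c(fst = unname(A / (A + B + C)), fis = unname(B / (B + C)),
      A = unname(A), B = unname(B), C = unname(C))
}

#' AMOVA F-statistics (Weir-Cockerham) with permutation tests
#'
#' Method-of-moments variance components per allele per locus: `a` among
#' populations, `b` among individuals within populations, `c` within
#' individuals, summed over alleles and loci. FST = sum(a)/sum(a+b+c),
#' FIS = sum(b)/sum(b+c). p(FST) permutes individuals among populations;
#' p(FIS) permutes allele copies among individuals within populations;
#' p = (#{permuted >= observed} + 1)/(n + 1).
#'
#' @param gm a [GenotypeMatrix] with >= 2 populations.
#' @param level `"site"` or `"island"`.
#' @param permutations number of permutations (default 20000, the study
#'   convention; 0 skips the tests).
#' @param seed RNG seed for the permutations.
#' @return list with fst, fis, pFst, pFis, components, nPermutations.
#' @export
amovaFstats <- function(gm, level = c("site", "island"), permutations = 20000L,
                        seed = 1L) {
    level <- match.arg(level)
    pop <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    pops <- unique(pop)
    if (length(pops) < 2L) stop("need at least 2 populations")
    small <- table(pop)
    if (any(small < 2L))
        stop(sprintf("population %s has fewer than 2 individuals",
                     names(small)[which(small < 2L)[1]]))
    r <- length(pops)
    ld <- .locusData(gm, level)
    obs <- .wcFstats(ld, r)
    pFst <- pFis <- NA_real_
    if (permutations > 0L) {
        popIdx <- match(pop, pops)
        nInd <- length(popIdx)
        withSeed(seed, {
            geFst <- 0L; geFis <- 0L
            for (b in seq_len(permutations)) {
                permPop <- popIdx[sample.int(nInd)]
                st <- .wcFstats(ld, r, popIdxAll = permPop)
                if (!is.na(st["fst"]) && st["fst"] >= obs["fst"])
                    geFst <- geFst + 1L
                # FIS: permute allele copies among individuals within pops
                Bc <- Cc <- 0
                for (l in ld) {
                    n <- length(l$a1)
                    if (!n) next
                    x <- c(l$a1, l$a2)
                    g <- c(l$pi, l$pi)
                    for (p in unique(l$pi)) {
                        w <- which(g == p)
                        x[w] <- x[w[sample.int(length(w))]]
                    }
                    n_i <- tabulate(l$pi, r)
                    v <- .wcLocus(x[seq_len(n)], x[n + seq_len(n)], l$pi, r, n_i)
                    if (!is.null(v)) { Bc <- Bc + v["B"]; Cc <- Cc + v["C"] }
                }
                if (isTRUE(Bc / (Bc + Cc) >= obs["fis"])) geFis <- geFis + 1L
            }
            pFst <- (geFst + 1) / (permutations + 1)
            pFis <- (geFis + 1) / (permutations + 1)
        })
    }
    list(fst = unname(obs["fst"]), fis = unname(obs["fis"]),
         pFst = pFst, pFis = pFis,
         components = obs[c("A", "B", "C")],
         nPermutations = as.integer(permutations))
}

# recode every allele label to be population-private, preserving the
# within-population genotype structure (Meirmans' maximal-differentiation
# recoding)
.recodePrivate <- function(gm, level) {
    pop <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    pops <- unique(pop)
    popIdx <- match(pop, pops)
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    for (ln in rownames(gm)) {
        K <- max(c(a1[ln, ], a2[ln, ]), na.rm = TRUE)
        off <- K * (popIdx - 1L)
        a1[ln, ] <- a1[ln, ] + off
        a2[ln, ] <- a2[ln, ] + off
    }
    GenotypeMatrix(a1, a2, site = siteLabels(gm), island = islandLabels(gm),
                   encoding = encodingType(gm))
}

#' Standardized FST (Meirmans' F'ST)
#'
#' F'ST = FST(observed) / FST(max), where FST(max) is the AMOVA FST of the
#' same data with every allele label recoded to be population-private (the
#' maximum differentiation compatible with the observed within-population
#' genotype structure). The p-value is inherited from the FST permutation
#' test.
#'
#' @inheritParams amovaFstats
#' @return list with fstStd, fst, fstMax, fis, pFst, pFis.
#' @export
standardizedFst <- function(gm, level = c("site", "island"),
                            permutations = 20000L, seed = 1L) {
    level <- match.arg(level)
    obs <- amovaFstats(gm, level, permutations, seed)
    mx <- amovaFstats(.recodePrivate(gm, level), level, permutations = 0L)
    if (!is.finite(mx$fst) || mx$fst <= 0)
        stop("FST(max) is zero: populations are monomorphic and identical")
    list(fstStd = obs$fst / mx$fst, fst = obs$fst, fstMax = mx$fst,
         fis = obs$fis, pFst = obs$pFst, pFis = obs$pFis,
         nPermutations = obs$nPermutations)
}

#' Pairwise standardized differentiation
#'
#' For each pair of groups the matrix is restricted to the two groups and
#' F'ST computed with its permutation test; the result matrix carries F'ST
#' above the diagonal and p-values below it.
#'
#' @param gm a [GenotypeMatrix].
#' @param level `"site"` or `"island"`.
#' @param permutations permutations per pair (default 20000).
#' @param seed RNG seed.
#' @return a [PairwiseMatrix].
#' @export
pairwiseDifferentiation <- function(gm, level = c("site", "island"),
                                    permutations = 20000L, seed = 1L) {
    level <- match.arg(level)
    grp <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    groups <- unique(grp)
    if (length(groups) < 2L) stop("need at least 2 groups")
    k <- length(groups)
    vals <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        sel <- grp %in% groups[c(i, j)]
        if (min(table(grp[sel])) < 2L) next  # pair skipped, flagged as NA
        sub <- gm[, sel]
        st <- standardizedFst(sub, level, permutations,
                              seed = deriveSeed(seed, paste(groups[i], groups[j])))
        vals[i, j] <- st$fstStd
        vals[j, i] <- st$pFst
    }
    new("PairwiseMatrix", labels = groups, values = vals,
        statName = "F'ST (above) / p (below)",
        nPermutations = as.integer(permutations))
}

# log conditional probability of a contingency table given its margins
# (multivariate hypergeometric)
.logTableProb <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Monte-Carlo exact tests of population differentiation
#'
#' Per locus and population pair, the allele-count contingency table is
#' compared with `steps` tables sampled from the null of no differentiation
#' (allele copies permuted among populations holding both margins, via
#' Patefield's algorithm); the p-value is the Monte-Carlo probability of a
#' table at most as probable as the observed one. Loci are combined per pair
#' with Fisher's method (chi-squared with 2L degrees of freedom).
#'
#' @param gm a [GenotypeMatrix].
#' @param level `"site"` or `"island"`.
#' @param steps Monte-Carlo tables per locus pair (default 100000).
#' @param seed RNG seed.
#' @return list with `perLocus` (pair, locus, p) and `combined` (pair,
#'   chisq, df, p).
#' @export
exactTest <- function(gm, level = c("site", "island"), steps = 100000L,
                      seed = 1L) {
    level <- match.arg(level)
    grp <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    groups <- unique(grp)
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    perLocus <- list(); combined <- list()
    withSeed(seed, {
        for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
            pairName <- paste(groups[i], groups[j], sep = "-")
            ps <- c()
            for (ln in rownames(gm)) {
                sel1 <- grp == groups[i] & !is.na(a1[ln, ])
                sel2 <- grp == groups[j] & !is.na(a1[ln, ])
                alle <- c(a1[ln, sel1], a2[ln, sel1],
                          a1[ln, sel2], a2[ln, sel2])
                popv <- rep(1:2, c(2 * sum(sel1), 2 * sum(sel2)))
                lv <- sort(unique(alle))
                if (length(lv) < 2L) next   # monomorphic in both: skipped
                tab <- table(popv, factor(alle, levels = lv))
                lpObs <- .logTableProb(tab)
                sims <- stats::r2dtable(steps, rowSums(tab), colSums(tab))
                lp <- vapply(sims, .logTableProb, numeric(1))
                p <- (sum(lp <= lpObs + 1e-9) + 1) / (steps + 1)
                ps <- c(ps, stats::setNames(p, ln))
            }
            if (length(ps)) {
                chisq <- -2 * sum(log(ps))
                df <- 2L * length(ps)
                combined[[pairName]] <- data.frame(
                    pair = pairName, chisq = chisq, df = df,
                    p = stats::pchisq(chisq, df, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
                perLocus[[pairName]] <- data.frame(
                    pair = pairName, locus = names(ps), p = unname(ps),
                    stringsAsFactors = FALSE)
            }
        }
    })
    list(perLocus = do.call(rbind, c(perLocus, list(make.row.names = FALSE))),
         combined = do.call(rbind, c(combined, list(make.row.names = FALSE))))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a standardized subsample of
#' `2 * rarefactionColonies` gene copies:
#' AR = sum over alleles of 1 - C(N - Ni, g)/C(N, g), with N the observed
#' gene copies and Ni the copies of allele i. Populations with fewer than
#' `g` observed copies at a locus are flagged `NA`, never extrapolated.
#'
#' @param gm a [GenotypeMatrix].
#' @param rarefactionColonies colonies in the standardized subsample
#'   (default 24, i.e. 48 gene copies).
#' @param includeTotal add a pooled "Total" column over all populations.
#' @return matrix loci x populations of rarefied richness.
#' @export
allelicRichness <- function(gm, rarefactionColonies = 24L,
                            includeTotal = TRUE) {
    g <- 2L * as.integer(rarefactionColonies)
    pop <- siteLabels(gm)
    pops <- unique(pop)
    cols <- if (includeTotal) c(pops, "Total") else pops
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    out <- matrix(NA_real_, nrow(gm), length(cols),
                  dimnames = list(rownames(gm), cols))
    for (ln in rownames(gm)) {
        for (pcol in cols) {
            sel <- if (pcol == "Total") !is.na(a1[ln, ])
                   else pop == pcol & !is.na(a1[ln, ])
            alle <- c(a1[ln, sel], a2[ln, sel])
            if (!length(alle)) next
            Ni <- table(alle)
            N <- sum(Ni)
            if (N < g) next
            out[ln, pcol] <- sum(1 - exp(lchoose(N - Ni, g) - lchoose(N, g)))
        }
    }
    out
}

# multilocus Hedrick G'ST for permutation use
.gstHedrick <- function(a1, a2, popIdx, lociNames) {
    vals <- c()
    for (ln in lociNames) {
        v <- .neiChesserLocus(a1[ln, ], a2[ln, ], popIdx)
        if (!is.null(v) && !is.na(v["GSTp"])) vals <- c(vals, v["GSTp"])
    }
    mean(vals)
}

#' Full diversity and differentiation summary
#'
#' Combines the Nei-Chesser diversity indices, the AMOVA F-statistics with
#' their permutation tests, the Meirmans standardized F'ST and a permutation
#' test for Hedrick's G'ST into one [DiversityResult].
#'
#' @inheritParams amovaFstats
#' @export
summarizeDiversity <- function(gm, level = c("site", "island"),
                               permutations = 20000L, seed = 1L) {
    level <- match.arg(level)
    div <- diversityIndices(gm, level)
    st <- standardizedFst(gm, level, permutations, seed)
    pGst <- NA_real_
    if (permutations > 0L) {
        pop <- if (level == "site") siteLabels(gm) else islandLabels(gm)
        a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
        obs <- .gstHedrick(a1, a2, pop, rownames(gm))
        withSeed(deriveSeed(seed, "gst"), {
            ge <- 0L
            for (b in seq_len(permutations)) {
                pp <- pop[sample.int(length(pop))]
                if (.gstHedrick(a1, a2, pp, rownames(gm)) >= obs)
                    ge <- ge + 1L
            }
            pGst <- (ge + 1) / (permutations + 1)
        })
    }
    overall <- c(div@overall, fst = st$fst, fst_std = st$fstStd,
                 fis = st$fis, fst_max = st$fstMax)
    new("DiversityResult", perLocus = div@perLocus, overall = overall,
        nPopulations = div@nPopulations,
        pValues = c(fst = st$pFst, fst_std = st$pFst, fis = st$pFis,
                    gst_std = pGst))
}

#' Compare dataset variants (strategy x prevalence x encoding)
#'
#' Reproduces the eight-way dataset comparison: second-allele selection by
#' depth (`topdepth`) vs at random (`random000`), the standard prevalence
#' filter (alleles in >= 2 colonies) vs the `min10` variant (alleles in more
#' than 10 colonies), and length vs unique-ID encoding. Each variant is
#' called, encoded, missing-filtered and summarized.
#'
#' @param tally a [SeqTally] that has passed the length and depth filters but
#'   NOT the prevalence filter.
#' @param loci list of [LocusSpec].
#' @param islands named character site -> island.
#' @param permutations permutations for the F-statistic tests.
#' @param seed master seed.
#' @param individuals optional individual universe.
#' @return list with `table` (one row per variant) and `matrices` (the
#'   eight [GenotypeMatrix] objects).
#' @export
compareDatasets <- function(tally, loci, islands, permutations = 199L,
                            seed = 1L, individuals = NULL) {
    variants <- expand.grid(
        strategy = c("random", "depth"),
        prevalence = c(2L, 11L),
        encoding = c("unique_id", "length"),
        stringsAsFactors = FALSE)
    tallies <- list(
        `2` = applyDepthPrevalenceFilters(tally, minDepth = 1L, minColonies = 2L)$tally,
        `11` = applyDepthPrevalenceFilters(tally, minDepth = 1L, minColonies = 11L)$tally)
    rows <- list(); mats <- list()
    for (v in seq_len(nrow(variants))) {
        vt <- variants[v, ]
        tal <- tallies[[as.character(vt$prevalence)]]
        calls <- callGenotypes(tal, strategy = vt$strategy,
                               seed = deriveSeed(seed, paste0("call", vt$strategy,
                                                              vt$prevalence)),
                               individuals = individuals)
        gm <- encodeAlleles(calls, loci, islands, vt$encoding)
        gm <- applyMissingFilters(gm)
        res <- summarizeDiversity(gm, "site", permutations,
                                  seed = deriveSeed(seed, paste0("perm", v)))
        nm <- paste0(
            ifelse(vt$strategy == "depth",
                   ifelse(vt$prevalence > 2L, "depth_min10", "topdepth"),
                   ifelse(vt$prevalence > 2L, "random_min10", "random000")),
            ifelse(vt$encoding == "unique_id", "_ID", "_len"))
        ov <- overallIndices(res)
        rows[[nm]] <- data.frame(
            dataset = nm, n_individuals = ncol(gm), n_loci = nrow(gm),
            N = ov["N"], NE = ov["NE"], HE = ov["HS"], HO = ov["HO"],
            HTp = ov["HTp"], FST = ov["fst"], FSTp = ov["fst_std"],
            p_fst = res@pValues["fst"], FIS = ov["fis"],
            p_fis = res@pValues["fis"], GSTp = ov["GSTp"],
            p_gst = res@pValues["gst_std"],
            stringsAsFactors = FALSE)
        mats[[nm]] <- gm
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab, matrices = mats)
}
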