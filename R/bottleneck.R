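#' Mutation model for equilibrium heterozygosity simulation
#'
#' @param kind `"IAM"` (infinite alleles) or `"TPM"` (two-phase).
#' @param pStepwise TPM probability of a single-step mutation (default 0.70,
#'   i.e. 70% stepwise / 30% multistep).
#' @param multistepVar variance of the geometric multistep size distribution
#'   (default 30, the conventional two-phase parameterization).
#' @return list of class parameters used by [simulateHeq()].
#' @export
MutationModel <- function(kind = c("IAM", "TPM"), pStepwise = 0.70,
                          multistepVar = 30) {
    kind <- match.arg(kind)
    if (pStepwise < 0 || pStepwise > 1) stop("pStepwise must be in [0, 1]")
    if (multistepVar <= 0) stop("multistepVar must be positive")
    # geometric on {1, 2, ...}: var (1-p)/p^2 = multistepVar
    geomP <- (-1 + sqrt(1 + 4 * multistepVar)) / (2 * multistepVar)
    list(kind = kind, pStepwise = pStepwise, multistepVar = multistepVar,
         geomP = geomP)
}

# Ewens closed form: expected allele count in a sample of n genes at theta
.ewensMeanK <- function(theta, n) {
    sum(theta / (theta + 0:(n - 1)))
}

# calibration cache: theta solving mean allele count == kObs
.thetaCache <- new.env(parent = emptyenv())

#' Calibrate theta so the mean simulated allele count equals k
#'
#' IAM uses the Ewens closed form E(K) = sum theta/(theta + i) inverted by
#' bisection (exact). TPM uses stochastic bisection on batches of coalescent
#' simulations. Results are cached per (n, k, model).
#'
#' @param nGenes sample size in gene copies.
#' @param kObs observed allele count, in [2, nGenes].
#' @param model a [MutationModel()].
#' @param batch TPM simulations per bisection step.
#' @keywords internal
calibrateTheta <- function(nGenes, kObs, model, batch = 600L) {
    key <- sprintf("%s_%d_%d_%g_%g", model$kind, nGenes, kObs,
                   model$pStepwise, model$multistepVar)
    if (!is.null(.thetaCache[[key]])) return(.thetaCache[[key]])
    if (kObs < 2L || kObs > nGenes) stop("need 2 <= kObs <= nGenes")
    lo <- 1e-4; hi <- 1e4
    meanK <- if (model$kind == "IAM") {
        function(th) .ewensMeanK(th, nGenes)
    } else {
        function(th) mean(cpp_tpm_sims(nGenes, th, batch, model$pStepwise,
                                       model$geomP)$k)
    }
    # calibration runs on its own derived RNG stream (restored afterwards) so
    # a cache hit and a fresh calibration leave the caller's stream identical
    th <- withSeed(deriveSeed(nGenes * 131L + kObs, key), {
        if (meanK(lo) > kObs)
            stop("theta calibration failure: k below the attainable range")
        if (meanK(hi) < kObs) {
            # mean allele count saturates below n (all-distinct samples): use
            # the cap; the exact-k retention filter still applies
            hi
        } else {
            for (it in seq_len(if (model$kind == "IAM") 80L else 22L)) {
                mid <- sqrt(lo * hi)
                if (meanK(mid) < kObs) lo <- mid else hi <- mid
            }
            sqrt(lo * hi)
        }
    })
    .thetaCache[[key]] <- th
    th
}

#' Simulate the equilibrium heterozygosity distribution given k alleles
#'
#' Simulates samples of `nGenes` gene copies at mutation-drift equilibrium
#' under the chosen mutation model (coalescent with Poisson mutations; the
#' infinite-allele case uses the equivalent Hoppe-urn construction), with
#' theta calibrated so the mean allele count equals `kObs`; simulations with
#' exactly `kObs` alleles are retained and their unbiased expected
#' heterozygosity returned.
#'
#' @param nGenes gene copies in the sample.
#' @param kObs observed allele count (2 <= kObs <= nGenes).
#' @param model a [MutationModel()].
#' @param nIter retained simulations wanted (default 10000).
#' @param maxBatches cap on simulation batches before giving up with the
#'   simulations collected so far.
#' @return numeric vector of Heq values (length up to nIter).
#' @export
simulateHeq <- function(nGenes, kObs, model = MutationModel("IAM"),
                        nIter = 10000L, maxBatches = 200L) {
    if (kObs < 2L) stop("locus with a single allele: skipped upstream")
    if (kObs > nGenes) stop("kObs cannot exceed nGenes")
    theta <- calibrateTheta(nGenes, kObs, model)
    out <- numeric(0)
    batch <- max(1000L, as.integer(nIter))
    for (b in seq_len(maxBatches)) {
        sims <- if (model$kind == "IAM")
            cpp_iam_sims(nGenes, theta, batch)
        else cpp_tpm_sims(nGenes, theta, batch, model$pStepwise, model$geomP)
        out <- c(out, sims$he[sims$k == kObs])
        if (length(out) >= nIter) return(out[seq_len(nIter)])
    }
    if (!length(out))
        stop(sprintf("no equilibrium simulations with k = %d at n = %d",
                     kObs, nGenes))
    warning(sprintf("only %d of %d requested simulations retained", length(out),
                    nIter))
    out
}

# unbiased expected heterozygosity from an allele-count vector
.unbiasedHe <- function(counts) {
    n <- sum(counts)
    n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Heterozygosity-excess bottleneck test
#'
#' For each polymorphic locus in the chosen population, compares the observed
#' unbiased expected heterozygosity with the distribution of equilibrium
#' heterozygosity given the observed allele count (Cornuet-Luikart), then
#' applies a one-tailed Wilcoxon signed-rank test for excess across loci.
#'
#' @param gm a [GenotypeMatrix].
#' @param population site (or island, see `level`) to test.
#' @param level `"site"` or `"island"`.
#' @param model a [MutationModel()].
#' @param nIter equilibrium simulations per locus (default 10000).
#' @param seed RNG seed.
#' @return list with `perLocus` data.frame (locus, n_genes, k_obs, he_obs,
#'   heq_mean, heq_sd, dh, p_excess) and `wilcoxonP` (one-tailed).
#' @export
hetExcessTest <- function(gm, population, level = c("site", "island"),
                          model = MutationModel("IAM"), nIter = 10000L,
                          seed = 1L) {
    level <- match.arg(level)
    grp <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    sel <- grp == population
    if (!any(sel)) stop(sprintf("unknown population %s", population))
    a1 <- assay(gm, "allele1")[, sel, drop = FALSE]
    a2 <- assay(gm, "allele2")[, sel, drop = FALSE]
    rows <- list()
    withSeed(seed, {
        for (ln in rownames(gm)) {
            alle <- c(a1[ln, ], a2[ln, ])
            alle <- alle[!is.na(alle)]
            if (!length(alle)) next
            counts <- as.vector(table(alle))
            k <- length(counts)
            if (k < 2L) next               # monomorphic locus skipped
            n <- length(alle)
            heObs <- .unbiasedHe(counts)
            heq <- simulateHeq(n, k, model, nIter)
            dh <- (heObs - mean(heq)) / stats::sd(heq)
            rows[[ln]] <- data.frame(
                locus = ln, model = model$kind, n_genes = n, k_obs = k,
                he_obs = heObs, heq_mean = mean(heq), heq_sd = stats::sd(heq),
                dh = dh, p_excess = mean(heq <= heObs),
                stringsAsFactors = FALSE)
        }
    })
    perLocus <- do.call(rbind, rows)
    rownames(perLocus) <- NULL
    if (is.null(perLocus) || nrow(perLocus) < 4L)
        warning("fewer than 4 polymorphic loci: Wilcoxon test has little power")
    diffs <- perLocus$he_obs - perLocus$heq_mean
    wp <- stats::wilcox.test(diffs, alternative = "greater")$p.value
    list(perLocus = perLocus, wilcoxonP = wp)
}

#' Mode-shift test on the allele frequency spectrum
#'
#' Pools allele frequencies over loci within the population and bins them
#' into ten left-open classes (0,0.1], (0.1,0.2], ..., (0.9,1]. The spectrum
#' is "L-shaped" (no bottleneck signal) iff the lowest class holds strictly
#' more alleles than every other class.
#'
#' @param gm a [GenotypeMatrix].
#' @param population site (or island) to test.
#' @param level `"site"` or `"island"`.
#' @return list with `counts` (10 classes) and `verdict`.
#' @export
modeShiftTest <- function(gm, population, level = c("site", "island")) {
    level <- match.arg(level)
    grp <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    sel <- grp == population
    a1 <- assay(gm, "allele1")[, sel, drop = FALSE]
    a2 <- assay(gm, "allele2")[, sel, drop = FALSE]
    freqs <- c()
    for (ln in rownames(gm)) {
        alle <- c(a1[ln, ], a2[ln, ])
        alle <- alle[!is.na(alle)]
        if (length(alle) < 2L) next
        tb <- table(alle)
        if (length(tb) < 2L) next          # monomorphic locus contributes none
        freqs <- c(freqs, as.vector(tb) / sum(tb))
    }
    if (!length(freqs))
        return(list(counts = rep(NA_integer_, 10L), verdict = NA_character_))
    cls <- cut(freqs, breaks = seq(0, 1, by = 0.1), right = TRUE,
               include.lowest = FALSE)
    counts <- as.integer(table(cls))
    verdict <- if (counts[1] > max(counts[-1])) "L-shaped" else "mode-shifted"
    list(counts = counts, verdict = verdict)
}

#' Combined bottleneck analysis for one population
#'
#' Runs the heterozygosity-excess Wilcoxon test under both the infinite
#' allele model and the two-phase model (70% stepwise / 30% multistep), plus
#' the graphical mode-shift test.
#'
#' @inheritParams hetExcessTest
#' @param pStepwise,multistepVar TPM parameters (see [MutationModel()]).
#' @return a [BottleneckResult].
#' @export
bottleneckTest <- function(gm, population, level = c("site", "island"),
                           nIter = 10000L, pStepwise = 0.70,
                           multistepVar = 30, seed = 1L) {
    level <- match.arg(level)
    iam <- hetExcessTest(gm, population, level, MutationModel("IAM"),
                         nIter, seed = deriveSeed(seed, "iam"))
    tpm <- hetExcessTest(gm, population, level,
                         MutationModel("TPM", pStepwise, multistepVar),
                         nIter, seed = deriveSeed(seed, "tpm"))
    ms <- modeShiftTest(gm, population, level)
    new("BottleneckResult", population = population,
        perLocus = rbind(iam$perLocus, tpm$perLocus),
        wilcoxonP = c(IAM = iam$wilcoxonP, TPM = tpm$wilcoxonP),
        modeShiftCounts = ms$counts, modeShiftVerdict = ms$verdict)
}

#' Sample an equilibrium infinite-allele population
#'
#' Draws one Ewens sample of `2 * nColonies` gene copies at the given theta
#' and pairs the copies into Hardy-Weinberg diploid genotypes; used to build
#' constant-size null populations for calibration studies.
#'
#' @param nColonies diploid individuals.
#' @param theta scaled mutation rate.
#' @return integer matrix nColonies x 2 of allele labels.
#' @export
sampleEquilibriumPopulation <- function(nColonies, theta = 5) {
    lab <- cpp_iam_sample(2L * nColonies, theta)
    matrix(lab, ncol = 2L)
}
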