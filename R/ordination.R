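#' @importFrom stats prcomp
NULL

# individuals x allele-indicator matrix: count (0/1/2) of each allele per
# individual, NA when the call is missing
.indicatorMatrix <- function(gm) {
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    blocks <- list()
    for (ln in rownames(gm)) {
        alle <- sort(unique(c(a1[ln, ], a2[ln, ])))
        alle <- alle[!is.na(alle)]
        if (!length(alle)) next
        m <- matrix(NA_real_, ncol(gm), length(alle),
                    dimnames = list(colnames(gm), paste(ln, alle, sep = ".")))
        ok <- !is.na(a1[ln, ])
        for (j in seq_along(alle))
            m[ok, j] <- (a1[ln, ok] == alle[j]) + (a2[ln, ok] == alle[j])
        blocks[[ln]] <- m
    }
    do.call(cbind, blocks)
}

# covariance PCA with per-axis permutation p-values: columns shuffled
# independently, count eigenvalue >= observed
.covPca <- function(x, permutations, seed) {
    # mean-impute missing entries per column, then column-centre
    for (j in seq_len(ncol(x))) {
        mis <- is.na(x[, j])
        if (any(mis)) x[mis, j] <- mean(x[, j], na.rm = TRUE)
    }
    x <- scale(x, center = TRUE, scale = FALSE)
    if (all(abs(x) < 1e-12)) stop("zero-variance matrix")
    pc <- prcomp(x, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    keep <- seq_along(ev)
    scores <- pc$x[, keep, drop = FALSE]
    load <- pc$rotation[, keep, drop = FALSE]
    # sign convention: largest-magnitude loading positive per axis
    for (k in seq_len(ncol(load))) {
        i <- which.max(abs(load[, k]))
        if (load[i, k] < 0) {
            load[, k] <- -load[, k]
            scores[, k] <- -scores[, k]
        }
    }
    axisP <- rep(NA_real_, length(ev))
    if (permutations > 0L) {
        ge <- integer(length(ev))
        withSeed(seed, {
            n <- nrow(x)
            for (b in seq_len(permutations)) {
                xp <- apply(x, 2L, function(col) col[sample.int(n)])
                evp <- svd(scale(xp, center = TRUE, scale = FALSE),
                           nu = 0L, nv = 0L)$d^2 / (n - 1)
                evp <- c(evp, rep(0, max(0L, length(ev) - length(evp))))
                ge <- ge + (evp[seq_along(ev)] >= ev)
            }
        })
        axisP <- (ge + 1) / (permutations + 1)
    }
    list(scores = scores, ev = ev, frac = ev / sum(ev), axisP = axisP)
}

#' PCA of individuals on allele indicators
#'
#' Individuals are coded as counts (0/1/2) of every allele at every locus;
#' missing genotypes are mean-imputed per column; the column-centered matrix
#' is decomposed (covariance PCA). Axis significance is assessed by
#' permutations that shuffle each column independently, counting how often
#' the permuted eigenvalue reaches the observed one.
#'
#' @param gm a [GenotypeMatrix] with >= 3 individuals.
#' @param permutations permutations for axis p-values (default 10000, the
#'   study convention; 0 skips them).
#' @param seed RNG seed.
#' @return a [PCAResult].
#' @export
pcaIndividuals <- function(gm, permutations = 10000L, seed = 1L) {
    if (ncol(gm) < 3L) stop("need at least 3 individuals")
    x <- .indicatorMatrix(gm)
    r <- .covPca(x, permutations, seed)
    new("PCAResult", scores = r$scores, eigenvalues = r$ev,
        varianceFraction = r$frac, axisP = r$axisP,
        objectData = data.frame(site = siteLabels(gm),
                                island = islandLabels(gm),
                                row.names = colnames(gm)))
}

#' PCA of populations on allele frequencies
#'
#' Populations are coded by their per-allele frequencies (pairwise-deletion
#' counts) and decomposed by centered covariance PCA with the same
#' permutation scheme as [pcaIndividuals()].
#'
#' @param gm a [GenotypeMatrix] with >= 3 populations.
#' @param level `"site"` or `"island"`.
#' @param permutations permutations for axis p-values.
#' @param seed RNG seed.
#' @return a [PCAResult].
#' @export
pcaPopulations <- function(gm, level = c("site", "island"),
                           permutations = 10000L, seed = 1L) {
    level <- match.arg(level)
    grp <- if (level == "site") siteLabels(gm) else islandLabels(gm)
    groups <- unique(grp)
    if (length(groups) < 3L) stop("need at least 3 populations")
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    blocks <- list()
    for (ln in rownames(gm)) {
        alle <- sort(unique(c(a1[ln, ], a2[ln, ])))
        alle <- alle[!is.na(alle)]
        if (!length(alle)) next
        fm <- matrix(NA_real_, length(groups), length(alle),
                     dimnames = list(groups, paste(ln, alle, sep = ".")))
        for (g in groups) {
            sel <- grp == g & !is.na(a1[ln, ])
            copies <- c(a1[ln, sel], a2[ln, sel])
            if (!length(copies)) next
            fm[g, ] <- vapply(alle, function(a) mean(copies == a), numeric(1))
        }
        blocks[[ln]] <- fm
    }
    x <- do.call(cbind, blocks)
    r <- .covPca(x, permutations, seed)
    isl <- vapply(groups, function(g) islandLabels(gm)[grp == g][1], character(1))
    new("PCAResult", scores = r$scores, eigenvalues = r$ev,
        varianceFraction = r$frac, axisP = r$axisP,
        objectData = data.frame(site = groups, island = isl,
                                row.names = groups))
}
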