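#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @useDynLib ampliSTR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.DNA_BASES <- c("A", "C", "G", "T")

.validDna <- function(x) {
    length(x) == 1L && !is.na(x) && grepl("^[ACGT]*$", x)
}

#' LocusSpec: description of one microsatellite locus
#'
#' Holds everything the simulator, the demultiplexer and the filters need to
#' know about a locus: primers, the constant flanking sequences, the repeat
#' motif and the plausible repeat-count range. Amplicon inserts have the
#' structure left flank + motif repeats + right flank.
#'
#' @slot name locus label.
#' @slot fwdPrimer,rvsPrimer forward/reverse primer sequences (DNA).
#' @slot leftFlank,rightFlank constant flanking sequences (DNA).
#' @slot motif repeat motif, 2-6 bp.
#' @slot repeatRange integer pair, minimum and maximum repeat count.
#' @slot maxKnownLength longest known full insert (bp) for this locus; the
#'   per-locus length cap is `maxKnownLength + 4 * nchar(motif)`.
#'
#' @export
setClass("LocusSpec",
    representation(
        name = "character",
        fwdPrimer = "character",
        rvsPrimer = "character",
        leftFlank = "character",
        rightFlank = "character",
        motif = "character",
        repeatRange = "integer",
        maxKnownLength = "integer"
    )
)

setValidity("LocusSpec", function(object) {
    msg <- character()
    for (s in c("fwdPrimer", "rvsPrimer", "leftFlank", "rightFlank", "motif"))
        if (!.validDna(slot(object, s)))
            msg <- c(msg, sprintf("%s must be a DNA string (ACGT)", s))
    m <- object@motif
    if (.validDna(m) && !(nchar(m) >= 2L && nchar(m) <= 6L))
        msg <- c(msg, "motif length must be in [2, 6]")
    rr <- object@repeatRange
    if (length(rr) != 2L || anyNA(rr))
        msg <- c(msg, "repeatRange must be two integers")
    else {
        if (rr[1] < 3L) msg <- c(msg, "minimum repeat count must be >= 3")
        if (rr[2] < rr[1]) msg <- c(msg, "repeatRange must be non-decreasing")
    }
    # flanks must not contain a full tandem copy of the motif, otherwise the
    # repeat/flank boundary is ambiguous
    if (.validDna(m) && nchar(m) >= 2L) {
        tand <- strrep(m, 2L)
        for (s in c("leftFlank", "rightFlank"))
            if (grepl(tand, slot(object, s), fixed = TRUE))
                msg <- c(msg, sprintf("%s contains a tandem copy of the motif", s))
    }
    if (length(object@maxKnownLength) != 1L || is.na(object@maxKnownLength) ||
        object@maxKnownLength < 1L)
        msg <- c(msg, "maxKnownLength must be a positive integer")
    if (length(msg)) msg else TRUE
})

#' @describeIn LocusSpec constructor.
#' @param name,fwdPrimer,rvsPrimer,leftFlank,rightFlank,motif see slots.
#' @param repeatRange integer pair (min, max) repeat count.
#' @param maxKnownLength longest known insert in bp; default is the length of
#'   an insert with the maximum repeat count.
#' @export
LocusSpec <- function(name, fwdPrimer, rvsPrimer, leftFlank, rightFlank,
                      motif, repeatRange, maxKnownLength = NULL) {
    if (is.null(maxKnownLength))
        maxKnownLength <- nchar(leftFlank) + nchar(rightFlank) +
            as.integer(repeatRange[2]) * nchar(motif)
    new("LocusSpec", name = name, fwdPrimer = toupper(fwdPrimer),
        rvsPrimer = toupper(rvsPrimer), leftFlank = toupper(leftFlank),
        rightFlank = toupper(rightFlank), motif = toupper(motif),
        repeatRange = as.integer(repeatRange),
        maxKnownLength = as.integer(maxKnownLength))
}

setMethod("show", "LocusSpec", function(object) {
    cat(sprintf("LocusSpec %s: motif %s x %d-%d, flanks %d/%d bp, primers %d/%d bp\n",
        object@name, object@motif, object@repeatRange[1], object@repeatRange[2],
        nchar(object@leftFlank), nchar(object@rightFlank),
        nchar(object@fwdPrimer), nchar(object@rvsPrimer)))
})

.hammingDist <- function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
}

#' BarcodeScheme: inline site and colony tags
#'
#' Site tags identify the sequencing pool (one per sampling site); colony tags
#' identify up to 48 colonies within a site. Tags are unique within their tier
#' with pairwise Hamming distance >= 2 so a single substitution can never turn
#' one valid tag into another.
#'
#' @slot siteTags named character vector, site -> DNA tag.
#' @slot colonyTags character vector of colony DNA tags.
#' @export
setClass("BarcodeScheme",
    representation(siteTags = "character", colonyTags = "character"))

setValidity("BarcodeScheme", function(object) {
    msg <- character()
    checkTier <- function(tags, what) {
        out <- character()
        if (!all(vapply(tags, .validDna, logical(1))))
            out <- c(out, sprintf("%s must be DNA strings", what))
        if (any(nchar(tags) < 1L))
            out <- c(out, sprintf("%s must have length >= 1", what))
        if (anyDuplicated(tags))
            out <- c(out, sprintf("%s must be unique", what))
        if (length(unique(nchar(tags))) == 1L && length(tags) > 1L) {
            for (i in seq_along(tags)[-1]) for (j in seq_len(i - 1L))
                if (.hammingDist(tags[i], tags[j]) < 2L) {
                    out <- c(out, sprintf("%s pairwise Hamming distance must be >= 2", what))
                    return(out)
                }
        }
        out
    }
    msg <- c(msg, checkTier(object@siteTags, "site tags"),
             checkTier(object@colonyTags, "colony tags"))
    if (is.null(names(object@siteTags)))
        msg <- c(msg, "siteTags must be named by site")
    if (length(msg)) msg else TRUE
})

#' @describeIn BarcodeScheme constructor.
#' @param siteTags named character vector of site tags.
#' @param colonyTags character vector of colony tags.
#' @export
BarcodeScheme <- function(siteTags, colonyTags) {
    new("BarcodeScheme", siteTags = toupper(siteTags),
        colonyTags = toupper(colonyTags))
}

setMethod("show", "BarcodeScheme", function(object) {
    cat(sprintf("BarcodeScheme: %d site tags (%d bp), %d colony tags (%d bp)\n",
        length(object@siteTags), nchar(object@siteTags[1]),
        length(object@colonyTags), nchar(object@colonyTags[1])))
})

#' SimConfig: parameters of the amplicon-library simulator
#'
#' @slot sites site labels.
#' @slot islands named character, site -> island group.
#' @slot popSizes named integer, colonies sampled per site (<= 48, the colony
#'   tag capacity).
#' @slot thetaFst divergence parameter of the Balding-Nichols island model,
#'   in (0, 1); equals the expected Weir-Cockerham theta.
#' @slot loci list of [LocusSpec] objects.
#' @slot meanDepth,depthDispersion negative-binomial read depth per
#'   colony-locus (mu and size).
#' @slot alleleBalanceBeta Beta(b, b) parameter for the heterozygote read
#'   split; large values keep the split close to 50/50.
#' @slot stutterRate per-read probability of slipping +-1 repeat unit.
#' @slot errorRate per-base substitution probability.
#' @slot lowQualTailFrac,lowQualTailLen fraction of reads carrying a
#'   low-quality tail, and its length in bases.
#' @slot nFlankVariants number of extra alleles per locus that duplicate an
#'   existing repeat count but carry a flank SNP (same-length, different
#'   sequence: invisible to length encoding, visible to sequence identity).
#' @slot seed master RNG seed.
#' @export
setClass("SimConfig",
    representation(
        sites = "character", islands = "character", popSizes = "integer",
        thetaFst = "numeric", loci = "list",
        meanDepth = "numeric", depthDispersion = "numeric",
        alleleBalanceBeta = "numeric", stutterRate = "numeric",
        errorRate = "numeric", lowQualTailFrac = "numeric",
        lowQualTailLen = "integer", nFlankVariants = "integer",
        seed = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (!(object@thetaFst > 0 && object@thetaFst < 1))
        msg <- c(msg, "thetaFst must be in (0, 1)")
    if (any(object@popSizes < 1L) || any(object@popSizes > 48L))
        msg <- c(msg, "popSizes must be in [1, 48] (colony tag capacity)")
    if (!setequal(names(object@popSizes), object@sites))
        msg <- c(msg, "popSizes must be named by site")
    if (!setequal(names(object@islands), object@sites))
        msg <- c(msg, "islands must be named by site")
    if (!all(vapply(object@loci, is, logical(1), "LocusSpec")))
        msg <- c(msg, "loci must be a list of LocusSpec")
    if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
    if (object@depthDispersion <= 0) msg <- c(msg, "depthDispersion must be positive")
    if (object@alleleBalanceBeta <= 0) msg <- c(msg, "alleleBalanceBeta must be positive")
    if (object@stutterRate < 0 || object@stutterRate >= 1)
        msg <- c(msg, "stutterRate must be in [0, 1)")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must be in [0, 1)")
    if (object@lowQualTailFrac < 0 || object@lowQualTailFrac > 1)
        msg <- c(msg, "lowQualTailFrac must be in [0, 1]")
    if (object@nFlankVariants < 0L) msg <- c(msg, "nFlankVariants must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d sites (%d islands), %d colonies, %d loci\n",
        "  thetaFst %.3g, depth NB(mu=%.3g, size=%.3g), balance Beta(%.3g)\n",
        "  stutter %.3g, error %.3g, seed %d\n"),
        length(object@sites), length(unique(object@islands)),
        sum(object@popSizes), length(object@loci), object@thetaFst,
        object@meanDepth, object@depthDispersion, object@alleleBalanceBeta,
        object@stutterRate, object@errorRate, object@seed))
})

#' TruthSet: known allele frequencies and genotypes behind a simulation
#'
#' @slot popFreqs per locus, a populations x alleles frequency matrix (columns
#'   named by allele sequence).
#' @slot alleleInfo per locus, a data.frame (sequence, repeats, variant).
#' @slot genotypes data.frame (site, colony, locus, allele1, allele2,
#'   repeats1, repeats2) with allele sequences.
#' @slot thetaFst divergence parameter used to draw population frequencies.
#' @export
setClass("TruthSet",
    representation(popFreqs = "list", alleleInfo = "list",
                   genotypes = "data.frame", thetaFst = "numeric"))

setValidity("TruthSet", function(object) {
    msg <- character()
    for (l in names(object@popFreqs)) {
        fr <- object@popFreqs[[l]]
        if (any(abs(rowSums(fr) - 1) > 1e-8))
            msg <- c(msg, sprintf("frequencies at %s do not sum to 1", l))
    }
    need <- c("site", "colony", "locus", "allele1", "allele2")
    if (!all(need %in% names(object@genotypes)))
        msg <- c(msg, "genotypes must have site/colony/locus/allele1/allele2")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet: %d loci, %d genotype rows, thetaFst %.3g\n",
        length(object@popFreqs), nrow(object@genotypes), object@thetaFst))
})

#' SeqTally: depth-annotated unique sequences per colony-locus
#'
#' The collapsed representation of a demultiplexed, trimmed library: one row
#' per (site, colony, locus, sequence) with its read depth. Pooled per-locus
#' totals (total depth, number of colonies carrying the sequence) drive the
#' depth and prevalence filters.
#'
#' @slot tally data.frame with columns site, colony, locus, sequence, depth.
#' @export
setClass("SeqTally", representation(tally = "data.frame"))

setValidity("SeqTally", function(object) {
    msg <- character()
    need <- c("site", "colony", "locus", "sequence", "depth")
    if (!all(need %in% names(object@tally)))
        return("tally must have columns site, colony, locus, sequence, depth")
    if (nrow(object@tally)) {
        if (any(object@tally$depth < 1L)) msg <- c(msg, "depths must be >= 1")
        key <- paste(object@tally$site, object@tally$colony,
                     object@tally$locus, object@tally$sequence)
        if (anyDuplicated(key))
            msg <- c(msg, "sequences must be unique within a colony-locus")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SeqTally constructor from a tally data.frame.
#' @param tally data.frame with columns site, colony, locus, sequence, depth.
#' @export
SeqTally <- function(tally) {
    tally <- as.data.frame(tally)[, c("site", "colony", "locus", "sequence", "depth")]
    tally$depth <- as.integer(tally$depth)
    rownames(tally) <- NULL
    new("SeqTally", tally = tally)
}

setMethod("show", "SeqTally", function(object) {
    tt <- object@tally
    cat(sprintf("SeqTally: %d unique sequences, %d reads, %d colony-locus groups, %d loci\n",
        nrow(tt), sum(tt$depth),
        length(unique(paste(tt$site, tt$colony, tt$locus))),
        length(unique(tt$locus))))
})

#' GenotypeMatrix: diploid genotypes of individuals at microsatellite loci
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two integer
#' assays, `allele1` and `allele2` (loci in rows, individuals in columns;
#' `NA` marks a missing call). `colData` carries `site` and `island` labels;
#' `metadata(x)$encoding` records whether allele labels index fragment
#' lengths (`"length"`) or distinct full sequences (`"unique_id"`), and
#' `metadata(x)$alleleKey` maps integer labels back to allele values per
#' locus.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("allele1", "allele2") %in% an))
        return("assays must include allele1 and allele2")
    a1 <- assay(object, "allele1"); a2 <- assay(object, "allele2")
    if (!is.integer(a1) || !is.integer(a2))
        msg <- c(msg, "allele assays must be integer matrices")
    if (!identical(is.na(a1), is.na(a2)))
        msg <- c(msg, "allele1 and allele2 must share the same missing mask")
    if (!all(c("site", "island") %in% names(colData(object))))
        msg <- c(msg, "colData must have site and island")
    enc <- metadata(object)$encoding
    if (is.null(enc) || !enc %in% c("length", "unique_id"))
        msg <- c(msg, "metadata encoding must be 'length' or 'unique_id'")
    if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeMatrix constructor.
#' @param allele1,allele2 integer matrices (loci x individuals), NA = missing.
#' @param site,island per-individual labels (island defaults to site).
#' @param encoding `"length"` or `"unique_id"`.
#' @param alleleKey optional per-locus label table (list of data.frames with
#'   columns label, value, code).
#' @export
GenotypeMatrix <- function(allele1, allele2, site, island = site,
                           encoding, alleleKey = list()) {
    storage.mode(allele1) <- "integer"
    storage.mode(allele2) <- "integer"
    se <- SummarizedExperiment(
        assays = list(allele1 = allele1, allele2 = allele2),
        colData = DataFrame(site = as.character(site),
                            island = as.character(island),
                            row.names = colnames(allele1)),
        metadata = list(encoding = encoding, alleleKey = alleleKey))
    new("GenotypeMatrix", se)
}

setMethod("show", "GenotypeMatrix", function(object) {
    miss <- mean(is.na(assay(object, "allele1")))
    cat(sprintf(paste0("GenotypeMatrix: %d loci x %d individuals (%s encoding)\n",
        "  %d sites, %d islands, %.1f%% missing calls\n"),
        nrow(object), ncol(object), metadata(object)$encoding,
        length(unique(colData(object)$site)),
        length(unique(colData(object)$island)), 100 * miss))
})

#' DiversityResult: per-locus and multilocus diversity indices
#'
#' @slot perLocus data.frame of per-locus indices.
#' @slot overall named numeric of unweighted locus means (indices) and
#'   variance-component F-statistics where filled in.
#' @slot nPopulations number of populations used.
#' @slot pValues named numeric of permutation p-values (NA when not computed).
#' @export
setClass("DiversityResult",
    representation(perLocus = "data.frame", overall = "numeric",
                   nPopulations = "integer", pValues = "numeric"))

setMethod("show", "DiversityResult", function(object) {
    cat(sprintf("DiversityResult over %d loci, %d populations\n",
        nrow(object@perLocus), object@nPopulations))
    ov <- object@overall
    cat(paste(sprintf("  %s = %.4f", names(ov), ov), collapse = "\n"), "\n")
})

#' PairwiseMatrix: pairwise statistic with significance
#'
#' Square matrix with the statistic above the diagonal and permutation (or
#' exact-test) p-values below it; the diagonal is NA.
#'
#' @slot labels group labels.
#' @slot values numeric matrix (statistic above, p below the diagonal).
#' @slot statName name of the statistic.
#' @slot nPermutations permutations or Monte-Carlo steps used.
#' @export
setClass("PairwiseMatrix",
    representation(labels = "character", values = "matrix",
                   statName = "character", nPermutations = "integer"))

setMethod("show", "PairwiseMatrix", function(object) {
    cat(sprintf("PairwiseMatrix of %s (%d groups, %d permutations)\n",
        object@statName, length(object@labels), object@nPermutations))
    print(round(object@values, 4))
})

#' BottleneckResult: heterozygosity-excess and mode-shift tests
#'
#' @slot population population tested.
#' @slot perLocus data.frame: locus, model, n_genes, k_obs, he_obs, heq_mean,
#'   heq_sd, dh (standardized difference), p_excess.
#' @slot wilcoxonP named numeric, one-tailed Wilcoxon signed-rank p per model.
#' @slot modeShiftCounts allele counts in ten frequency classes (0,0.1], ...
#' @slot modeShiftVerdict "L-shaped" or "mode-shifted".
#' @export
setClass("BottleneckResult",
    representation(population = "character", perLocus = "data.frame",
                   wilcoxonP = "numeric", modeShiftCounts = "integer",
                   modeShiftVerdict = "character"))

setMethod("show", "BottleneckResult", function(object) {
    cat(sprintf("BottleneckResult for %s (%d locus x model rows)\n",
        object@population, nrow(object@perLocus)))
    for (m in names(object@wilcoxonP))
        cat(sprintf("  Wilcoxon one-tailed p (%s): %.4g\n", m, object@wilcoxonP[m]))
    if (length(object@modeShiftVerdict))
        cat(sprintf("  Mode shift: %s\n", object@modeShiftVerdict))
})

#' PCAResult: covariance principal component analysis
#'
#' @slot scores objects x axes score matrix.
#' @slot eigenvalues covariance eigenvalues, non-increasing.
#' @slot varianceFraction per-axis fraction of total variance.
#' @slot axisP per-axis permutation p-values (NA when permutations = 0).
#' @slot objectData data.frame of object metadata (site, island).
#' @export
setClass("PCAResult",
    representation(scores = "matrix", eigenvalues = "numeric",
                   varianceFraction = "numeric", axisP = "numeric",
                   objectData = "data.frame"))

setMethod("show", "PCAResult", function(object) {
    cat(sprintf("PCAResult: %d objects, %d axes; axis 1 %.1f%%, axis 2 %.1f%%\n",
        nrow(object@scores), length(object@eigenvalues),
        100 * object@varianceFraction[1],
        100 * ifelse(length(object@varianceFraction) > 1,
                     object@varianceFraction[2], NA_real_)))
})
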