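#' Accessors for package classes
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param which for `alleleCalls`, 1 or 2 (which allele assay).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alleleCalls", function(x, which = 1L) standardGeneric("alleleCalls"))

#' @rdname accessors
#' @export
setMethod("alleleCalls", "GenotypeMatrix", function(x, which = 1L) {
    stopifnot(which %in% 1:2)
    assay(x, paste0("allele", which))
})

#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname accessors
#' @export
setMethod("siteLabels", "GenotypeMatrix", function(x) colData(x)$site)

#' @rdname accessors
#' @export
setGeneric("islandLabels", function(x) standardGeneric("islandLabels"))

#' @rdname accessors
#' @export
setMethod("islandLabels", "GenotypeMatrix", function(x) colData(x)$island)

#' @rdname accessors
#' @export
setGeneric("encodingType", function(x) standardGeneric("encodingType"))

#' @rdname accessors
#' @export
setMethod("encodingType", "GenotypeMatrix", function(x) metadata(x)$encoding)

#' @rdname accessors
#' @export
setGeneric("alleleKey", function(x) standardGeneric("alleleKey"))

#' @rdname accessors
#' @export
setMethod("alleleKey", "GenotypeMatrix", function(x) metadata(x)$alleleKey)

#' @rdname accessors
#' @export
setGeneric("tallyTable", function(x) standardGeneric("tallyTable"))

#' @rdname accessors
#' @export
setMethod("tallyTable", "SeqTally", function(x) x@tally)

#' Pooled per-locus sequence index
#'
#' Pools a [SeqTally] per locus across the entire dataset: for every unique
#' sequence at a locus, its total read depth and the number of distinct
#' colonies carrying it. This is the table the depth and prevalence filters
#' operate on.
#'
#' @param x a [SeqTally].
#' @return data.frame with columns locus, sequence, total_depth, n_colonies.
#' @export
setGeneric("pooledTally", function(x) standardGeneric("pooledTally"))

#' @rdname pooledTally
#' @export
setMethod("pooledTally", "SeqTally", function(x) {
    tt <- data.table::as.data.table(x@tally)
    if (!nrow(tt))
        return(data.frame(locus = character(), sequence = character(),
                          total_depth = integer(), n_colonies = integer()))
    pooled <- tt[, list(total_depth = sum(depth),
                        n_colonies = length(unique(paste(site, colony)))),
                 by = c("locus", "sequence")]
    as.data.frame(pooled)
})

#' @rdname accessors
#' @export
setGeneric("truthGenotypeTable", function(x) standardGeneric("truthGenotypeTable"))

#' @rdname accessors
#' @export
setMethod("truthGenotypeTable", "TruthSet", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("popFreqs", function(x) standardGeneric("popFreqs"))

#' @rdname accessors
#' @export
setMethod("popFreqs", "TruthSet", function(x) x@popFreqs)

#' @rdname accessors
#' @export
setGeneric("perLocusTable", function(x) standardGeneric("perLocusTable"))

#' @rdname accessors
#' @export
setMethod("perLocusTable", "DiversityResult", function(x) x@perLocus)

#' @rdname accessors
#' @export
setMethod("perLocusTable", "BottleneckResult", function(x) x@perLocus)

#' @rdname accessors
#' @export
setGeneric("overallIndices", function(x) standardGeneric("overallIndices"))

#' @rdname accessors
#' @export
setMethod("overallIndices", "DiversityResult", function(x) x@overall)

#' @rdname accessors
#' @export
setGeneric("pairwiseValues", function(x) standardGeneric("pairwiseValues"))

#' @rdname accessors
#' @export
setMethod("pairwiseValues", "PairwiseMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setMethod("pcaScores", "PCAResult", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' @rdname accessors
#' @export
setMethod("varianceFractions", "PCAResult", function(x) x@varianceFraction)

#' @rdname accessors
#' @export
setGeneric("wilcoxonP", function(x) standardGeneric("wilcoxonP"))

#' @rdname accessors
#' @export
setMethod("wilcoxonP", "BottleneckResult", function(x) x@wilcoxonP)

#' @rdname accessors
#' @export
setGeneric("modeShiftVerdict", function(x) standardGeneric("modeShiftVerdict"))

#' @rdname accessors
#' @export
setMethod("modeShiftVerdict", "BottleneckResult", function(x) x@modeShiftVerdict)
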