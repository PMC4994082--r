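#' Collapse trimmed inserts into depth-annotated unique sequences
#'
#' Exact-string collapse within each (site, colony, locus): depth is the
#' multiplicity of the insert among that colony-locus's reads. Empty inserts
#' are dropped here (they carry no sequence); read conservation holds over
#' the non-empty inserts.
#'
#' @param assignments data.frame from [trimReads()] (columns site, colony,
#'   locus, insert).
#' @return a [SeqTally].
#' @export
collapseReads <- function(assignments) {
    keep <- assignments[nchar(assignments$insert) > 0L, , drop = FALSE]
    if (!nrow(keep))
        return(SeqTally(data.frame(site = character(), colony = character(),
                                   locus = character(), sequence = character(),
                                   depth = integer())))
    dt <- data.table::as.data.table(keep[, c("site", "colony", "locus", "insert")])
    data.table::setnames(dt, "insert", "sequence")
    tt <- dt[, list(depth = .N), by = c("site", "colony", "locus", "sequence")]
    SeqTally(as.data.frame(tt))
}

#' Length filter with per-locus caps
#'
#' Keeps sequences with `minLen <= length <= maxLen`. When locus metadata is
#' supplied the cap is tightened per locus to
#' `min(maxLen, maxKnownLength + 4 * motif length)` — four extra repeat units
#' beyond the longest known microsatellite sequence. Rejected sequences are
#' returned (and optionally written) as an audit table, standing in for the
#' by-eye inspection of discarded reads.
#'
#' @param tally a [SeqTally].
#' @param minLen minimum insert length in bp (default 15).
#' @param maxLen global maximum insert length in bp (default 190).
#' @param loci optional list of [LocusSpec] for per-locus caps.
#' @param rejectsFile optional path for the rejected-sequence audit table.
#' @return list with `tally` (filtered [SeqTally]) and `rejects` (data.frame
#'   with a reject_reason column).
#' @export
applyLengthFilter <- function(tally, minLen = 15L, maxLen = 190L, loci = NULL,
                              rejectsFile = NULL) {
    stopifnot(is(tally, "SeqTally"), minLen <= maxLen)
    tt <- tallyTable(tally)
    len <- nchar(tt$sequence)
    cap <- rep(as.integer(maxLen), nrow(tt))
    if (!is.null(loci)) {
        for (l in loci) {
            sel <- tt$locus == l@name
            cap[sel] <- min(maxLen, l@maxKnownLength + 4L * nchar(l@motif))
        }
    }
    ok <- len >= minLen & len <= cap
    rejects <- tt[!ok, , drop = FALSE]
    if (nrow(rejects))
        rejects$reject_reason <- ifelse(nchar(rejects$sequence) < minLen,
                                        "too_short", "too_long")
    else rejects$reject_reason <- character(0)
    if (!is.null(rejectsFile))
        utils::write.table(rejects, rejectsFile, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    list(tally = SeqTally(tt[ok, , drop = FALSE]), rejects = rejects)
}

#' Pooled depth and prevalence filters
#'
#' Pools sequences per locus across the entire dataset, then removes (1) any
#' sequence whose pooled depth is below `minDepth` reads, and (2) any sequence
#' present in fewer than `minColonies` distinct colonies regardless of depth.
#' Setting `minColonies = 11` reproduces the "min10" dataset variants that
#' keep only alleles present in more than 10 colonies.
#'
#' @param tally a [SeqTally].
#' @param minDepth keep pooled depth >= minDepth (default 10: "fewer than 10
#'   reads" are removed).
#' @param minColonies keep sequences in >= minColonies colonies (default 2).
#' @return list with `tally` (filtered [SeqTally]) and `removed` (per-filter
#'   removal counts).
#' @export
applyDepthPrevalenceFilters <- function(tally, minDepth = 10L, minColonies = 2L) {
    stopifnot(is(tally, "SeqTally"))
    if (minDepth < 1L || minColonies < 1L)
        stop("minDepth and minColonies must be >= 1")
    tt <- tallyTable(tally)
    pooled <- pooledTally(tally)
    key <- paste(tt$locus, tt$sequence, sep = "\r")
    pkey <- paste(pooled$locus, pooled$sequence, sep = "\r")
    pd <- pooled$total_depth[match(key, pkey)]
    pc <- pooled$n_colonies[match(key, pkey)]
    lowDepth <- pd < minDepth
    afterDepth <- tt[!lowDepth, , drop = FALSE]
    lowPrev <- pc[!lowDepth] < minColonies
    out <- afterDepth[!lowPrev, , drop = FALSE]
    removed <- c(depth = length(unique(key[lowDepth])),
                 prevalence = length(unique(paste(afterDepth$locus,
                                                  afterDepth$sequence)[lowPrev])))
    list(tally = SeqTally(out), removed = removed)
}
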