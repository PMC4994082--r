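#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet vmatchPattern
NULL

# read a FASTQ (optionally gzipped) into plain character vectors; the 4-line
# record structure is validated first so a malformed record is reported by
# index (the Biostrings reader silently tolerates some defects)
.readFastq <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
    n <- length(lines)
    nrec <- n %/% 4L
    idx <- function(k) lines[seq.int(k, by = 4L, length.out = nrec)]
    bad <- if (nrec > 0L)
        !startsWith(idx(1L), "@") | !startsWith(idx(3L), "+") |
        nchar(idx(2L)) != nchar(idx(4L))
    else logical(0)
    if (n %% 4L != 0L) bad <- c(bad, TRUE)
    if (any(bad))
        stop(sprintf("malformed FASTQ record %d in %s", which(bad)[1], path),
             call. = FALSE)
    x <- tryCatch(
        readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
        error = function(e)
            stop(sprintf("malformed FASTQ file %s: %s", path,
                         conditionMessage(e)), call. = FALSE))
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         id = names(x))
}

.writeFastq <- function(seqs, quals, ids, path) {
    x <- DNAStringSet(seqs)
    names(x) <- ids
    writeXStringSet(x, filepath = path, format = "fastq",
                    qualities = BStringSet(quals),
                    compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Demultiplex amplicon reads by inline tags and primers
#'
#' Assigns each read to (site, colony, locus) from its prefix: the site tag
#' must match exactly, then the colony tag exactly, then a locus forward
#' primer within `maxMismatch` substitutions (no indels). Among loci the one
#' with fewest primer mismatches wins; a tie leaves the read unassigned. The
#' matched prefix (tags + primer) is stripped so the retained insert is
#' flank + repeats + flank + reverse primer.
#'
#' @param files character vector of FASTQ paths (gzip allowed).
#' @param scheme a [BarcodeScheme].
#' @param loci list of [LocusSpec].
#' @param maxMismatch substitutions tolerated in the forward primer
#'   (default 2); tags are always exact-match.
#' @return list with `assignments` (data.frame site, colony, locus, insert,
#'   quality), `unassigned` (data.frame file, read, reason), and `counts`
#'   (assigned per site x locus plus per-file totals).
#' @export
demultiplexReads <- function(files, scheme, loci, maxMismatch = 2L) {
    stopifnot(is(scheme, "BarcodeScheme"), length(files) >= 1L,
              maxMismatch >= 0L)
    if (any(nchar(scheme@siteTags) < 1L) || any(nchar(scheme@colonyTags) < 1L))
        stop("tags must be non-empty")
    lociNames <- vapply(loci, function(l) l@name, character(1))
    primers <- vapply(loci, function(l) l@fwdPrimer, character(1))
    if (any(nchar(primers) < 1L)) stop("primers must be non-empty")

    assignList <- list(); unassignList <- list(); fileCounts <- list()
    for (f in files) {
        fq <- .readFastq(f)
        n <- length(fq$seq)
        siteIdx <- rep(NA_integer_, n)
        for (i in seq_along(scheme@siteTags)) {
            tag <- scheme@siteTags[i]
            hit <- is.na(siteIdx) &
                substr(fq$seq, 1L, nchar(tag)) == tag
            siteIdx[hit] <- i
        }
        off <- ifelse(is.na(siteIdx), NA_integer_,
                      nchar(scheme@siteTags)[siteIdx])
        colIdx <- rep(NA_integer_, n)
        for (len in unique(nchar(scheme@colonyTags))) {
            sub <- substr(fq$seq, off + 1L, off + len)
            m <- match(sub, scheme@colonyTags[nchar(scheme@colonyTags) == len])
            take <- is.na(colIdx) & !is.na(m) & !is.na(siteIdx)
            full <- which(nchar(scheme@colonyTags) == len)
            colIdx[take] <- full[m[take]]
        }
        off2 <- off + ifelse(is.na(colIdx), NA_integer_,
                             nchar(scheme@colonyTags)[colIdx])
        # primer mismatch counts per locus
        mm <- matrix(NA_integer_, n, length(loci))
        okTags <- !is.na(colIdx)
        for (j in seq_along(loci)) {
            mm[okTags, j] <- .substrMismatch(fq$seq[okTags], primers[j],
                                             start = off2[okTags] + 1L)
        }
        best <- rep(NA_integer_, n); bestMM <- rep(NA_integer_, n)
        if (any(okTags)) {
            sub <- mm[okTags, , drop = FALSE]
            bm <- apply(sub, 1L, min)
            nb <- rowSums(sub == bm)
            bi <- apply(sub, 1L, which.min)
            sel <- bm <= maxMismatch & nb == 1L
            tmpBest <- ifelse(sel, bi, NA_integer_)
            best[okTags] <- tmpBest
            bestMM[okTags] <- bm
        }
        assigned <- !is.na(best)
        reason <- character(n)
        reason[is.na(siteIdx)] <- "no_site_tag"
        reason[!is.na(siteIdx) & is.na(colIdx)] <- "no_colony_tag"
        reason[okTags & !assigned] <- ifelse(
            bestMM[okTags & !assigned] > maxMismatch, "no_primer", "primer_tie")

        if (any(assigned)) {
            ia <- which(assigned)
            start <- off2[ia] + nchar(primers)[best[ia]] + 1L
            assignList[[f]] <- data.frame(
                site = names(scheme@siteTags)[siteIdx[ia]],
                colony = scheme@colonyTags[colIdx[ia]],
                locus = lociNames[best[ia]],
                insert = substr(fq$seq[ia], start, nchar(fq$seq[ia])),
                quality = substr(fq$qual[ia], start, nchar(fq$qual[ia])),
                primer_mismatches = bestMM[ia],
                stringsAsFactors = FALSE)
        }
        if (any(!assigned)) {
            iu <- which(!assigned)
            unassignList[[f]] <- data.frame(
                file = f, read = fq$seq[iu], reason = reason[iu],
                stringsAsFactors = FALSE)
        }
        fileCounts[[f]] <- data.frame(
            file = f, total = n, assigned = sum(assigned),
            unassigned = sum(!assigned), stringsAsFactors = FALSE)
    }
    assignments <- if (length(assignList)) do.call(rbind, assignList) else
        data.frame(site = character(), colony = character(),
                   locus = character(), insert = character(),
                   quality = character(), primer_mismatches = integer())
    rownames(assignments) <- NULL
    unassigned <- if (length(unassignList)) do.call(rbind, unassignList) else
        data.frame(file = character(), read = character(), reason = character())
    rownames(unassigned) <- NULL
    counts <- do.call(rbind, fileCounts)
    rownames(counts) <- NULL
    classCounts <- if (nrow(assignments))
        as.data.frame(table(site = assignments$site, locus = assignments$locus),
                      responseName = "assigned")
    else data.frame(site = character(), locus = character(), assigned = integer())
    list(assignments = assignments, unassigned = unassigned,
         fileCounts = counts, classCounts = classCounts)
}

#' Trim reverse primers and low-quality tails from assigned reads
#'
#' For each read, the locus's reverse primer is located (within `maxMismatch`
#' substitutions) and the primer plus everything after it is removed; the
#' remainder is then truncated at the first sliding window of `window` bases
#' whose mean Phred quality falls below `minQuality` (bases at the head of
#' that window that are individually above threshold are kept). The result is
#' the bare
#' insert: flank + tandem repeats + flank. Fully trimmed reads keep a
#' zero-length insert (flagged `empty`) for the length filter to reject;
#' trimming an already-trimmed insert is a no-op.
#'
#' @param assignments data.frame from [demultiplexReads()].
#' @param loci list of [LocusSpec] (for reverse primers).
#' @param window sliding window width in bases (default 4).
#' @param minQuality minimum mean window quality (default 15).
#' @param maxMismatch substitutions tolerated in the reverse primer.
#' @return the assignments data.frame with trimmed `insert`/`quality` and a
#'   logical `empty` column.
#' @export
trimReads <- function(assignments, loci, window = 4L, minQuality = 15,
                      maxMismatch = 2L) {
    stopifnot(window >= 1L)
    lociByName <- stats::setNames(loci, vapply(loci, function(l) l@name,
                                               character(1)))
    ins <- assignments$insert
    qual <- assignments$quality
    for (ln in unique(assignments$locus)) {
        idx <- which(assignments$locus == ln)
        primer <- lociByName[[ln]]@rvsPrimer
        nonEmpty <- idx[nchar(ins[idx]) >= 1L]
        if (!length(nonEmpty)) next
        hits <- vmatchPattern(primer, DNAStringSet(ins[nonEmpty]),
                              max.mismatch = maxMismatch)
        starts <- vapply(Biostrings::startIndex(hits), function(s)
            if (is.null(s) || !length(s)) NA_integer_ else min(s), integer(1))
        cut <- which(!is.na(starts))
        if (length(cut)) {
            i <- nonEmpty[cut]
            ins[i] <- substr(ins[i], 1L, starts[cut] - 1L)
            qual[i] <- substr(qual[i], 1L, starts[cut] - 1L)
        }
    }
    # sliding-window quality truncation; only reads containing a base below
    # threshold can trigger it
    minChar <- intToUtf8(as.integer(minQuality) + 33L)
    flag <- which(nchar(ins) > 0L &
                  vapply(qual, function(q) {
                      q != "" && min(utf8ToInt(q)) - 33L < minQuality
                  }, logical(1), USE.NAMES = FALSE))
    for (i in flag) {
        q <- utf8ToInt(qual[i]) - 33L
        L <- length(q)
        if (L < window) {
            if (mean(q) < minQuality) { ins[i] <- ""; qual[i] <- "" }
            next
        }
        cs <- cumsum(c(0, q))
        wm <- (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
        bad <- which(wm < minQuality)
        if (length(bad)) {
            # cut at the failing window, then keep any leading bases of that
            # window still individually above threshold
            keep <- bad[1] - 1L
            while (keep < L && q[keep + 1L] >= minQuality) keep <- keep + 1L
            ins[i] <- substr(ins[i], 1L, keep)
            qual[i] <- substr(qual[i], 1L, keep)
        }
    }
    assignments$insert <- ins
    assignments$quality <- qual
    assignments$empty <- nchar(ins) == 0L
    assignments
}
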