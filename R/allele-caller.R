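#' Candidate alleles under the half-maximum-depth rule
#'
#' The top-depth sequence is always a candidate, together with every sequence
#' whose depth is strictly greater than half the top depth. Sequences tied
#' for the top depth are all candidates (a tied top trivially exceeds half of
#' itself).
#'
#' @param sequences character vector of unique sequences for one colony-locus.
#' @param depths matching read depths.
#' @return data.frame (sequence, depth) ordered by decreasing depth; zero
#'   rows when the input is empty (a missing call, not an error).
#' @export
selectCandidates <- function(sequences, depths) {
    if (!length(sequences))
        return(data.frame(sequence = character(), depth = integer()))
    stopifnot(length(sequences) == length(depths), all(depths >= 1))
    keep <- depths > max(depths) / 2
    ord <- order(-depths[keep])
    data.frame(sequence = sequences[keep][ord],
               depth = as.integer(depths[keep][ord]),
               stringsAsFactors = FALSE)
}

#' Resolve a candidate set to an ordered diploid genotype
#'
#' The first allele is always the top-depth sequence (ties for the top broken
#' at random). With a single candidate the call is homozygous. With several,
#' the second allele is either the next-highest-depth candidate (`"depth"`
#' strategy; ties among the second-highest depth broken at random) or a
#' uniform draw from all non-top candidates (`"random"` strategy).
#'
#' @param candidates data.frame from [selectCandidates()].
#' @param strategy `"depth"` or `"random"`.
#' @return character vector (allele1, allele2), or `c(NA, NA)` for an empty
#'   candidate set.
#' @export
resolveGenotype <- function(candidates, strategy = c("depth", "random")) {
    strategy <- match.arg(strategy)
    k <- nrow(candidates)
    if (k == 0L) return(c(NA_character_, NA_character_))
    # random tie-break within equal depths, then stable sort by depth
    ord <- sample.int(k)
    ord <- ord[order(-candidates$depth[ord])]
    seqs <- candidates$sequence[ord]
    if (k == 1L) return(c(seqs[1], seqs[1]))
    a2 <- if (strategy == "depth") seqs[2]
          else seqs[1 + sample.int(k - 1L, 1L)]
    c(seqs[1], a2)
}

#' Call genotypes for every colony-locus in a filtered tally
#'
#' @param tally a filtered [SeqTally].
#' @param strategy `"depth"` or `"random"` (second-allele choice for
#'   multi-candidate colonies).
#' @param seed RNG seed for the random tie-breaks/draws.
#' @param individuals optional data.frame (site, colony) fixing the set of
#'   individuals; colony-loci absent from the tally are missing calls.
#' @return data.frame (site, colony, locus, seq1, seq2, n_candidates).
#' @export
callGenotypes <- function(tally, strategy = c("depth", "random"), seed = 1L,
                          individuals = NULL) {
    strategy <- match.arg(strategy)
    stopifnot(is(tally, "SeqTally"))
    tt <- tallyTable(tally)
    withSeed(seed, {
        dt <- data.table::as.data.table(tt)
        res <- dt[, {
            cand <- selectCandidates(sequence, depth)
            g <- resolveGenotype(cand, strategy)
            list(seq1 = g[1], seq2 = g[2], n_candidates = nrow(cand))
        }, by = c("site", "colony", "locus")]
        calls <- as.data.frame(res)
        if (!is.null(individuals)) {
            loci <- unique(tt$locus)
            grid <- merge(individuals, data.frame(locus = loci), by = NULL)
            calls <- merge(grid, calls, all.x = TRUE,
                           by = c("site", "colony", "locus"))
            calls$n_candidates[is.na(calls$n_candidates)] <- 0L
        }
        calls
    })
}

#' Replicate datasets from repeated random second-allele selection
#'
#' Re-draws the random-strategy calls `k` times with independent derived
#' seeds, producing `k` genotype matrices that differ only at colonies with
#' more than two candidate alleles. Replicate 0 (named `random000`) is the
#' canonical analysis dataset.
#'
#' @param tally a filtered [SeqTally].
#' @param loci list of [LocusSpec].
#' @param islands named character site -> island.
#' @param encoding `"length"` or `"unique_id"`.
#' @param k number of replicates (default 10).
#' @param seed master seed; replicate i uses a derived child seed.
#' @param individuals optional individual universe (see [callGenotypes()]).
#' @return named list of `k` [GenotypeMatrix] objects.
#' @export
generateReplicateDatasets <- function(tally, loci, islands, encoding = "unique_id",
                                      k = 10L, seed = 1L, individuals = NULL) {
    out <- vector("list", k)
    for (i in seq_len(k)) {
        calls <- callGenotypes(tally, strategy = "random",
                               seed = deriveSeed(seed, sprintf("random%03d", i - 1L)),
                               individuals = individuals)
        out[[i]] <- encodeAlleles(calls, loci, islands, encoding)
    }
    names(out) <- sprintf("random%03d", seq_len(k) - 1L)
    out
}

# consensus score of a periodic region: +1 per base matching the per-phase
# consensus, -1 per mismatch (etandem's scoring)
.consensusScore <- function(chars, s, e, m) {
    matches <- 0L
    motif <- character(m)
    for (ph in seq_len(m)) {
        pos <- seq(s + ph - 1L, e, by = m)
        tb <- tabulate(factor(chars[pos], levels = .DNA_BASES), nbins = 4L)
        matches <- matches + max(tb)
        motif[ph] <- .DNA_BASES[which.max(tb)]
    }
    len <- e - s + 1L
    list(score = 2L * matches - len, motif = paste(motif, collapse = ""))
}

#' Separate a tandem repeat from its flanking regions
#'
#' Scans motif sizes 2-6 for tandem runs (period-m self-match), scores each
#' run as matches minus mismatches against the periodic consensus, and merges
#' adjacent runs across short interruptions when that raises the score, so
#' near-perfect repeats are handled. Returns the maximal-score run; ties go
#' to the longer region, then the leftmost, then the smallest motif (a pure
#' dinucleotide run also matches period 4 and 6 with equal score).
#'
#' @param sequence DNA string.
#' @return list with leftFlank, repeatRegion, rightFlank, motif, score,
#'   found. When no run of >= 2 motif copies exists the whole sequence is
#'   returned as leftFlank with `found = FALSE`.
#' @export
splitTandemRepeat <- function(sequence) {
    none <- list(leftFlank = sequence, repeatRegion = "", rightFlank = "",
                 motif = "", score = 0L, found = FALSE)
    n <- nchar(sequence)
    if (n < 4L) return(none)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    best <- NULL
    for (m in 2:6) {
        if (n < 2L * m) next
        b <- chars[seq_len(n - m)] == chars[(m + 1L):n]
        r <- rle(b)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runIdx <- which(r$values & r$lengths >= m)
        if (!length(runIdx)) next
        segs <- data.frame(s = starts[runIdx], e = ends[runIdx] + m)
        # merge pass: join neighbouring runs interrupted by a point change
        # (a substitution inside a repeat breaks the self-match for exactly
        # m positions and preserves the phase); merging requires phase
        # agreement, a gap of at most m, and a consensus score gain
        i <- 1L
        while (i < nrow(segs)) {
            phaseOk <- (segs$s[i + 1L] - segs$s[i]) %% m == 0L
            gapOk <- segs$s[i + 1L] - segs$e[i] - 1L <= m
            if (phaseOk && gapOk) {
                sc1 <- .consensusScore(chars, segs$s[i], segs$e[i], m)$score
                sc2 <- .consensusScore(chars, segs$s[i + 1L], segs$e[i + 1L], m)$score
                scm <- .consensusScore(chars, segs$s[i], segs$e[i + 1L], m)$score
                if (scm > max(sc1, sc2)) {
                    segs$e[i] <- segs$e[i + 1L]
                    segs <- segs[-(i + 1L), , drop = FALSE]
                    next
                }
            }
            i <- i + 1L
        }
        for (j in seq_len(nrow(segs))) {
            # regions hold an integral number of motif copies: trim the run
            # to the best-scoring span whose length is a multiple of m
            L <- segs$e[j] - segs$s[j] + 1L
            L2 <- (L %/% m) * m
            if (L2 < 2L * m) next
            bestSub <- NULL
            for (off in 0:(L - L2)) {
                s0 <- segs$s[j] + off
                cs0 <- .consensusScore(chars, s0, s0 + L2 - 1L, m)
                if (is.null(bestSub) || cs0$score > bestSub$score)
                    bestSub <- list(s = s0, e = s0 + L2 - 1L, score = cs0$score,
                                    motif = cs0$motif)
            }
            cs <- bestSub
            cand <- list(s = cs$s, e = cs$e, m = m,
                         score = cs$score, motif = cs$motif)
            if (is.null(best) ||
                cand$score > best$score ||
                (cand$score == best$score &&
                 (cand$e - cand$s > best$e - best$s ||
                  (cand$e - cand$s == best$e - best$s &&
                   (cand$s < best$s ||
                    (cand$s == best$s && cand$m < best$m))))))
                best <- cand
        }
    }
    if (is.null(best)) return(none)
    list(leftFlank = substr(sequence, 1L, best$s - 1L),
         repeatRegion = substr(sequence, best$s, best$e),
         rightFlank = substr(sequence, best$e + 1L, n),
         motif = best$motif, score = best$score, found = TRUE)
}

# cached STR split over a vector of sequences
.splitRepeatLengths <- function(seqs) {
    uni <- unique(seqs)
    info <- lapply(uni, splitTandemRepeat)
    data.frame(sequence = uni,
               repeatLen = vapply(info, function(x)
                   if (x$found) nchar(x$repeatRegion) else NA_integer_,
                   numeric(1)),
               motifLen = vapply(info, function(x)
                   if (x$found) nchar(x$motif) else NA_integer_, numeric(1)),
               stringsAsFactors = FALSE)
}

# shared GenotypeMatrix assembly from a calls table with seq1/seq2 columns
.buildGenotypeMatrix <- function(calls, lociByName, islands, encoding) {
    ind <- unique(calls[, c("site", "colony")])
    ind <- ind[order(match(ind$site, names(islands)), ind$colony), , drop = FALSE]
    indId <- paste(ind$site, ind$colony, sep = ":")
    lociNames <- intersect(names(lociByName), unique(calls$locus))
    if (!length(lociNames)) lociNames <- sort(unique(calls$locus))
    a1 <- matrix(NA_integer_, length(lociNames), nrow(ind),
                 dimnames = list(lociNames, indId))
    a2 <- a1
    key <- list()
    callId <- paste(calls$site, calls$colony, sep = ":")
    for (ln in lociNames) {
        sel <- which(calls$locus == ln & !is.na(calls$seq1))
        if (!length(sel)) { key[[ln]] <- data.frame(label = integer(),
            value = character(), code = integer()); next }
        s1 <- calls$seq1[sel]; s2 <- calls$seq2[sel]
        if (encoding == "unique_id") {
            vals <- sort(unique(c(s1, s2)))
            lab1 <- match(s1, vals); lab2 <- match(s2, vals)
            code <- seq_along(vals)
            keep <- rep(TRUE, length(sel))
        } else {
            sp <- .splitRepeatLengths(unique(c(s1, s2)))
            len1 <- sp$repeatLen[match(s1, sp$sequence)]
            len2 <- sp$repeatLen[match(s2, sp$sequence)]
            keep <- !is.na(len1) & !is.na(len2)  # no detectable repeat: missing
            lens <- sort(unique(c(len1[keep], len2[keep])))
            vals <- as.character(lens)
            lab1 <- match(len1, lens); lab2 <- match(len2, lens)
            mlen <- if (ln %in% names(lociByName))
                nchar(lociByName[[ln]]@motif)
            else stats::median(sp$motifLen, na.rm = TRUE)
            code <- as.integer(round(lens / mlen))
        }
        if (length(vals) && max(code) > 999L)
            stop(sprintf("allele code overflow (>999) at locus %s", ln))
        cols <- match(callId[sel], indId)
        a1[ln, cols[keep]] <- lab1[keep]
        a2[ln, cols[keep]] <- lab2[keep]
        key[[ln]] <- data.frame(label = seq_along(vals), value = vals,
                                code = code, stringsAsFactors = FALSE)
    }
    GenotypeMatrix(a1, a2, site = ind$site,
                   island = unname(islands[ind$site]),
                   encoding = encoding, alleleKey = key)
}

#' Encode called genotypes as a GenotypeMatrix
#'
#' Length mode labels an allele by the length of its tandem-repeat region
#' (flank variation is invisible, as in fragment-length peak calling);
#' unique-ID mode gives every distinct full sequence its own label. Label
#' tables are kept in `metadata(x)$alleleKey`; genepop codes are repeat-unit
#' counts (length mode) or label integers (unique-ID mode).
#'
#' @param calls data.frame from [callGenotypes()].
#' @param loci list of [LocusSpec].
#' @param islands named character site -> island.
#' @param encoding `"length"` or `"unique_id"`.
#' @return a [GenotypeMatrix].
#' @export
encodeAlleles <- function(calls, loci, islands,
                          encoding = c("unique_id", "length")) {
    encoding <- match.arg(encoding)
    lociByName <- stats::setNames(loci, vapply(loci, function(l) l@name,
                                               character(1)))
    .buildGenotypeMatrix(calls, lociByName, islands, encoding)
}
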