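#' Default microsatellite locus panel
#'
#' A deterministic panel of loci mimicking a typical coral microsatellite
#' study: mostly dinucleotide motifs with a few tri-/tetranucleotides, 20 bp
#' primers and ~15-25 bp flanks, repeat counts spanning roughly 6-20 units so
#' every insert falls well inside the 15-190 bp length filters.
#'
#' @param nLoci number of loci (default 11, the study's analysed panel size).
#' @param seed internal seed for the deterministic sequence draws.
#' @return list of [LocusSpec] objects named loc01, loc02, ...
#' @export
defaultLocusPanel <- function(nLoci = 11L, seed = 101L) {
    motifs <- rep(c("AC", "AG", "TC", "GT", "CA", "AT", "AAG", "ATC", "ACAG"),
                  length.out = nLoci)
    # flanks carry no short tandem of their own and cannot extend the repeat
    # run across the junction, so the repeat/flank boundary is unambiguous
    flankDraw <- function(len, m, side) {
        repeat {
            s <- .randomDna(1L, len, avoid = m, tandemFree = TRUE)
            clean <- if (side == "left")
                !endsWith(s, substr(m, nchar(m), nchar(m)))
            else !startsWith(s, substr(m, 1L, 1L))
            if (clean) return(s)
        }
    }
    withSeed(seed, {
        lapply(seq_len(nLoci), function(i) {
            m <- motifs[i]
            minRep <- 6L
            maxRep <- as.integer(minRep + 13L)  # allele space of 14 counts
            LocusSpec(
                name = sprintf("loc%02d", i),
                fwdPrimer = .randomDna(1L, 20L, avoid = m),
                rvsPrimer = .randomDna(1L, 20L, avoid = m),
                leftFlank = flankDraw(15L + (i %% 6L), m, "left"),
                rightFlank = flankDraw(15L + ((i + 3L) %% 6L), m, "right"),
                motif = m,
                repeatRange = c(minRep, maxRep))
        }) -> loci
        names(loci) <- vapply(loci, function(l) l@name, character(1))
        loci
    })
}

#' Default barcode scheme
#'
#' 6 bp site tags and 48 unique 6 bp colony tags, all pairwise Hamming
#' distance >= 2 within their tier.
#'
#' @param sites site labels (default: the seven-site, three-island layout of
#'   the emulated study design).
#' @param seed internal seed for the deterministic tag draws.
#' @export
defaultBarcodeScheme <- function(sites = defaultSites()$site, seed = 202L) {
    makeTags <- function(n, len) {
        tags <- character(0)
        while (length(tags) < n) {
            cand <- paste(sample(.DNA_BASES, len, replace = TRUE), collapse = "")
            ok <- all(vapply(tags, function(t) .hammingDist(t, cand) >= 2L,
                             logical(1)))
            if (ok) tags <- c(tags, cand)
        }
        tags
    }
    withSeed(seed, {
        st <- makeTags(length(sites), 6L)
        names(st) <- sites
        BarcodeScheme(siteTags = st, colonyTags = makeTags(48L, 6L))
    })
}

#' Default site layout: seven sites on three island groups
#'
#' Mirrors the emulated study design: three sites on Palau, three on Yap and
#' one on Ngulu, 48 colonies each.
#'
#' @export
defaultSites <- function() {
    data.frame(
        site = c("S17", "S20", "S24", "S27", "S29", "S30", "S28"),
        island = c("Palau", "Palau", "Palau", "Yap", "Yap", "Yap", "Ngulu"),
        n = rep(48L, 7L),
        stringsAsFactors = FALSE)
}

#' Simulator configuration with study-design defaults
#'
#' Defaults emulate the study design: 7 sites on 3 islands, 48 diploid
#' colonies per site, 11 loci, island-model divergence at the given
#' `thetaFst`. Read depth per colony-locus is negative binomial; heterozygote
#' reads split by a concentrated Beta draw; stutter moves a read +-1 repeat
#' unit; point errors flip single bases. See the methods vignette for the
#' reasoning behind each default.
#'
#' @param sites,islands,popSizes site layout (defaults: [defaultSites()]).
#' @param thetaFst island-model divergence (default 0.10).
#' @param loci list of [LocusSpec] (default [defaultLocusPanel()]).
#' @param meanDepth,depthDispersion negative binomial depth (mu 50, size 8).
#' @param alleleBalanceBeta Beta split concentration (150).
#' @param stutterRate per-read +-1-repeat slip probability (0.35).
#' @param errorRate per-base substitution probability (0.001).
#' @param lowQualTailFrac,lowQualTailLen low-quality tail: fraction of reads
#'   (0.10) and tail length (10 bases, shorter than any reverse primer so the
#'   tail exercises quality trimming without touching the insert).
#' @param nFlankVariants same-length flank-SNP alleles per locus (1).
#' @param seed master seed.
#' @export
SimConfig <- function(sites = defaultSites()$site,
                      islands = stats::setNames(defaultSites()$island, defaultSites()$site),
                      popSizes = stats::setNames(defaultSites()$n, defaultSites()$site),
                      thetaFst = 0.10,
                      loci = defaultLocusPanel(),
                      meanDepth = 50, depthDispersion = 8,
                      alleleBalanceBeta = 150,
                      stutterRate = 0.35, errorRate = 0.001,
                      lowQualTailFrac = 0.10, lowQualTailLen = 10L,
                      nFlankVariants = 1L, seed = 1L) {
    popSizes <- stats::setNames(as.integer(popSizes), names(popSizes))
    new("SimConfig", sites = sites, islands = islands,
        popSizes = popSizes, thetaFst = thetaFst, loci = loci,
        meanDepth = meanDepth, depthDispersion = depthDispersion,
        alleleBalanceBeta = alleleBalanceBeta, stutterRate = stutterRate,
        errorRate = errorRate, lowQualTailFrac = lowQualTailFrac,
        lowQualTailLen = as.integer(lowQualTailLen),
        nFlankVariants = as.integer(nFlankVariants), seed = as.integer(seed))
}

#' Build a full allele sequence from a repeat count
#'
#' Concatenates left flank + motif x repeats + right flank.
#'
#' @param locus a [LocusSpec].
#' @param repeats repeat count, within the locus's `repeatRange`.
#' @export
buildAlleleSequence <- function(locus, repeats) {
    stopifnot(is(locus, "LocusSpec"))
    repeats <- as.integer(repeats)
    rr <- locus@repeatRange
    if (any(is.na(repeats)) || any(repeats < rr[1]) || any(repeats > rr[2]))
        stop(sprintf("repeat count outside range [%d, %d] for locus %s",
                     rr[1], rr[2], locus@name))
    paste0(locus@leftFlank, strrep(locus@motif, repeats), locus@rightFlank)
}

#' Draw per-population allele frequencies under an island model
#'
#' Balding-Nichols construction: each population's frequency vector is an
#' independent Dirichlet(ancestral * (1 - theta) / theta) draw, so the
#' expected Weir-Cockerham theta across populations equals `theta`.
#'
#' @param ancestral ancestral frequency simplex (named by allele).
#' @param theta divergence parameter in (0, 1).
#' @param nPops number of populations.
#' @return matrix nPops x alleles, rows summing to 1.
#' @export
drawPopFreqs <- function(ancestral, theta, nPops) {
    if (!(theta > 0 && theta < 1)) stop("theta must be in (0, 1)")
    if (abs(sum(ancestral) - 1) > 1e-8) stop("ancestral must sum to 1")
    scale <- (1 - theta) / theta
    k <- length(ancestral)
    g <- matrix(stats::rgamma(nPops * k,
                              shape = rep(ancestral * scale, each = nPops)),
                nrow = nPops, ncol = k)
    fr <- g / rowSums(g)
    colnames(fr) <- names(ancestral)
    fr
}

# allele table for one locus: core alleles on distinct repeat counts plus
# optional flank-SNP variants (same length, different sequence); ancestral
# frequencies decay geometrically so no simulated allele is vanishingly rare
.alleleInfoForLocus <- function(locus, nCoreAlleles = 8L, nFlankVariants = 1L,
                                decay = 0.8) {
    rr <- locus@repeatRange
    nCoreAlleles <- min(nCoreAlleles, rr[2] - rr[1] + 1L)
    reps <- as.integer(round(seq(rr[1], rr[2], length.out = nCoreAlleles)))
    reps <- unique(reps)
    info <- data.frame(
        repeats = reps,
        leftFlank = locus@leftFlank,
        rightFlank = locus@rightFlank,
        variant = FALSE,
        stringsAsFactors = FALSE)
    if (nFlankVariants > 0L) {
        for (v in seq_len(nFlankVariants)) {
            # variant duplicates the v-th core repeat count with one SNP in
            # the right flank (position v, substituted cyclically)
            rf <- locus@rightFlank
            pos <- ((v - 1L) %% nchar(rf)) + 1L
            old <- substr(rf, pos, pos)
            newBase <- .DNA_BASES[(match(old, .DNA_BASES)) %% 4L + 1L]
            substr(rf, pos, pos) <- newBase
            if (grepl(strrep(locus@motif, 2L), rf, fixed = TRUE)) next
            info <- rbind(info, data.frame(
                repeats = reps[v], leftFlank = locus@leftFlank,
                rightFlank = rf, variant = TRUE, stringsAsFactors = FALSE))
        }
    }
    info$sequence <- paste0(info$leftFlank,
                            strrep(locus@motif, info$repeats),
                            info$rightFlank)
    w <- decay^(seq_len(nrow(info)) - 1L)
    info$ancestralFreq <- w / sum(w)
    info
}

#' Simulate a truth set: population frequencies and diploid genotypes
#'
#' Builds the allele space per locus, draws island-model population
#' frequencies at `thetaFst`, and samples Hardy-Weinberg genotypes for every
#' colony.
#'
#' @param config a [SimConfig].
#' @return a [TruthSet].
#' @export
simulateTruth <- function(config) {
    stopifnot(is(config, "SimConfig"))
    withSeed(deriveSeed(config@seed, "truth"), {
        popFreqs <- list(); alleleInfo <- list()
        for (locus in config@loci) {
            info <- .alleleInfoForLocus(locus,
                                        nFlankVariants = config@nFlankVariants)
            anc <- stats::setNames(info$ancestralFreq, info$sequence)
            fr <- drawPopFreqs(anc, config@thetaFst, length(config@sites))
            rownames(fr) <- config@sites
            popFreqs[[locus@name]] <- fr
            alleleInfo[[locus@name]] <- info
        }
        geno <- simulateGenotypes(popFreqs, config@popSizes)
        # annotate repeat counts from the allele table
        for (ln in names(alleleInfo)) {
            info <- alleleInfo[[ln]]
            sel <- geno$locus == ln
            geno$repeats1[sel] <- info$repeats[match(geno$allele1[sel], info$sequence)]
            geno$repeats2[sel] <- info$repeats[match(geno$allele2[sel], info$sequence)]
        }
        new("TruthSet", popFreqs = popFreqs, alleleInfo = alleleInfo,
            genotypes = geno, thetaFst = config@thetaFst)
    })
}

#' Sample Hardy-Weinberg genotypes from population frequencies
#'
#' Each colony receives two independent allele draws from its population's
#' frequency vector, in randomized order.
#'
#' @param popFreqs list per locus of populations x alleles frequency matrices
#'   (rownames = site, colnames = allele).
#' @param popSizes named integer, colonies per site.
#' @return data.frame (site, colony, locus, allele1, allele2).
#' @export
simulateGenotypes <- function(popFreqs, popSizes) {
    rows <- list()
    for (ln in names(popFreqs)) {
        fr <- popFreqs[[ln]]
        for (s in rownames(fr)) {
            n <- popSizes[[s]]
            p <- fr[s, ]
            a1 <- sample(colnames(fr), n, replace = TRUE, prob = p)
            a2 <- sample(colnames(fr), n, replace = TRUE, prob = p)
            swap <- stats::runif(n) < 0.5
            tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
            rows[[length(rows) + 1L]] <- data.frame(
                site = s,
                colony = sprintf("%s_C%02d", s, seq_len(n)),
                locus = ln, allele1 = a1, allele2 = a2,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# stutter: shift a read's repeat count by +-1 (floor at 1 repeat), keeping
# the read's own flanks
.applyStutter <- function(reps, motif, lf, rf, stutterRate) {
    hit <- stats::runif(length(reps)) < stutterRate
    if (any(hit)) {
        dir <- ifelse(stats::runif(sum(hit)) < 0.5, -1L, 1L)
        newReps <- pmax(1L, reps[hit] + dir)
        reps[hit] <- newReps
    }
    list(reps = reps, seqs = paste0(lf, strrep(motif, reps), rf))
}

#' Simulate an amplicon FASTQ library from a truth set
#'
#' Writes one 4-line FASTQ per site plus tab-separated truth tables. Each
#' read is siteTag + colonyTag + forward primer + insert + reverse primer;
#' total colony-locus depth is negative binomial, split between a
#' heterozygote's alleles by a Beta draw; stutter moves individual reads +-1
#' repeat unit; every base flips with `errorRate`; a configurable fraction of
#' reads carries a low-quality tail.
#'
#' @param truth a [TruthSet] from [simulateTruth()].
#' @param config the [SimConfig] used to build it.
#' @param scheme a [BarcodeScheme]; must provide a tag for every site and
#'   colony.
#' @param outDir output directory (created if needed).
#' @param gzip compress the FASTQ output.
#' @return list with `fastq` (named paths per site), `truthFile`,
#'   `readCounts` (data.frame site, colony, locus, n_reads).
#' @export
simulateReadSet <- function(truth, config, scheme = defaultBarcodeScheme(config@sites),
                            outDir = tempfile("amplistr_sim_"), gzip = FALSE) {
    stopifnot(is(truth, "TruthSet"), is(config, "SimConfig"),
              is(scheme, "BarcodeScheme"))
    if (!all(config@sites %in% names(scheme@siteTags)))
        stop("barcode scheme lacks tags for some sites")
    if (max(config@popSizes) > length(scheme@colonyTags))
        stop("barcode scheme lacks colony tags for the largest site")
    if (any(nchar(scheme@siteTags) < 1L) || any(nchar(scheme@colonyTags) < 1L))
        stop("config error: tags must be at least 1 nt")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    lociByName <- stats::setNames(config@loci,
                                  vapply(config@loci, function(l) l@name, character(1)))
    geno <- truth@genotypes
    fastqPaths <- character(0)
    countRows <- list()

    withSeed(deriveSeed(config@seed, "reads"), {
        for (s in config@sites) {
            gs <- geno[geno$site == s, , drop = FALSE]
            colonies <- unique(gs$colony)
            colonyTag <- stats::setNames(
                scheme@colonyTags[seq_along(colonies)], colonies)
            seqsAll <- character(0); qualAll <- character(0); idAll <- character(0)
            for (r in seq_len(nrow(gs))) {
                locus <- lociByName[[gs$locus[r]]]
                info <- truth@alleleInfo[[gs$locus[r]]]
                d <- stats::rnbinom(1L, size = config@depthDispersion,
                                    mu = config@meanDepth)
                countRows[[length(countRows) + 1L]] <- data.frame(
                    site = s, colony = gs$colony[r], locus = gs$locus[r],
                    n_reads = d, stringsAsFactors = FALSE)
                if (d == 0L) next
                het <- gs$allele1[r] != gs$allele2[r]
                if (het) {
                    b <- stats::rbeta(1L, config@alleleBalanceBeta,
                                      config@alleleBalanceBeta)
                    d1 <- as.integer(round(d * b)); d2 <- d - d1
                } else { d1 <- d; d2 <- 0L }
                mkReads <- function(alleleSeq, n) {
                    if (n <= 0L) return(character(0))
                    i <- match(alleleSeq, info$sequence)
                    st <- .applyStutter(rep(info$repeats[i], n), locus@motif,
                                        info$leftFlank[i], info$rightFlank[i],
                                        config@stutterRate)
                    st$seqs
                }
                inserts <- c(mkReads(gs$allele1[r], d1),
                             if (het) mkReads(gs$allele2[r], d2) else character(0))
                reads <- paste0(scheme@siteTags[[s]], colonyTag[[gs$colony[r]]],
                                locus@fwdPrimer, inserts, locus@rvsPrimer)
                reads <- .mutateBases(reads, config@errorRate)
                qual <- strrep("I", nchar(reads))
                tail <- stats::runif(length(reads)) < config@lowQualTailFrac
                if (any(tail)) {
                    tl <- pmin(config@lowQualTailLen, nchar(reads[tail]))
                    qual[tail] <- paste0(
                        substr(qual[tail], 1L, nchar(reads[tail]) - tl),
                        strrep("#", tl))
                }
                seqsAll <- c(seqsAll, reads)
                qualAll <- c(qualAll, qual)
                idAll <- c(idAll, sprintf("%s:%s:%06d", s, gs$colony[r],
                                          seq_along(reads) + length(idAll)))
            }
            path <- file.path(outDir, paste0(s, if (gzip) ".fastq.gz" else ".fastq"))
            .writeFastq(seqsAll, qualAll, idAll, path)
            fastqPaths[s] <- path
        }
    })

    truthFile <- file.path(outDir, "truth_genotypes.tsv")
    utils::write.table(geno, truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    readCounts <- do.call(rbind, countRows)
    utils::write.table(readCounts, file.path(outDir, "truth_read_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fastq = fastqPaths, truthFile = truthFile, readCounts = readCounts,
         outDir = outDir)
}

#' Encode a truth set directly as a GenotypeMatrix
#'
#' Bypasses reads entirely: the known genotypes are encoded with the same
#' length / unique-sequence-identity rules the allele caller uses, so
#' estimator properties can be studied without sequencing noise.
#'
#' @param truth a [TruthSet].
#' @param config the matching [SimConfig] (for site-to-island mapping).
#' @param encoding `"length"` or `"unique_id"`.
#' @return a [GenotypeMatrix].
#' @export
truthGenotypes <- function(truth, config, encoding = c("unique_id", "length")) {
    encoding <- match.arg(encoding)
    geno <- truth@genotypes
    lociByName <- stats::setNames(config@loci,
                                  vapply(config@loci, function(l) l@name, character(1)))
    calls <- geno
    names(calls)[names(calls) == "allele1"] <- "seq1"
    names(calls)[names(calls) == "allele2"] <- "seq2"
    .buildGenotypeMatrix(calls, lociByName, config@islands, encoding)
}

#' Analytic F-statistics from true population frequencies
#'
#' The infinite-sample limit of the Weir-Cockerham variance components,
#' evaluated on the true per-population allele frequencies under
#' Hardy-Weinberg within populations; FST(max) recodes every allele to be
#' population-private, giving the Meirmans standardized F'ST. This is the
#' matched oracle for the sample-based AMOVA estimator.
#'
#' @param truth a [TruthSet].
#' @return named numeric: fst, fst_max, fst_std.
#' @export
truthFstats <- function(truth) {
    comp <- function(frList) {
        A <- 0; ABC <- 0
        for (fr in frList) {
            r <- nrow(fr)
            for (k in seq_len(ncol(fr))) {
                p <- fr[, k]
                pbar <- mean(p)
                s2 <- if (r > 1) sum((p - pbar)^2) / (r - 1) else 0
                hbar <- mean(2 * p * (1 - p))
                a <- s2
                b <- pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 2
                cc <- hbar / 2
                A <- A + a; ABC <- ABC + a + b + cc
            }
        }
        A / ABC
    }
    recode <- function(fr) {
        r <- nrow(fr); k <- ncol(fr)
        out <- matrix(0, r, r * k)
        for (i in seq_len(r))
            out[i, ((i - 1) * k + 1):(i * k)] <- fr[i, ]
        out
    }
    fst <- comp(truth@popFreqs)
    fstMax <- comp(lapply(truth@popFreqs, recode))
    c(fst = fst, fst_max = fstMax, fst_std = fst / fstMax)
}
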