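asgRow <- function(site, colony, locus, insert)
    data.frame(site = site, colony = colony, locus = locus, insert = insert,
               stringsAsFactors = FALSE)

test_that("collapseReads collapses exact duplicates and conserves reads", {
    asg <- asgRow("S", "c1", "l1", c("ACGT", "ACGT", "ACGA"))
    tt <- tallyTable(collapseReads(asg))
    expect_identical(sort(tt$sequence), c("ACGA", "ACGT"))
    expect_identical(tt$depth[match(c("ACGT", "ACGA"), tt$sequence)], c(2L, 1L))
    expect_identical(sum(tt$depth), 3L)
    empty <- collapseReads(asgRow(character(0), character(0), character(0),
                                  character(0)))
    expect_identical(nrow(tallyTable(empty)), 0L)
})

test_that("length filter keeps the stated boundary cases", {
    tt <- data.frame(site = "S", colony = paste0("c", 1:4), locus = "l1",
                     sequence = c(strrep("A", 14), strrep("A", 15),
                                  strrep("C", 190), strrep("C", 191)),
                     depth = 5L, stringsAsFactors = FALSE)
    res <- applyLengthFilter(SeqTally(tt), minLen = 15, maxLen = 190)
    expect_setequal(nchar(tallyTable(res$tally)$sequence), c(15L, 190L))
    expect_setequal(res$rejects$reject_reason, c("too_short", "too_long"))
})

test_that("per-locus cap is longest known sequence + 4 repeat units", {
    loc <- LocusSpec("l1", strrep("ACGT", 5), strrep("TGCA", 5), "AAGT", "CCT",
                     "GA", c(3L, 60L), maxKnownLength = 150L)
    tt <- data.frame(site = "S", colony = "c1", locus = "l1",
                     sequence = c(strrep("A", 158), strrep("A", 159)),
                     depth = 5L, stringsAsFactors = FALSE)
    res <- applyLengthFilter(SeqTally(tt), loci = list(loc))
    expect_identical(nchar(tallyTable(res$tally)$sequence), 158L)
})

test_that("depth and prevalence filters follow the pooled rules", {
    # pooled depth 9 across 3 colonies -> removed by the depth rule
    # depth 500 in a single colony -> removed by the prevalence rule
    tt <- data.frame(
        site = "S",
        colony = c("c1", "c2", "c3", "c4", "c5", "c6"),
        locus = "l1",
        sequence = c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG", "GGGG"),
        depth = c(3L, 3L, 3L, 500L, 30L, 40L),
        stringsAsFactors = FALSE)
    res <- applyDepthPrevalenceFilters(SeqTally(tt))
    expect_setequal(unique(tallyTable(res$tally)$sequence), "GGGG")
    expect_error(applyDepthPrevalenceFilters(SeqTally(tt), minDepth = 0L),
                 ">= 1")
})

randomTally <- function(n, nCol = 8L, seed) {
    withr::with_seed(seed, data.frame(
        site = "S",
        colony = sample(paste0("c", seq_len(nCol)), n, replace = TRUE),
        locus = sample(c("l1", "l2"), n, replace = TRUE),
        sequence = vapply(sample(4:40, n, replace = TRUE), function(k)
            paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                  collapse = ""), character(1)),
        depth = sample(1:30, n, replace = TRUE),
        stringsAsFactors = FALSE))
}

dedupTally <- function(tt) {
    key <- paste(tt$site, tt$colony, tt$locus, tt$sequence)
    tt[!duplicated(key), ]
}

test_that("filters equal brute-force predicate evaluation on random tallies", {
    for (seed in 1:25) {
        tt <- dedupTally(randomTally(30L, seed = seed))
        tal <- SeqTally(tt)
        lenKeep <- applyLengthFilter(tal, minLen = 10, maxLen = 30)$tally
        bruteLen <- tt[nchar(tt$sequence) >= 10 & nchar(tt$sequence) <= 30, ]
        expect_identical(nrow(tallyTable(lenKeep)), nrow(bruteLen))
        res <- applyDepthPrevalenceFilters(tal, minDepth = 8L, minColonies = 2L)
        # brute force: pool per locus over the whole dataset
        key <- paste(tt$locus, tt$sequence)
        pooledDepth <- tapply(tt$depth, key, sum)
        pooledCol <- tapply(paste(tt$site, tt$colony), key,
                            function(x) length(unique(x)))
        keep <- pooledDepth[key] >= 8 & pooledCol[key] >= 2
        expect_identical(sort(paste(tallyTable(res$tally)$colony,
                                    tallyTable(res$tally)$sequence)),
                         sort(paste(tt$colony[keep], tt$sequence[keep])))
    }
})

test_that("filter composition is monotone and no colony gains sequences", {
    tt <- dedupTally(randomTally(60L, seed = 101))
    tal <- SeqTally(tt)
    lenOnly <- applyLengthFilter(tal, 10, 30)$tally
    dpOnly <- applyDepthPrevalenceFilters(tal, 8L, 2L)$tally
    composed <- applyDepthPrevalenceFilters(lenOnly, 8L, 2L)$tally
    idOf <- function(x) paste(tallyTable(x)$colony, tallyTable(x)$sequence)
    expect_true(all(idOf(composed) %in% idOf(lenOnly)))
    expect_true(all(idOf(composed) %in% idOf(dpOnly)))
    perColony <- function(x) table(factor(tallyTable(x)$colony,
                                          levels = unique(tt$colony)))
    expect_true(all(perColony(composed) <= perColony(lenOnly)))
})
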