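# shared fixtures: everything is generated in code, no stored data

tinyPanel <- function(n = 4L) defaultLocusPanel(n)

tinySites <- function() {
    list(sites = c("A", "B", "C"),
         islands = stats::setNames(c("I1", "I1", "I2"), c("A", "B", "C")))
}

tinyConfig <- function(popSize = 8L, nLoci = 4L, seed = 7L, ...) {
    ts <- tinySites()
    SimConfig(sites = ts$sites, islands = ts$islands,
              popSizes = stats::setNames(rep(popSize, 3L), ts$sites),
              loci = defaultLocusPanel(nLoci), seed = seed, ...)
}

# build a one-or-more-locus GenotypeMatrix from allele label vectors
makeGm <- function(a1, a2, site, island = site, loci = NULL) {
    a1 <- rbind(a1); a2 <- rbind(a2)
    if (is.null(loci)) loci <- sprintf("L%02d", seq_len(nrow(a1)))
    dimnames(a1) <- dimnames(a2) <- list(loci, sprintf("i%03d", seq_len(ncol(a1))))
    GenotypeMatrix(a1, a2, site = site, island = island,
                   encoding = "unique_id")
}

# unordered allele-value pair for one individual-locus, or NA when missing
valuePair <- function(gm, ind, locus) {
    key <- alleleKey(gm)[[locus]]
    l1 <- SummarizedExperiment::assay(gm, "allele1")[locus, ind]
    l2 <- SummarizedExperiment::assay(gm, "allele2")[locus, ind]
    if (is.na(l1)) return(NA_character_)
    paste(sort(c(key$value[key$label == l1], key$value[key$label == l2])),
          collapse = "/")
}

# fraction of colony-locus pairs where the called genotype equals the truth;
# truth colonies map to colony tags in order of creation within each site
genotypeRecovery <- function(called, truthGm, config, scheme) {
    tot <- 0L; hit <- 0L
    for (s in config@sites) {
        for (ci in seq_len(config@popSizes[[s]])) {
            idT <- sprintf("%s:%s_C%02d", s, s, ci)
            idG <- paste0(s, ":", scheme@colonyTags[ci])
            for (ln in rownames(called)) {
                tot <- tot + 1L
                if (identical(valuePair(truthGm, idT, ln),
                              valuePair(called, idG, ln)))
                    hit <- hit + 1L
            }
        }
    }
    hit / tot
}

# run the read-level pipeline (demux -> trim -> collapse -> length+depth
# filters) on a simulated library; prevalence filtering left to the caller
pipelineToTally <- function(truth, config, scheme, minColonies = 2L) {
    sim <- simulateReadSet(truth, config, scheme)
    dmx <- demultiplexReads(sim$fastq, scheme, config@loci)
    tr <- trimReads(dmx$assignments, config@loci)
    lf <- applyLengthFilter(collapseReads(tr), loci = config@loci)
    dp <- applyDepthPrevalenceFilters(lf$tally, minColonies = minColonies)
    list(tally = dp$tally, trimmed = tr, demux = dmx, sim = sim)
}

# independent Weir-Cockerham oracle: nested random-effects ANOVA on allele
# indicator variables (mean squares -> variance components), a different
# algebraic route from the package's direct component formulas
wcAnovaOracle <- function(a1, a2, pop) {
    ok <- !is.na(a1)
    a1 <- a1[ok]; a2 <- a2[ok]; pop <- as.character(pop[ok])
    pops <- unique(pop)
    r <- length(pops)
    n_i <- as.vector(table(factor(pop, levels = pops)))
    ntot <- sum(n_i)
    nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
    A <- B <- C <- 0
    for (al in sort(unique(c(a1, a2)))) {
        y1 <- as.numeric(a1 == al); y2 <- as.numeric(a2 == al)
        ybarI <- (y1 + y2) / 2                       # individual means
        ybarP <- tapply(y1 + y2, pop, sum)[pops] / (2 * n_i)
        ybar <- sum(y1 + y2) / (2 * ntot)
        SSG <- sum((y1 - ybarI)^2 + (y2 - ybarI)^2)  # within individuals
        SSI <- 2 * sum((ybarI - ybarP[pop])^2)       # inds within pops
        SSP <- 2 * sum(n_i * (ybarP - ybar)^2)       # among pops
        MSG <- SSG / ntot
        MSI <- SSI / (ntot - r)
        MSP <- SSP / (r - 1)
        A <- A + (MSP - MSI) / (2 * nc)
        B <- B + (MSI - MSG) / 2
        C <- C + MSG
    }
    c(A = A, B = B, C = C, fst = A / (A + B + C), fis = B / (B + C))
}
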