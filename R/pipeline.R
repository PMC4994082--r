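.RUN_THRESHOLDS <- c(
    min_len = 15, max_len = 190, plus_repeats = 4, min_depth = 10,
    min_colonies = 2, locus_missing = 0.15, individual_missing = 0.35,
    rarefaction_colonies = 24, permutations = 20000, exact_steps = 100000,
    bottleneck_iter = 10000, pca_permutations = 10000)

#' Run configuration
#'
#' Bundles paths, the locus panel, the barcode scheme, every pipeline
#' threshold (each present with its standard default) and the master seed.
#' Validation fails naming any threshold that has been removed.
#'
#' @param loci list of [LocusSpec].
#' @param scheme a [BarcodeScheme].
#' @param islands named character site -> island.
#' @param fastq character vector of input FASTQ paths (optional when
#'   `simulate` is supplied).
#' @param outDir output directory for the results bundle.
#' @param thresholds named numeric; defaults: min_len 15, max_len 190,
#'   plus_repeats 4, min_depth 10, min_colonies 2, locus_missing 0.15,
#'   individual_missing 0.35, rarefaction_colonies 24, permutations 20000,
#'   exact_steps 100000, bottleneck_iter 10000, pca_permutations 10000.
#' @param strategy `"random"` or `"depth"` second-allele selection for the
#'   primary dataset.
#' @param encoding `"unique_id"` or `"length"` primary encoding.
#' @param replicates random-selection replicate datasets (default 10).
#' @param seed master seed.
#' @param simulate optional [SimConfig]: simulate the library first.
#' @export
RunConfig <- function(loci, scheme, islands, fastq = character(0),
                      outDir = "amplistr_run", thresholds = .RUN_THRESHOLDS,
                      strategy = c("random", "depth"),
                      encoding = c("unique_id", "length"),
                      replicates = 10L, seed = 1L, simulate = NULL) {
    strategy <- match.arg(strategy)
    encoding <- match.arg(encoding)
    missing <- setdiff(names(.RUN_THRESHOLDS), names(thresholds))
    if (length(missing))
        stop(sprintf("config validation error: missing threshold(s): %s",
                     paste(missing, collapse = ", ")))
    cfg <- list(loci = loci, scheme = scheme, islands = islands,
                fastq = fastq, outDir = outDir,
                thresholds = thresholds[names(.RUN_THRESHOLDS)],
                strategy = strategy, encoding = encoding,
                replicates = as.integer(replicates), seed = as.integer(seed),
                simulate = simulate)
    class(cfg) <- "amplistr_run_config"
    cfg
}

#' Read a run configuration from a YAML file
#'
#' Thresholds, strategy, encoding, replicates and seed are read from the
#' file; the locus panel and barcode scheme default to the package's
#' study-design panel unless locus/barcode tables are given inline.
#'
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    th <- .RUN_THRESHOLDS
    if (!is.null(y$thresholds)) {
        given <- unlist(y$thresholds)
        th <- c(given, th[setdiff(names(th), names(given))])
        if (!is.null(y$strict) && isTRUE(y$strict)) th <- given
    }
    loci <- if (is.null(y$loci)) defaultLocusPanel() else
        lapply(y$loci, function(l) do.call(LocusSpec, l))
    sites <- defaultSites()
    islands <- stats::setNames(sites$island, sites$site)
    if (!is.null(y$islands)) islands <- unlist(y$islands)
    RunConfig(loci = loci, scheme = defaultBarcodeScheme(names(islands)),
              islands = islands,
              fastq = if (is.null(y$fastq)) character(0) else unlist(y$fastq),
              outDir = if (is.null(y$out_dir)) "amplistr_run" else y$out_dir,
              thresholds = th,
              strategy = if (is.null(y$strategy)) "random" else y$strategy,
              encoding = if (is.null(y$encoding)) "unique_id" else y$encoding,
              replicates = if (is.null(y$replicates)) 10L else y$replicates,
              seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Run the full genotyping and analysis pipeline
#'
#' simulate (optional) -> demultiplex -> trim -> collapse -> length/depth/
#' prevalence filters -> allele calling (both strategies, with replicate
#' random datasets) -> encoding (both modes) -> missing-data filters ->
#' diversity + AMOVA + pairwise differentiation + allelic richness +
#' bottleneck + PCA, with per-stage counts and every artifact written under
#' `config$outDir`.
#'
#' @param config a [RunConfig()].
#' @param stats run the analysis stages (disable for genotyping only).
#' @return invisibly, a list with the tallies, genotype matrices and results.
#' @export
runPipeline <- function(config, stats = TRUE) {
    stopifnot(inherits(config, "amplistr_run_config"))
    th <- config$thresholds
    # validate inputs before touching the filesystem
    if (is.null(config$simulate)) {
        if (!length(config$fastq))
            stop("no input FASTQ files (and no simulate config)")
        miss <- config$fastq[!file.exists(config$fastq)]
        if (length(miss))
            stop(sprintf("missing inputs: %s", paste(miss, collapse = ", ")))
    }
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    log <- function(...) message(sprintf(...))

    fastq <- config$fastq
    if (!is.null(config$simulate)) {
        truth <- simulateTruth(config$simulate)
        sim <- simulateReadSet(truth, config$simulate, config$scheme,
                               outDir = file.path(config$outDir, "reads"))
        fastq <- sim$fastq
        log("simulated %d FASTQ files under %s", length(fastq), config$outDir)
    }
    if (!length(fastq)) stop("no input FASTQ files (and no simulate config)")
    miss <- fastq[!file.exists(fastq)]
    if (length(miss))
        stop(sprintf("missing inputs: %s", paste(miss, collapse = ", ")))

    dmx <- demultiplexReads(fastq, config$scheme, config$loci)
    report <- dmx$fileCounts
    report$file <- basename(report$file)
    utils::write.table(report, file.path(config$outDir, "demux_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log("demultiplexed: %d assigned / %d reads", sum(dmx$fileCounts$assigned),
        sum(dmx$fileCounts$total))

    trimmed <- trimReads(dmx$assignments, config$loci)
    tally <- collapseReads(trimmed)
    lf <- applyLengthFilter(tally, minLen = th["min_len"], maxLen = th["max_len"],
                            loci = config$loci,
                            rejectsFile = file.path(config$outDir, "length_rejects.tsv"))
    dp <- applyDepthPrevalenceFilters(lf$tally, minDepth = th["min_depth"],
                                      minColonies = 1L)  # prevalence applied per variant
    log("filters: %d sequences rejected by length, %d by pooled depth",
        nrow(lf$rejects), dp$removed[["depth"]])
    individuals <- unique(trimmed[, c("site", "colony")])

    cmp <- compareDatasets(dp$tally, config$loci, config$islands,
                           permutations = 0L,
                           seed = deriveSeed(config$seed, "compare"),
                           individuals = individuals)
    utils::write.csv(cmp$table, file.path(config$outDir, "dataset_comparison.csv"),
                     row.names = FALSE)

    # primary dataset at the standard prevalence filter
    primTally <- applyDepthPrevalenceFilters(dp$tally, minDepth = 1L,
                                             minColonies = th[["min_colonies"]])$tally
    utils::write.table(tallyTable(primTally), file.path(config$outDir, "tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reps <- generateReplicateDatasets(primTally, config$loci, config$islands,
                                      config$encoding, k = config$replicates,
                                      seed = deriveSeed(config$seed, "replicates"),
                                      individuals = individuals)
    primary <- if (config$strategy == "random") reps[[1]] else
        encodeAlleles(callGenotypes(primTally, "depth",
                                    seed = deriveSeed(config$seed, "calldepth"),
                                    individuals = individuals),
                      config$loci, config$islands, config$encoding)
    primary <- applyMissingFilters(primary, th[["locus_missing"]],
                                   th[["individual_missing"]])
    writeGenotypeTable(primary, file.path(config$outDir, "genotypes_primary.tsv"))
    writeGenepop(primary, file.path(config$outDir, "genotypes_primary.genepop"))
    for (nm in names(reps))
        writeGenotypeTable(reps[[nm]],
                           file.path(config$outDir, sprintf("genotypes_%s.tsv", nm)))

    results <- list(comparison = cmp$table)
    if (stats) {
        perm <- th[["permutations"]]
        div <- summarizeDiversity(primary, "site", permutations = perm,
                                  seed = deriveSeed(config$seed, "div"))
        pwSite <- pairwiseDifferentiation(primary, "site", permutations = perm,
                                          seed = deriveSeed(config$seed, "pwsite"))
        pwIsl <- pairwiseDifferentiation(primary, "island", permutations = perm,
                                         seed = deriveSeed(config$seed, "pwisl"))
        ex <- exactTest(primary, "site",
                        steps = th[["exact_steps"]],
                        seed = deriveSeed(config$seed, "exact"))
        ar <- allelicRichness(primary, th[["rarefaction_colonies"]])
        bn <- lapply(unique(islandLabels(primary)), function(isl)
            bottleneckTest(primary, isl, "island",
                           nIter = th[["bottleneck_iter"]],
                           seed = deriveSeed(config$seed, paste0("bn", isl))))
        names(bn) <- unique(islandLabels(primary))
        pcaInd <- pcaIndividuals(primary,
                                 permutations = th[["pca_permutations"]],
                                 seed = deriveSeed(config$seed, "pcaind"))
        pcaPop <- pcaPopulations(primary, "site",
                                 permutations = th[["pca_permutations"]],
                                 seed = deriveSeed(config$seed, "pcapop"))
        utils::write.csv(perLocusTable(div),
                         file.path(config$outDir, "diversity_per_locus.csv"),
                         row.names = FALSE)
        utils::write.csv(pairwiseValues(pwSite),
                         file.path(config$outDir, "pairwise_sites.csv"))
        utils::write.csv(pairwiseValues(pwIsl),
                         file.path(config$outDir, "pairwise_islands.csv"))
        utils::write.csv(as.data.frame(ar),
                         file.path(config$outDir, "allelic_richness.csv"))
        utils::write.csv(pcaScores(pcaInd),
                         file.path(config$outDir, "pca_individuals.csv"))
        utils::write.csv(pcaScores(pcaPop),
                         file.path(config$outDir, "pca_populations.csv"))
        results <- c(results, list(
            diversity = div, pairwiseSites = pwSite, pairwiseIslands = pwIsl,
            exact = ex, richness = ar, bottleneck = bn,
            pcaIndividuals = pcaInd, pcaPopulations = pcaPop))
        bundle <- list(
            config = list(thresholds = as.list(th), strategy = config$strategy,
                          encoding = config$encoding, seed = config$seed,
                          replicates = config$replicates),
            overall = as.list(overallIndices(div)),
            p_values = as.list(div@pValues),
            pca = list(individual_axis_pct = 100 * varianceFractions(pcaInd)[1:2],
                       population_axis_pct = 100 * varianceFractions(pcaPop)[1:2]),
            bottleneck = lapply(bn, function(b)
                list(wilcoxon = as.list(wilcoxonP(b)),
                     mode_shift = modeShiftVerdict(b))))
        jsonlite::write_json(bundle, file.path(config$outDir, "results.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    results$primary <- primary
    results$replicates <- reps
    results$tally <- primTally
    invisible(results)
}
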