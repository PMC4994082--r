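.datatable.aware <- TRUE

utils::globalVariables(c(
    "depth", "site", "colony", "locus", "sequence", "total_depth",
    "n_colonies", "insert", "quality", "allele1", "allele2", "N"
))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so simulation helpers are deterministic
#' without disturbing the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else rm(".Random.seed", envir = globalenv())
    })
    expr
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives the whole pipeline; each stage gets its own child
#' seed so stages can be re-run independently with identical results. Kept
#' strictly below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @export
deriveSeed <- function(master, stage) {
    h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
    as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

# vectorized count of mismatches between fixed-length substrings of `x`
# starting at `start` and a single pattern
.substrMismatch <- function(x, pattern, start = 1L) {
    np <- nchar(pattern)
    mm <- integer(length(x))
    short <- nchar(x) < start + np - 1L
    for (i in seq_len(np)) {
        mm <- mm + (substr(x, start + i - 1L, start + i - 1L) !=
                    substr(pattern, i, i))
    }
    mm[short] <- np
    mm
}

# TRUE when the string contains no 2-copy tandem of any 2-6 bp period
.tandemFree <- function(s) {
    n <- nchar(s)
    for (m in 2:6) {
        if (n < 2L * m) next
        for (i in seq_len(n - 2L * m + 1L))
            if (substr(s, i, i + m - 1L) == substr(s, i + m, i + 2L * m - 1L))
                return(FALSE)
    }
    TRUE
}

# deterministic random DNA with no tandem copy of `avoid` motifs anywhere,
# and no single copy at either end (a terminal copy would extend an adjacent
# repeat run by a full period, blurring the repeat/flank boundary); with
# tandemFree = TRUE the string contains no 2-copy tandem of any short period
# at all, so it can never host a competing repeat run
.randomDna <- function(n, len, avoid = character(0), tandemFree = FALSE) {
    out <- character(n)
    for (i in seq_len(n)) {
        repeat {
            s <- paste(sample(.DNA_BASES, len, replace = TRUE), collapse = "")
            bad <- FALSE
            for (m in avoid) {
                if (grepl(strrep(m, 2L), s, fixed = TRUE) ||
                    startsWith(s, m) || endsWith(s, m)) { bad <- TRUE; break }
            }
            if (!bad && tandemFree && !.tandemFree(s)) bad <- TRUE
            if (!bad) { out[i] <- s; break }
        }
    }
    out
}

# per-base substitution noise over a character vector of reads
.mutateBases <- function(seqs, rate) {
    if (rate <= 0 || !length(seqs)) return(seqs)
    nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
    idx <- which(nerr > 0L)
    for (i in idx) {
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(length(s), nerr[i])
        for (p in pos) s[p] <- sample(setdiff(.DNA_BASES, s[p]), 1L)
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}
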