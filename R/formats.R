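#' Write a GenotypeMatrix in genepop format
#'
#' Title line, one locus name per line, then one "Pop" block per population
#' with individuals as `name ,  aaabbb aaabbb ...` using 3-digit allele codes
#' (from the allele key's `code` column when present, otherwise the label
#' itself); `000000` marks a missing call.
#'
#' @param gm a [GenotypeMatrix].
#' @param path output file.
#' @param title genepop title line.
#' @export
writeGenepop <- function(gm, path, title = "ampliSTR genotypes") {
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    key <- alleleKey(gm)
    codeOf <- function(ln, lab) {
        if (!is.null(key[[ln]]) && nrow(key[[ln]]))
            key[[ln]]$code[match(lab, key[[ln]]$label)]
        else lab
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(title, con)
    writeLines(rownames(gm), con)
    pops <- unique(siteLabels(gm))
    for (p in pops) {
        writeLines("Pop", con)
        for (i in which(siteLabels(gm) == p)) {
            codes <- vapply(rownames(gm), function(ln) {
                l1 <- a1[ln, i]; l2 <- a2[ln, i]
                if (is.na(l1)) return("000000")
                c1 <- codeOf(ln, l1); c2 <- codeOf(ln, l2)
                if (is.na(c1) || is.na(c2) || c1 > 999L || c2 > 999L)
                    stop(sprintf("allele code overflow (>999) at locus %s", ln))
                sprintf("%03d%03d", c1, c2)
            }, character(1))
            writeLines(paste0(colnames(gm)[i], " ,  ",
                              paste(codes, collapse = " ")), con)
        }
    }
    invisible(path)
}

#' Read a genepop file into a GenotypeMatrix
#'
#' Supports the 6-digit diploid coding written by [writeGenepop()] (3 digits
#' per allele, `000` = missing). Island labels are not part of the format and
#' default to the population name.
#'
#' @param path genepop file.
#' @param encoding encoding tag to record on the result.
#' @export
readGenepop <- function(path, encoding = "unique_id") {
    lines <- readLines(path)
    if (length(lines) < 3L) stop(sprintf("malformed genepop %s: too short", path))
    isPop <- toupper(trimws(lines)) == "POP"
    firstPop <- which(isPop)[1]
    if (is.na(firstPop) || firstPop < 3L)
        stop(sprintf("malformed genepop %s: no Pop line after locus list", path))
    lociNames <- trimws(lines[2:(firstPop - 1L)])
    lociNames <- unlist(strsplit(lociNames, ",[ ]*"))
    nl <- length(lociNames)
    ind <- character(); popLab <- character()
    allele1 <- list(); allele2 <- list()
    popCount <- 0L
    for (i in firstPop:length(lines)) {
        ln <- lines[i]
        if (!nzchar(trimws(ln))) next
        if (toupper(trimws(ln)) == "POP") { popCount <- popCount + 1L; next }
        parts <- strsplit(ln, ",")[[1]]
        if (length(parts) < 2L)
            stop(sprintf("genepop parse error at line %d of %s", i, path))
        nm <- trimws(parts[1])
        codes <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
        if (length(codes) != nl)
            stop(sprintf("genepop parse error at line %d of %s: %d codes for %d loci",
                         i, path, length(codes), nl))
        c1 <- as.integer(substr(codes, 1L, 3L))
        c2 <- as.integer(substr(codes, 4L, 6L))
        c1[c1 == 0L] <- NA_integer_; c2[c2 == 0L] <- NA_integer_
        miss <- is.na(c1) | is.na(c2)
        c1[miss] <- NA_integer_; c2[miss] <- NA_integer_
        ind <- c(ind, nm)
        popLab <- c(popLab, sprintf("pop%02d", popCount))
        allele1[[length(allele1) + 1L]] <- c1
        allele2[[length(allele2) + 1L]] <- c2
    }
    a1 <- do.call(cbind, allele1); a2 <- do.call(cbind, allele2)
    rownames(a1) <- rownames(a2) <- lociNames
    colnames(a1) <- colnames(a2) <- make.unique(ind)
    GenotypeMatrix(a1, a2, site = popLab, island = popLab,
                   encoding = encoding)
}

#' Write/read the native tab-separated genotype table
#'
#' Long format: individual, site, island, locus, allele1, allele2 (integer
#' labels; `NA` for missing), plus the encoding as a header comment.
#'
#' @param gm a [GenotypeMatrix].
#' @param path file path.
#' @export
writeGenotypeTable <- function(gm, path) {
    a1 <- assay(gm, "allele1"); a2 <- assay(gm, "allele2")
    rows <- expand.grid(locus = rownames(gm), ind = seq_len(ncol(gm)),
                        stringsAsFactors = FALSE)
    df <- data.frame(
        individual = colnames(gm)[rows$ind],
        site = siteLabels(gm)[rows$ind],
        island = islandLabels(gm)[rows$ind],
        locus = rows$locus,
        allele1 = a1[cbind(match(rows$locus, rownames(a1)), rows$ind)],
        allele2 = a2[cbind(match(rows$locus, rownames(a1)), rows$ind)],
        stringsAsFactors = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# encoding=%s", encodingType(gm)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeGenotypeTable
#' @export
readGenotypeTable <- function(path) {
    first <- readLines(path, n = 1L)
    encoding <- if (grepl("^# encoding=", first))
        sub("^# encoding=", "", first) else "unique_id"
    df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    loci <- unique(df$locus)
    inds <- unique(df$individual)
    a1 <- matrix(NA_integer_, length(loci), length(inds),
                 dimnames = list(loci, inds))
    a2 <- a1
    a1[cbind(match(df$locus, loci), match(df$individual, inds))] <- df$allele1
    a2[cbind(match(df$locus, loci), match(df$individual, inds))] <- df$allele2
    meta <- df[!duplicated(df$individual), c("individual", "site", "island")]
    meta <- meta[match(inds, meta$individual), ]
    GenotypeMatrix(a1, a2, site = meta$site, island = meta$island,
                   encoding = encoding)
}
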