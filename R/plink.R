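## PLINK map/ped readers and writers, the allele-coded map extension, the
## compact "0125" export and selection-list files. All files are plain
## whitespace-delimited text; chromosome labels are never coerced to numbers.

#' Read a SNP map file
#'
#' Accepts four dialects, detected from the (uniform) column count per line:
#' 3 columns (chromosome, SNP name, bp position), 4-column standard PLINK
#' (chromosome, name, cM, bp), and either of those with a trailing allele
#' coding — a single two-letter token such as \code{AB} or two single-letter
#' tokens such as \code{A B}. A 4-column file whose last column is a
#' two-letter allele token is read as 3 columns + coding. The cM column is
#' ignored.
#'
#' @param path map file path.
#' @return data.frame with columns \code{chromosome}, \code{snp_name},
#'   \code{position_bp}, \code{allele1}, \code{allele2} (NA when the map
#'   carries no coding) and \code{vector_index} (1-based file order).
#' @export
readMap <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty map file", call. = FALSE)
    toks <- strsplit(trimws(lines), "[ \t]+")
    nc <- lengths(toks)
    if (length(unique(nc)) != 1L)
        stop(sprintf("inconsistent column count in map: line %d has %d columns, line 1 has %d",
                     which(nc != nc[1])[1], nc[nc != nc[1]][1], nc[1]),
             call. = FALSE)
    nc <- nc[1]
    if (!(nc %in% 3:6))
        stop(sprintf("map files must have 3-6 columns, found %d", nc),
             call. = FALSE)
    m <- matrix(unlist(toks), ncol = nc, byrow = TRUE)
    isPairTok <- function(x) all(grepl("^[A-Za-z]{2}$", x))
    isOneTok <- function(x) all(grepl("^[A-Za-z]$", x))
    chrom <- m[, 1]; name <- m[, 2]
    a1 <- a2 <- rep.int(NA_character_, nrow(m))
    if (nc == 3L) {
        bp <- m[, 3]
    } else if (nc == 4L) {
        if (isPairTok(m[, 4])) {          # 3 columns + "AB"
            bp <- m[, 3]; a1 <- substr(m[, 4], 1, 1); a2 <- substr(m[, 4], 2, 2)
        } else bp <- m[, 4]               # standard PLINK, col 3 is cM
    } else if (nc == 5L) {
        if (isOneTok(m[, 4]) && isOneTok(m[, 5])) {   # 3 columns + "A B"
            bp <- m[, 3]; a1 <- m[, 4]; a2 <- m[, 5]
        } else if (isPairTok(m[, 5])) {               # PLINK + "AB"
            bp <- m[, 4]; a1 <- substr(m[, 5], 1, 1); a2 <- substr(m[, 5], 2, 2)
        } else stop("cannot interpret 5-column map: last column is neither an allele pair nor two allele tokens",
                    call. = FALSE)
    } else {                                          # PLINK + "A B"
        if (!(isOneTok(m[, 5]) && isOneTok(m[, 6])))
            stop("6-column map must end with two single-letter allele columns",
                 call. = FALSE)
        bp <- m[, 4]; a1 <- m[, 5]; a2 <- m[, 6]
    }
    bpn <- suppressWarnings(as.numeric(bp))
    if (anyNA(bpn) || any(bpn != floor(bpn)))
        stop(sprintf("non-integer bp position at map line %d",
                     which(is.na(bpn) | bpn != floor(bpn))[1]), call. = FALSE)
    if (anyDuplicated(name))
        stop(sprintf("duplicate SNP name in map: %s",
                     name[duplicated(name)][1]), call. = FALSE)
    if (any(!is.na(a1) & a1 == a2))
        stop(sprintf("degenerate allele coding at SNP %s: alleles must differ",
                     name[!is.na(a1) & a1 == a2][1]), call. = FALSE)
    data.frame(chromosome = chrom, snp_name = name, position_bp = bpn,
               allele1 = a1, allele2 = a2,
               vector_index = seq_along(name), stringsAsFactors = FALSE)
}

## Internal: stream a ped file in chunks of rows. `fun(ped, a1, a2, lineno)`
## receives the 6 leading columns (data.frame), allele matrices (rows x
## nSnps) and the 1-based line numbers. Memory is bounded by the chunk size.
.streamPed <- function(path, nSnps, fun, chunkSize = 200L) {
    con <- file(path, "r")
    on.exit(close(con))
    expected <- 6L + 2L * nSnps
    lineno <- 0L
    total <- 0L
    repeat {
        lines <- readLines(con, n = chunkSize)
        if (!length(lines)) break
        keep <- nzchar(trimws(lines))
        lnum <- lineno + seq_along(lines)
        lineno <- lineno + length(lines)
        lines <- lines[keep]
        lnum <- lnum[keep]
        if (!length(lines)) next
        toks <- strsplit(trimws(lines), "[ \t]+")
        nf <- lengths(toks)
        if (any(nf != expected))
            stop(sprintf("ped line %d: expected %d fields (6 + 2 x %d), got %d",
                         lnum[nf != expected][1], expected, nSnps,
                         nf[nf != expected][1]), call. = FALSE)
        m <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
        ped <- data.frame(family_id = m[, 1], individual_id = m[, 2],
                          paternal_id = m[, 3], maternal_id = m[, 4],
                          sex = m[, 5], phenotype = m[, 6],
                          stringsAsFactors = FALSE)
        a1 <- m[, 6L + 2L * seq_len(nSnps) - 1L, drop = FALSE]
        a2 <- m[, 6L + 2L * seq_len(nSnps), drop = FALSE]
        fun(ped, a1, a2, lnum)
        total <- total + nrow(ped)
    }
    invisible(total)
}

#' Read a PLINK ped file
#'
#' Validates that every row carries exactly \code{6 + 2 * nSnps}
#' whitespace-separated fields and returns the parsed rows. Internally the
#' file is processed in fixed-size chunks, so arbitrarily many samples can
#' be streamed (see [importData()], which never materializes the whole
#' file). Missing genotypes (\code{"0 0"}) are passed through.
#'
#' @param path ped file path.
#' @param nSnps expected SNP count (the panel size).
#' @return list with \code{ped} (data.frame of the 6 leading columns) and
#'   \code{a1}, \code{a2} (character matrices, samples x SNPs, the two
#'   observed alleles).
#' @export
readPed <- function(path, nSnps) {
    peds <- list(); a1s <- list(); a2s <- list()
    i <- 0L
    .streamPed(path, nSnps, function(ped, a1, a2, lnum) {
        i <<- i + 1L
        peds[[i]] <<- ped; a1s[[i]] <<- a1; a2s[[i]] <<- a2
    })
    list(ped = do.call(rbind, peds),
         a1 = do.call(rbind, a1s), a2 = do.call(rbind, a2s))
}

.mapLines <- function(snps) {
    # exported maps are always 4-column PLINK, cM = 0, tab-separated
    paste(snps$chromosome, snps$snp_name, 0L,
          format(snps$position_bp, scientific = FALSE, trim = TRUE),
          sep = "\t")
}

.pedGenotypeLookup <- function(snps, missing = "0") {
    # 4 x nSnps matrix of ready-made "a b" pair strings, indexed by code + 1
    rbind(paste(snps$allele1, snps$allele1),
          paste(snps$allele1, snps$allele2),
          paste(missing, missing),
          paste(snps$allele2, snps$allele2))
}

.pedLines <- function(ped, codes, lookup) {
    # codes: integer matrix samples x nSnps; lookup from .pedGenotypeLookup
    n <- nrow(codes)
    vapply(seq_len(n), function(i) {
        g <- lookup[cbind(codes[i, ] + 1L, seq_len(ncol(codes)))]
        paste(c(ped$family_id[i], ped$individual_id[i], ped$paternal_id[i],
                ped$maternal_id[i], ped$sex[i], ped$phenotype[i], g),
              collapse = " ")
    }, character(1))
}

.DIGITS_0125 <- c("0", "1", "5", "2")  # by code + 1: hom1, het, missing, hom2

.lines0125 <- function(sampleIds, codes) {
    n <- nrow(codes)
    vapply(seq_len(n), function(i)
        paste0(sampleIds[i], "\t",
               paste(.DIGITS_0125[codes[i, ] + 1L], collapse = "")),
        character(1))
}

#' Write genotypes as PLINK ped/map files
#'
#' Writes \code{<prefix>.ped} (single-space separated; 6 leading columns
#' then allele pairs decoded through each SNP's coding, heterozygotes in
#' canonical (allele1, allele2) order) and \code{<prefix>.map} (tab-separated
#' 4-column PLINK with cM = 0). Output is byte-stable for fixed input.
#'
#' @param ped data.frame of the 6 leading ped columns (\code{family_id},
#'   \code{individual_id}, \code{paternal_id}, \code{maternal_id},
#'   \code{sex}, \code{phenotype}).
#' @param codes integer matrix (samples x SNPs) of genotype codes for the
#'   emitted SNPs.
#' @param snps data.frame of the emitted SNPs in vector-index order, with
#'   allele codings (see [readMap()]).
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
writePedMap <- function(ped, codes, snps, prefix) {
    stopifnot(nrow(codes) == nrow(ped), ncol(codes) == nrow(snps))
    if (nrow(ped) == 0L)
        stop("refusing to export an empty sample selection", call. = FALSE)
    pedPath <- paste0(prefix, ".ped"); mapPath <- paste0(prefix, ".map")
    writeLines(.pedLines(ped, codes, .pedGenotypeLookup(snps)), pedPath)
    writeLines(.mapLines(snps), mapPath)
    invisible(c(pedPath, mapPath))
}

#' Write genotypes in the "0125" format
#'
#' One line per sample: the sample ID, a tab, then one character per emitted
#' SNP — \code{0} homozygous for allele 1, \code{1} heterozygous, \code{2}
#' homozygous for allele 2, \code{5} missing. A companion
#' \code{<prefix>.map} is written as in [writePedMap()]. Available
#' regardless of the format originally imported.
#'
#' @param sampleIds character vector of sample IDs.
#' @inheritParams writePedMap
#' @return character vector of the files written, invisibly.
#' @export
write0125 <- function(sampleIds, codes, snps, prefix) {
    stopifnot(nrow(codes) == length(sampleIds), ncol(codes) == nrow(snps))
    if (!length(sampleIds))
        stop("refusing to export an empty sample selection", call. = FALSE)
    gPath <- paste0(prefix, ".0125"); mapPath <- paste0(prefix, ".map")
    writeLines(.lines0125(sampleIds, codes), gPath)
    writeLines(.mapLines(snps), mapPath)
    invisible(c(gPath, mapPath))
}

#' Read sample and SNP selection-list files
#'
#' A sample list holds one sample ID per line; every listed sample is kept.
#' A SNP list comes in two dialects: one SNP name per line (named SNPs are
#' kept) or two columns, name plus a \code{0}/\code{1} flag (\code{0} marks
#' SNPs excluded from the subset). Whether the listed identifiers exist is
#' checked when the lists are applied by [subsetByLists()].
#'
#' @param sampleListPath,snpListPath file paths; at least one must be given.
#' @return list with \code{samples} (character vector or NULL) and
#'   \code{snpFlags} (named logical vector of keep flags, or NULL).
#' @export
readSelectionLists <- function(sampleListPath = NULL, snpListPath = NULL) {
    if (is.null(sampleListPath) && is.null(snpListPath))
        stop("at least one of sampleListPath, snpListPath is required",
             call. = FALSE)
    samples <- NULL
    snpFlags <- NULL
    if (!is.null(sampleListPath)) {
        samples <- trimws(readLines(sampleListPath))
        samples <- samples[nzchar(samples)]
        if (!length(samples))
            stop(sprintf("empty sample selection list: %s", sampleListPath),
                 call. = FALSE)
        if (anyDuplicated(samples))
            stop(sprintf("duplicate sample ID in selection list: %s",
                         samples[duplicated(samples)][1]), call. = FALSE)
    }
    if (!is.null(snpListPath)) {
        lines <- trimws(readLines(snpListPath))
        lines <- lines[nzchar(lines)]
        if (!length(lines))
            stop(sprintf("empty SNP selection list: %s", snpListPath),
                 call. = FALSE)
        toks <- strsplit(lines, "[ \t]+")
        nc <- lengths(toks)
        dialect <- "names"
        if (all(nc == 1L)) {
            nm <- vapply(toks, `[`, "", 1L)
            snpFlags <- rep.int(TRUE, length(nm))
        } else if (all(nc == 2L)) {
            dialect <- "flags"
            nm <- vapply(toks, `[`, "", 1L)
            fl <- vapply(toks, `[`, "", 2L)
            if (!all(fl %in% c("0", "1")))
                stop(sprintf("malformed SNP selection flag '%s' (must be 0 or 1)",
                             fl[!fl %in% c("0", "1")][1]), call. = FALSE)
            snpFlags <- fl == "1"
        } else
            stop("SNP selection list must have one or two columns throughout",
                 call. = FALSE)
        if (anyDuplicated(nm))
            stop(sprintf("duplicate SNP name in selection list: %s",
                         nm[duplicated(nm)][1]), call. = FALSE)
        names(snpFlags) <- nm
        attr(snpFlags, "dialect") <- dialect
    }
    list(samples = samples, snpFlags = snpFlags)
}
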