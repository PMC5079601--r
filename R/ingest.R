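## Import orchestration: map-first panel loading, streamed ped ingestion with
## 2-bit encoding, and creation of the initial full genotype set (gs_NNN
## backed by an all-samples is_NNN and an all-ones ss_NNN).

#' Import a SNP map as a new panel
#'
#' Genotype data can only be entered relative to a previously loaded map, so
#' every workflow starts here. No genotype data are touched.
#'
#' @param store a [GenotypeStore-class].
#' @param mapPath map file (see [readMap()] for accepted dialects).
#' @param panelName unique name for the new panel.
#' @return the panel row (name, size), invisibly.
#' @export
importPanel <- function(store, mapPath, panelName) {
    addPanel(store, panelName, readMap(mapPath))
}

## Infer per-SNP allele codings from observed ped alleles: first-observed
## order; when both alleles first appear in the same (heterozygous) genotype
## the tie is broken lexicographically. Monomorphic SNPs get the placeholder
## "0" as allele2.
.inferCodings <- function(pedPath, nSnps, missing = "0", chunkSize = 200L) {
    A1 <- rep.int(NA_character_, nSnps)
    A2 <- rep.int(NA_character_, nSnps)
    tie <- rep.int(FALSE, nSnps)
    .streamPed(pedPath, nSnps, function(ped, a1, a2, lnum) {
        todo <- which(is.na(A2))
        for (j in todo) {
            v <- as.vector(rbind(a1[, j], a2[, j]))   # row order, both tokens
            v <- v[v != missing]
            if (!length(v)) next
            u <- unique(v)
            if (is.na(A1[j])) {
                A1[j] <<- u[1]
                if (length(u) >= 2L) {
                    A2[j] <<- u[2]
                    # same-genotype discovery: positions of first occurrences
                    tie[j] <<- ceiling(match(u[1], v) / 2) ==
                               ceiling(match(u[2], v) / 2)
                }
            } else {
                u <- setdiff(u, A1[j])
                if (length(u)) A2[j] <<- u[1]
            }
        }
    }, chunkSize = chunkSize)
    swap <- !is.na(A2) & tie & A2 < A1
    tmp <- A1[swap]; A1[swap] <- A2[swap]; A2[swap] <- tmp
    mono <- !is.na(A1) & is.na(A2)
    A2[mono] <- missing                      # monomorphic placeholder
    list(allele1 = A1, allele2 = A2, monomorphic = mono)
}

#' Import a ped/map pair as genotype records plus the full genotype set
#'
#' Streams the ped file, encodes each row against the panel's allele coding
#' (inferring and persisting the coding from the data when the map carries
#' none) and stores one packed genotype record per row. On success an
#' individual selection with all imported records in file order, a SNP
#' selection with every position active and a genotype set referencing both
#' are created — the import's exportable unit. The import is atomic: any
#' parse or encoding error aborts before the store is touched.
#'
#' The map file must be supplied with every import and is checked for
#' identity (SNP name, chromosome, bp position, in order) against the stored
#' panel, ensuring unambiguous SNP mapping; cM differences are ignored.
#'
#' @param store a [GenotypeStore-class].
#' @param pedPath,mapPath PLINK ped and map files.
#' @param panelName name of a previously imported panel.
#' @param comment optional comment stored with the new genotype set.
#' @return name of the new genotype set (e.g. \code{"gs_001"}).
#' @export
importData <- function(store, pedPath, mapPath, panelName,
                       comment = NA_character_) {
    e <- store@env
    panel <- .panelRow(store, panelName)
    snps <- .panelSnps(store, panelName)
    map <- readMap(mapPath)
    if (nrow(map) != panel$size ||
        !identical(map$snp_name, snps$snp_name) ||
        !identical(map$chromosome, snps$chromosome) ||
        !identical(map$position_bp, snps$position_bp))
        stop(sprintf("map %s does not match stored panel %s (SNP name/chromosome/position identity required)",
                     mapPath, panelName), call. = FALSE)

    if (all(snps$coding_set)) {
        A1 <- snps$allele1; A2 <- snps$allele2
        inferred <- NULL
    } else {
        inferred <- .inferCodings(pedPath, panel$size)
        A1 <- inferred$allele1; A2 <- inferred$allele2
        never <- is.na(A1)   # SNPs never observed (all missing)
        A1[never] <- "0"
        A2[never] <- "0"
    }

    payChunks <- list()
    pedChunks <- list()
    k <- 0L
    nm <- snps$snp_name
    .streamPed(pedPath, panel$size, function(ped, a1, a2, lnum) {
        nr <- nrow(a1)
        codes <- tryCatch(
            encodeGenotype(as.vector(t(a1)), as.vector(t(a2)),
                           rep.int(A1, nr), rep.int(A2, nr),
                           snpNames = rep.int(nm, nr)),
            error = function(err)
                stop(sprintf("ped lines %d-%d: %s", lnum[1], lnum[nr],
                             conditionMessage(err)), call. = FALSE))
        codes <- matrix(codes, nrow = nr, byrow = TRUE)
        pays <- vector("list", nr)
        for (i in seq_len(nr)) pays[[i]] <- cpp_pack(codes[i, ])
        payChunks[[length(payChunks) + 1L]] <<- pays
        pedChunks[[length(pedChunks) + 1L]] <<- ped
        k <<- k + nr
    })
    if (k == 0L)
        stop(sprintf("ped file has no data rows: %s", pedPath), call. = FALSE)
    payloads <- do.call(c, payChunks)
    ped <- do.call(rbind, pedChunks)

    # ---- commit (nothing above mutated the store) ----
    if (!is.null(inferred)) {
        idx <- which(e$snps$panel == panelName)
        idx <- idx[order(e$snps$vector_index[idx])]
        e$snps$allele1[idx] <- A1
        e$snps$allele2[idx] <- A2
        e$snps$coding_set[idx] <- TRUE
    }
    keys <- .addRecordsPacked(store, ped$individual_id, panelName, payloads,
                              ped = ped[, c("family_id", "paternal_id",
                                            "maternal_id", "sex",
                                            "phenotype")])
    src <- sprintf("import %s", basename(pedPath))
    isName <- .newIndividualSelection(store, panelName, keys, src)
    ssName <- .newSnpSelection(store, panelName,
                               .packSelBits(rep.int(TRUE, panel$size)), src)
    gsName <- .newGenotypeSet(store, panelName, ssName, isName, comment)
    .autosave(store)
    gsName
}

#' Bulk-import pre-packed genotype records
#'
#' Programmatic counterpart of [importData()] for genotypes that already
#' exist as packed 2-bit payloads (e.g. produced by the synthetic-data
#' generator at panel sizes where a ped text file would be impractically
#' large). Creates the same structures as a ped import: one record per
#' payload, an all-records individual selection, an all-ones SNP selection
#' and the genotype set tying them together. Small-scale equivalence with
#' the text path is part of the test suite.
#'
#' @param store a [GenotypeStore-class].
#' @param panelName name of a previously imported panel.
#' @param sampleIds character vector of external sample IDs (repeats create
#'   duplicate records for the same individual).
#' @param payloads list of raw vectors, each \code{ceiling(size/4)} bytes,
#'   or a list of [PackedGenotypes].
#' @param comment optional comment stored with the new genotype set.
#' @param source source label recorded on the created selections.
#' @return name of the new genotype set.
#' @export
importPacked <- function(store, panelName, sampleIds, payloads,
                         comment = NA_character_, source = "bulk import") {
    size <- .panelRow(store, panelName)$size
    n <- length(sampleIds)
    if (length(payloads) != n)
        stop("sampleIds and payloads must have equal length", call. = FALSE)
    if (n == 0L) stop("nothing to import", call. = FALSE)
    nb <- ceiling(size / 4)
    payloads <- lapply(payloads, function(p) {
        if (is(p, "PackedGenotypes")) {
            if (nSnps(p) != size)
                stop(sprintf("record has %d genotypes but panel %s has %d SNPs",
                             nSnps(p), panelName, size), call. = FALSE)
            payload(p)
        } else {
            if (length(p) != nb)
                stop(sprintf("payload has %d bytes but panel %s needs %d",
                             length(p), panelName, nb), call. = FALSE)
            p
        }
    })
    keys <- .addRecordsPacked(store, sampleIds, panelName, payloads)
    isName <- .newIndividualSelection(store, panelName, keys, source)
    ssName <- .newSnpSelection(store, panelName,
                               .packSelBits(rep.int(TRUE, size)), source)
    gsName <- .newGenotypeSet(store, panelName, ssName, isName, comment)
    .autosave(store)
    gsName
}
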