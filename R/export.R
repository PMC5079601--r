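## Export of named genotype sets. One database fetch per sample: each packed
## record is retrieved once and its SNP-selection positions are decoded in
## bulk over the payload bytes (mask/shift), independent of panel size.

#' Export a genotype set to PLINK ped/map or "0125" files
#'
#' Materializes a named genotype set: for each record key in
#' individual-selection order the packed vector is fetched once, the active
#' positions of the SNP selection are unpacked in bulk, decoded through the
#' panel's allele coding and written out. \code{format = "plink"} writes
#' \code{<prefix>.ped} and \code{<prefix>.map}; \code{format = "0125"}
#' writes \code{<prefix>.0125} and \code{<prefix>.map} (see
#' [writePedMap()], [write0125()]). If any included sample has phenotypes in
#' the store they are written alongside as
#' \code{<prefix>_phenotypes.csv}. Exports are read-only and byte-stable:
#' repeating an export reproduces identical files.
#'
#' @param store a [GenotypeStore-class].
#' @param setName genotype set name.
#' @param format \code{"plink"} or \code{"0125"}.
#' @param outPrefix output path prefix.
#' @param chunkSize samples decoded per write batch.
#' @return invisibly, a list with \code{files} (paths written),
#'   \code{n_samples} and \code{n_snps}.
#' @export
exportSet <- function(store, setName, format = c("plink", "0125"), outPrefix,
                      chunkSize = 200L) {
    format <- match.arg(format)
    set <- .getSet(store, setName)
    if (!length(set$keys))
        stop(sprintf("genotype set %s has an empty individual selection (samples deleted?); refusing to export",
                     setName), call. = FALSE)
    act <- which(.unpackSelBits(set$bits, set$size))
    if (!length(act))
        stop(sprintf("genotype set %s has an empty SNP selection; refusing to export",
                     setName), call. = FALSE)
    e <- store@env
    snps <- .panelSnps(store, set$panel)[act, , drop = FALSE]
    if (any(!snps$coding_set))
        stop(sprintf("panel %s has SNPs without allele coding; import genotype data first",
                     set$panel), call. = FALSE)
    rec <- e$genotype_records[match(set$keys, e$genotype_records$record_key),
                              , drop = FALSE]
    sids <- .keysSampleIds(store, set$keys)

    mainPath <- paste0(outPrefix, if (format == "plink") ".ped" else ".0125")
    mapPath <- paste0(outPrefix, ".map")
    writeLines(.mapLines(snps), mapPath)
    lookup <- .pedGenotypeLookup(snps)
    act0 <- act - 1L
    con <- file(mainPath, "w")
    on.exit(close(con))
    n <- length(set$keys)
    for (start in seq(1L, n, by = chunkSize)) {
        idx <- start:min(start + chunkSize - 1L, n)
        codes <- matrix(0L, nrow = length(idx), ncol = length(act))
        for (k in seq_along(idx))
            codes[k, ] <- cpp_unpack_at(
                e$payloads[[as.character(set$keys[idx[k]])]], act0, set$size)
        lines <- if (format == "plink") {
            ped <- data.frame(family_id = rec$family_id[idx],
                              individual_id = sids[idx],
                              paternal_id = rec$paternal_id[idx],
                              maternal_id = rec$maternal_id[idx],
                              sex = rec$sex[idx],
                              phenotype = rec$phenotype[idx],
                              stringsAsFactors = FALSE)
            .pedLines(ped, codes, lookup)
        } else {
            .lines0125(sids[idx], codes)
        }
        writeLines(lines, con)
    }
    files <- c(mainPath, mapPath)
    phenoPath <- paste0(outPrefix, "_phenotypes.csv")
    nPheno <- exportPhenotypes(store, setName, phenoPath)
    if (nPheno > 0) files <- c(files, phenoPath)
    invisible(list(files = files, n_samples = n, n_snps = length(act)))
}

#' Export the SNP names and sample IDs of a genotype set
#'
#' Writes two text files: \code{<prefix>_snps.txt} with the active SNP names
#' in vector order and \code{<prefix>_samples.txt} with the sample IDs in
#' individual-selection order.
#'
#' @inheritParams exportSet
#' @return invisibly, a list with \code{files}, \code{n_snps},
#'   \code{n_samples}.
#' @export
exportIds <- function(store, setName, outPrefix) {
    set <- .getSet(store, setName)
    snps <- .panelSnps(store, set$panel)
    act <- which(.unpackSelBits(set$bits, set$size))
    snpPath <- paste0(outPrefix, "_snps.txt")
    samplePath <- paste0(outPrefix, "_samples.txt")
    writeLines(snps$snp_name[act], snpPath)
    writeLines(.keysSampleIds(store, set$keys), samplePath)
    invisible(list(files = c(snpPath, samplePath), n_snps = length(act),
                   n_samples = length(set$keys)))
}
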