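## Generalized phenotype storage: an entity-attribute-value model keyed by
## external sample ID. Any number of named phenotypes per sample, values
## kept as uninterpreted text; CSV in, CSV out.

#' Import phenotypes from a CSV file
#'
#' The first column holds sample IDs; the remaining header fields are
#' phenotype (attribute) names. Every non-empty cell becomes one stored
#' value; empty cells are absent values, not empty strings. Samples need not
#' be genotyped yet — phenotypes are linked by sample ID. A
#' (sample, attribute) pair already present in the store, or appearing twice
#' within the file, is a conflict error.
#'
#' @param store a [GenotypeStore-class].
#' @param csvPath CSV file with a header row.
#' @return number of phenotype values stored, invisibly.
#' @export
importPhenotypes <- function(store, csvPath) {
    df <- read.csv(csvPath, colClasses = "character", check.names = FALSE)
    if (ncol(df) < 2L)
        stop("phenotype CSV needs a sample-ID column plus at least one phenotype column",
             call. = FALSE)
    e <- store@env
    attrs <- names(df)[-1]
    long <- data.frame(
        sample_id = rep(df[[1]], times = length(attrs)),
        attribute = rep(attrs, each = nrow(df)),
        value = unlist(df[-1], use.names = FALSE),
        stringsAsFactors = FALSE)
    long <- long[!is.na(long$value) & nzchar(long$value), , drop = FALSE]
    key <- paste(long$sample_id, long$attribute, sep = "\r")
    if (anyDuplicated(key))
        stop(sprintf("duplicate (sample, phenotype) pair in %s: %s",
                     csvPath, sub("\r", " / ", key[duplicated(key)][1])),
             call. = FALSE)
    existing <- paste(e$phenotypes$sample_id, e$phenotypes$attribute,
                      sep = "\r")
    clash <- key %in% existing
    if (any(clash))
        stop(sprintf("phenotype already stored for %s",
                     sub("\r", " / ", key[clash][1])), call. = FALSE)
    if (nrow(long)) {
        long$created <- .now()
        e$phenotypes <- rbind(e$phenotypes, long)
    }
    .autosave(store)
    invisible(nrow(long))
}

.phenotypeFrame <- function(store, sampleIds) {
    # wide CSV frame for the given samples; attributes sorted for determinism
    ph <- store@env$phenotypes
    ph <- ph[ph$sample_id %in% sampleIds, , drop = FALSE]
    if (!nrow(ph)) return(NULL)
    attrs <- sort(unique(ph$attribute))
    sids <- unique(sampleIds[sampleIds %in% ph$sample_id])
    wide <- data.frame(sample_id = sids, stringsAsFactors = FALSE,
                       check.names = FALSE)
    for (a in attrs) {
        sub <- ph[ph$attribute == a, , drop = FALSE]
        wide[[a]] <- sub$value[match(sids, sub$sample_id)]
    }
    wide
}

#' Export the phenotypes of a genotype set as CSV
#'
#' Scans the store for phenotypes of the samples in the set and writes one
#' CSV row per sample that has at least one phenotype, under the union of
#' their attribute names (sorted; missing values as empty cells). If no
#' included sample has phenotypes, no file is written and 0 is returned.
#'
#' @param store a [GenotypeStore-class].
#' @param setName genotype set name.
#' @param outPath CSV output path.
#' @return number of data rows written (0 if no file was written).
#' @export
exportPhenotypes <- function(store, setName, outPath) {
    set <- .getSet(store, setName)
    wide <- .phenotypeFrame(store, unique(.keysSampleIds(store, set$keys)))
    if (is.null(wide)) return(0L)
    wide[is.na(wide)] <- ""
    write.csv(wide, outPath, row.names = FALSE, quote = FALSE)
    nrow(wide)
}
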