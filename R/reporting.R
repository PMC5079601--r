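## Housekeeping reports: database and panel sizes, selection-vector
## contents, comments. All reports are pure reads.

#' Database content report
#'
#' Per panel: SNP count, genotype record count and exact packed payload
#' bytes (records times \code{ceiling(size/4)}). Per selection kind:
#' row counts and byte costs (1 bit per SNP for SNP selections, 4 bytes per
#' key for individual selections). Grand totals included. The result is a
#' plain list (machine-readable); printing renders the usual console table.
#'
#' @param store a [GenotypeStore-class].
#' @return list of class \code{"databaseReport"} with elements
#'   \code{panels} (data.frame), \code{sets} (data.frame), and
#'   \code{totals} (named numeric: \code{records},
#'   \code{genotype_payload_bytes}, \code{selection_bytes},
#'   \code{total_bytes}).
#' @export
reportDatabase <- function(store) {
    e <- store@env
    p <- e$panels
    panels <- data.frame(panel = p$name, n_snps = p$size,
                         n_records = integer(nrow(p)),
                         payload_bytes = numeric(nrow(p)),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(p))) {
        nr <- sum(e$genotype_records$panel == p$name[i])
        panels$n_records[i] <- nr
        panels$payload_bytes[i] <- nr * packedSize(p$size[i])
    }
    ssBytes <- sum(vapply(e$ss_bits, length, 0))
    isBytes <- 4 * sum(vapply(e$is_keys, length, 0))
    sets <- data.frame(
        kind = c("genotype_set", "snp_selection", "individual_selection"),
        rows = c(nrow(e$genotype_sets), nrow(e$snp_selections),
                 nrow(e$individual_selections)),
        bytes = c(0, ssBytes, isBytes),
        stringsAsFactors = FALSE)
    totals <- c(records = nrow(e$genotype_records),
                genotype_payload_bytes = sum(panels$payload_bytes),
                selection_bytes = ssBytes + isBytes,
                total_bytes = attr(storageReport(store), "total_bytes"))
    structure(list(panels = panels, sets = sets, totals = totals),
              class = "databaseReport")
}

#' @export
print.databaseReport <- function(x, ...) {
    cat("Database report\n===============\n")
    if (nrow(x$panels)) {
        cat("Panels:\n")
        print(x$panels, row.names = FALSE)
    } else cat("Panels: none\n")
    cat("Selections and sets:\n")
    print(x$sets, row.names = FALSE)
    cat(sprintf("Totals: %d records, %s genotype payload bytes, %s selection bytes\n",
                x$totals[["records"]],
                format(x$totals[["genotype_payload_bytes"]], big.mark = ","),
                format(x$totals[["selection_bytes"]], big.mark = ",")))
    invisible(x)
}

#' Dump the contents of a selection vector
#'
#' For a SNP selection: the active SNP names and vector indices; for an
#' individual selection: the sample IDs (and record keys) in order. Source,
#' parent, creation timestamp and any comments are included.
#'
#' @param store a [GenotypeStore-class].
#' @param name selection name (\code{ss_NNN} or \code{is_NNN}).
#' @return list with \code{kind}, \code{name}, \code{panel}, \code{source},
#'   \code{parent}, \code{created}, \code{comments} and the contents
#'   (\code{snps} data.frame or \code{samples} data.frame).
#' @export
dumpSelection <- function(store, name) {
    e <- store@env
    if (name %in% e$snp_selections$name) {
        row <- e$snp_selections[match(name, e$snp_selections$name), ]
        size <- e$panels$size[match(row$panel, e$panels$name)]
        act <- which(.unpackSelBits(e$ss_bits[[name]], size))
        snps <- .panelSnps(store, row$panel)
        contents <- list(snps = data.frame(
            vector_index = act, snp_name = snps$snp_name[act],
            chromosome = snps$chromosome[act], stringsAsFactors = FALSE))
        kind <- "snp_selection"
    } else if (name %in% e$individual_selections$name) {
        row <- e$individual_selections[match(name,
                                             e$individual_selections$name), ]
        keys <- e$is_keys[[name]]
        contents <- list(samples = data.frame(
            record_key = keys, sample_id = .keysSampleIds(store, keys),
            stringsAsFactors = FALSE))
        kind <- "individual_selection"
    } else
        stop(sprintf("unknown selection: %s", name), call. = FALSE)
    cm <- e$comments[e$comments$entity == name, , drop = FALSE]
    c(list(kind = kind, name = row$name, panel = row$panel,
           source = row$source, parent = row$parent, created = row$created,
           comments = cm), contents)
}

.entityExists <- function(store, name) {
    e <- store@env
    name %in% c(e$panels$name, e$genotype_sets$name, e$snp_selections$name,
                e$individual_selections$name, e$individuals$sample_id)
}

#' Attach a comment to a database entity
#'
#' Comments document database actions as part of the database content. Each
#' call appends a timestamped row to the comment history; the latest comment
#' is the entity's current one (and is shown in [provenanceReport()] for
#' genotype sets). The full history is retained.
#'
#' @param store a [GenotypeStore-class].
#' @param entityName a panel, genotype set, selection or sample ID.
#' @param text comment text.
#' @return the comment history rows for the entity, invisibly.
#' @export
setComment <- function(store, entityName, text) {
    if (!.entityExists(store, entityName))
        stop(sprintf("unknown entity: %s", entityName), call. = FALSE)
    e <- store@env
    e$comments <- rbind(e$comments,
        data.frame(entity = entityName, text = text, created = .now()))
    i <- match(entityName, e$genotype_sets$name)
    if (!is.na(i)) e$genotype_sets$comment[i] <- text
    .autosave(store)
    invisible(e$comments[e$comments$entity == entityName, , drop = FALSE])
}

#' Comment history of an entity
#'
#' @param store a [GenotypeStore-class].
#' @param entityName entity name.
#' @return data.frame of comment rows in insertion order.
#' @export
getComments <- function(store, entityName) {
    e <- store@env
    e$comments[e$comments$entity == entityName, , drop = FALSE]
}
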