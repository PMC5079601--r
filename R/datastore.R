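## Embedded store: normalized tables held in an environment, persisted as a
## single serialized file. Mirrors the classical genotype-repository schema:
## panel, snp map, individual, genotype_data (packed payloads), snp_selection,
## individual_selection, genotype_set, phenotypes, comments; every row
## timestamped.

.SCHEMA_VERSION <- 1L

.emptyTables <- function() {
    now <- Sys.time()
    list(
        panels = data.frame(name = character(), size = integer(),
                            created = now[0]),
        snps = data.frame(panel = character(), vector_index = integer(),
                          chromosome = character(), snp_name = character(),
                          position_bp = numeric(), allele1 = character(),
                          allele2 = character(), coding_set = logical(),
                          created = now[0]),
        individuals = data.frame(sample_key = integer(),
                                 sample_id = character(), created = now[0]),
        genotype_records = data.frame(record_key = integer(),
                                      sample_key = integer(),
                                      panel = character(),
                                      family_id = character(),
                                      paternal_id = character(),
                                      maternal_id = character(),
                                      sex = character(),
                                      phenotype = character(),
                                      created = now[0]),
        snp_selections = data.frame(name = character(), panel = character(),
                                    source = character(), parent = character(),
                                    created = now[0]),
        individual_selections = data.frame(name = character(),
                                           panel = character(),
                                           source = character(),
                                           parent = character(),
                                           created = now[0]),
        genotype_sets = data.frame(name = character(), panel = character(),
                                   snp_selection = character(),
                                   individual_selection = character(),
                                   comment = character(), created = now[0]),
        phenotypes = data.frame(sample_id = character(),
                                attribute = character(), value = character(),
                                created = now[0]),
        comments = data.frame(entity = character(), text = character(),
                              created = now[0])
    )
}

#' Open or create a genotype store
#'
#' Creates an empty store (all schema tables present, no rows) or reopens an
#' existing one from its single backing file. Opening is idempotent: an
#' existing file is loaded, never overwritten. With \code{path = NA} the
#' store lives in memory only (useful for large transient analyses and
#' tests); [saveStore()] is then unavailable until a path is supplied.
#'
#' @param path backing file path, or \code{NA} for an in-memory store. The
#'   parent directory must exist and be writable.
#' @return a [GenotypeStore-class] handle.
#' @examples
#' st <- initStore(NA)   # in-memory store
#' st
#' @export
initStore <- function(path = NA_character_) {
    env <- new.env(parent = emptyenv())
    if (!is.na(path) && file.exists(path)) {
        dump <- readRDS(path)
        if (!identical(dump$schema_version, .SCHEMA_VERSION))
            stop(sprintf("store schema version mismatch: file has %s, package expects %d",
                         format(dump$schema_version), .SCHEMA_VERSION),
                 call. = FALSE)
        for (nm in names(dump$tables)) assign(nm, dump$tables[[nm]], envir = env)
        env$payloads <- dump$payloads
        env$ss_bits <- dump$ss_bits
        env$is_keys <- dump$is_keys
        env$counters <- dump$counters
    } else {
        if (!is.na(path)) {
            dir <- dirname(path)
            if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
                stop(sprintf("store path not writable: %s", path), call. = FALSE)
        }
        tabs <- .emptyTables()
        for (nm in names(tabs)) assign(nm, tabs[[nm]], envir = env)
        env$payloads <- list()
        env$ss_bits <- list()
        env$is_keys <- list()
        env$counters <- c(gs = 0L, is = 0L, ss = 0L,
                          sample_key = 0L, record_key = 0L)
    }
    store <- new("GenotypeStore", path = as.character(path), env = env)
    validObject(store)
    if (!is.na(path) && !file.exists(path)) saveStore(store)
    store
}

#' Persist a genotype store to its backing file
#'
#' Serializes all tables, selection vectors and packed payloads to a single
#' file. Mutating operations call this automatically for stores opened with
#' a path; it only needs to be called by hand after mutating an in-memory
#' store that was later given a path.
#'
#' @param store a [GenotypeStore-class].
#' @param path optional override of the store's backing file.
#' @return the store, invisibly.
#' @export
saveStore <- function(store, path = storePath(store)) {
    stopifnot(is(store, "GenotypeStore"))
    if (is.na(path))
        stop("store has no backing file; pass a path", call. = FALSE)
    e <- store@env
    dump <- list(schema_version = .SCHEMA_VERSION,
                 tables = mget(.STORE_TABLES, envir = e),
                 payloads = e$payloads, ss_bits = e$ss_bits,
                 is_keys = e$is_keys, counters = e$counters)
    saveRDS(dump, path, compress = FALSE)
    invisible(store)
}

.autosave <- function(store) {
    if (!is.na(store@path)) saveStore(store)
    invisible(store)
}

.now <- function() Sys.time()

.nextName <- function(store, kind) {
    # gs_/is_/ss_ sequential names, zero-padded to 3 digits, widening past 999
    e <- store@env
    e$counters[kind] <- e$counters[kind] + 1L
    sprintf("%s_%03d", kind, e$counters[kind])
}

.panelRow <- function(store, panel) {
    p <- store@env$panels
    i <- match(panel, p$name)
    if (is.na(i)) stop(sprintf("unknown panel: %s", panel), call. = FALSE)
    p[i, , drop = FALSE]
}

.panelSnps <- function(store, panel) {
    s <- store@env$snps
    s <- s[s$panel == panel, , drop = FALSE]
    s[order(s$vector_index), , drop = FALSE]
}

#' Register a panel (SNP map)
#'
#' A panel is a fixed, ordered SNP map; every genotype record refers to a
#' panel, and vector position \code{i} of a packed record is the panel's
#' \code{i}-th SNP. Map files must be imported before any genotype data
#' (see [importPanel()] / [importData()]).
#'
#' @param store a [GenotypeStore-class].
#' @param name unique panel name.
#' @param snps data.frame with columns \code{chromosome}, \code{snp_name},
#'   \code{position_bp} and optionally \code{allele1}/\code{allele2} (the
#'   allele coding), in map order — as returned by [readMap()].
#' @return the panel row (name, size), invisibly.
#' @export
addPanel <- function(store, name, snps) {
    stopifnot(is(store, "GenotypeStore"), is.data.frame(snps))
    e <- store@env
    if (name %in% e$panels$name)
        stop(sprintf("panel already exists: %s", name), call. = FALSE)
    need <- c("chromosome", "snp_name", "position_bp")
    if (!all(need %in% names(snps)))
        stop("snps must have columns chromosome, snp_name, position_bp",
             call. = FALSE)
    if (anyDuplicated(snps$snp_name))
        stop(sprintf("duplicate SNP name(s) in map: %s",
                     paste(unique(snps$snp_name[duplicated(snps$snp_name)])[1:3],
                           collapse = ", ")), call. = FALSE)
    n <- nrow(snps)
    if (n == 0L) stop("empty map", call. = FALSE)
    hasCoding <- all(c("allele1", "allele2") %in% names(snps)) &&
        !all(is.na(snps$allele1))
    rows <- data.frame(
        panel = name, vector_index = seq_len(n),
        chromosome = as.character(snps$chromosome),
        snp_name = as.character(snps$snp_name),
        position_bp = as.numeric(snps$position_bp),
        allele1 = if (hasCoding) as.character(snps$allele1) else NA_character_,
        allele2 = if (hasCoding) as.character(snps$allele2) else NA_character_,
        coding_set = if (hasCoding) !is.na(snps$allele1) else FALSE,
        created = .now())
    e$snps <- rbind(e$snps, rows)
    e$panels <- rbind(e$panels,
                      data.frame(name = name, size = n, created = .now()))
    .autosave(store)
    invisible(e$panels[e$panels$name == name, , drop = FALSE])
}

.DEFAULT_PED <- function(sampleId)
    c(family_id = sampleId, paternal_id = "0", maternal_id = "0",
      sex = "0", phenotype = "-9")

## Internal: append packed records in bulk (one rbind per call, so imports
## stay linear in the number of records). `payloads` is a list of raw
## vectors already validated against the panel size; `ped` an optional
## data.frame of the 6 leading ped columns minus the sample ID. Returns the
## new record keys in input order.
.addRecordsPacked <- function(store, sampleIds, panel, payloads, ped = NULL) {
    e <- store@env
    sampleIds <- as.character(sampleIds)
    n <- length(sampleIds)
    skey <- e$individuals$sample_key[match(sampleIds, e$individuals$sample_id)]
    newIds <- unique(sampleIds[is.na(skey)])
    if (length(newIds)) {
        keys <- e$counters[["sample_key"]] + seq_along(newIds)
        e$counters["sample_key"] <- keys[length(keys)]
        e$individuals <- rbind(e$individuals,
            data.frame(sample_key = keys, sample_id = newIds,
                       created = .now()))
        skey <- e$individuals$sample_key[match(sampleIds,
                                               e$individuals$sample_id)]
    }
    rkey <- e$counters[["record_key"]] + seq_len(n)
    e$counters["record_key"] <- rkey[n]
    if (is.null(ped))
        ped <- data.frame(family_id = sampleIds, paternal_id = "0",
                          maternal_id = "0", sex = "0", phenotype = "-9",
                          stringsAsFactors = FALSE)
    e$genotype_records <- rbind(e$genotype_records,
        data.frame(record_key = rkey, sample_key = skey, panel = panel,
                   family_id = ped$family_id, paternal_id = ped$paternal_id,
                   maternal_id = ped$maternal_id, sex = ped$sex,
                   phenotype = ped$phenotype, created = .now()))
    e$payloads <- c(e$payloads, stats::setNames(payloads, as.character(rkey)))
    rkey
}

.addRecordPacked <- function(store, sampleId, panel, pay, ped = NULL) {
    pedDf <- if (is.null(ped)) NULL
             else as.data.frame(as.list(ped), stringsAsFactors = FALSE)
    .addRecordsPacked(store, sampleId, panel, list(pay), pedDf)
}

#' Store one genotype record
#'
#' Packs and stores one sample's genotypes on a panel. A new individual row
#' is created the first time a \code{sampleId} is seen; importing the same
#' \code{sampleId} again adds a second record to the same individual —
#' duplicate records are data (re-genotyping), not errors, and can be listed
#' with [findDuplicateSamples()].
#'
#' @param store a [GenotypeStore-class].
#' @param sampleId external sample ID.
#' @param panel panel name.
#' @param codes integer genotype codes (length = panel size) or a
#'   [PackedGenotypes] of matching length.
#' @param ped optional named character vector with elements \code{family_id},
#'   \code{paternal_id}, \code{maternal_id}, \code{sex}, \code{phenotype}
#'   (the ped leading columns); defaults are \code{sampleId, 0, 0, 0, -9}.
#' @return the new record key, invisibly.
#' @export
addGenotypeRecord <- function(store, sampleId, panel, codes, ped = NULL) {
    stopifnot(is(store, "GenotypeStore"))
    size <- .panelRow(store, panel)$size
    if (is(codes, "PackedGenotypes")) {
        if (nSnps(codes) != size)
            stop(sprintf("record has %d genotypes but panel %s has %d SNPs",
                         nSnps(codes), panel, size), call. = FALSE)
        pay <- payload(codes)
    } else {
        if (length(codes) != size)
            stop(sprintf("record has %d genotypes but panel %s has %d SNPs",
                         length(codes), panel, size), call. = FALSE)
        pay <- cpp_pack(as.integer(codes))
    }
    key <- .addRecordPacked(store, sampleId, panel, pay, ped)
    .autosave(store)
    invisible(key)
}

.recordPayload <- function(store, recordKey) {
    store@env$payloads[[as.character(recordKey)]]
}

#' List samples with more than one genotype record
#'
#' A duplicate is the same external sample ID with two or more genotype
#' records on the same panel (re-genotyped samples). Repeats across panels
#' are not duplicates.
#'
#' @param store a [GenotypeStore-class].
#' @param panel panel name.
#' @return data.frame with columns \code{sample_id}, \code{n_records}
#'   (only IDs with two or more records).
#' @export
findDuplicateSamples <- function(store, panel) {
    .panelRow(store, panel)
    e <- store@env
    rec <- e$genotype_records[e$genotype_records$panel == panel, , drop = FALSE]
    sid <- e$individuals$sample_id[match(rec$sample_key,
                                         e$individuals$sample_key)]
    tab <- table(sid)
    tab <- tab[tab >= 2L]
    data.frame(sample_id = names(tab), n_records = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
}

## ---- deletion with cascades ----

.dependentsOfSelection <- function(store, col, name) {
    e <- store@env
    tbl <- if (col == "snp_selection") e$snp_selections else e$individual_selections
    kids <- tbl$name[!is.na(tbl$parent) & tbl$parent == name]
    sets <- e$genotype_sets$name[e$genotype_sets[[col]] == name]
    out <- list(children = kids, sets = sets)
    for (k in kids) {
        sub <- .dependentsOfSelection(store, col, k)
        out$children <- union(out$children, sub$children)
        out$sets <- union(out$sets, sub$sets)
    }
    out
}

#' Delete an entity with cascading deletes
#'
#' Removes a panel, individual, genotype set, selection vector or genotype
#' record, together with everything that depends on it. Deleting a selection
#' that other selections or genotype sets are built on requires
#' \code{cascade = TRUE}; without it the call refuses and lists the
#' dependents. Deleting an individual or genotype record prunes its key from
#' individual selections (genotype sets whose individual selection becomes
#' empty are retained but refuse to export).
#'
#' @param store a [GenotypeStore-class].
#' @param kind one of \code{"panel"}, \code{"individual"},
#'   \code{"genotype_set"}, \code{"individual_selection"},
#'   \code{"snp_selection"}, \code{"genotype_record"}.
#' @param name entity name (panel name, sample ID, set/selection name, or
#'   record key as character).
#' @param cascade allow removal of dependent selections and sets.
#' @return named integer vector: rows removed per table.
#' @export
deleteEntity <- function(store, kind, name, cascade = FALSE) {
    kind <- match.arg(kind, c("panel", "individual", "genotype_set",
                              "individual_selection", "snp_selection",
                              "genotype_record"))
    e <- store@env
    removed <- c(panels = 0L, snps = 0L, individuals = 0L,
                 genotype_records = 0L, snp_selections = 0L,
                 individual_selections = 0L, genotype_sets = 0L,
                 comments = 0L)
    name <- as.character(name)

    dropComments <- function(entities) {
        keep <- !(e$comments$entity %in% entities)
        removed["comments"] <<- removed["comments"] + sum(!keep)
        e$comments <- e$comments[keep, , drop = FALSE]
    }
    dropSets <- function(sets) {
        keep <- !(e$genotype_sets$name %in% sets)
        removed["genotype_sets"] <<- removed["genotype_sets"] + sum(!keep)
        e$genotype_sets <- e$genotype_sets[keep, , drop = FALSE]
        dropComments(sets)
    }
    dropSelection <- function(col, names) {
        tblName <- if (col == "snp_selection") "snp_selections"
                   else "individual_selections"
        tbl <- e[[tblName]]
        keep <- !(tbl$name %in% names)
        removed[tblName] <<- removed[tblName] + sum(!keep)
        e[[tblName]] <- tbl[keep, , drop = FALSE]
        if (col == "snp_selection")
            e$ss_bits[names] <- NULL
        else
            e$is_keys[names] <- NULL
        dropComments(names)
    }
    dropRecords <- function(keys) {
        keep <- !(e$genotype_records$record_key %in% keys)
        removed["genotype_records"] <<- removed["genotype_records"] + sum(!keep)
        e$genotype_records <- e$genotype_records[keep, , drop = FALSE]
        e$payloads[as.character(keys)] <- NULL
        # prune deleted record keys from individual selections
        e$is_keys <- lapply(e$is_keys, function(k) setdiff(k, keys))
    }

    if (kind == "genotype_set") {
        if (!(name %in% e$genotype_sets$name))
            stop(sprintf("unknown genotype set: %s", name), call. = FALSE)
        dropSets(name)
    } else if (kind %in% c("snp_selection", "individual_selection")) {
        tbl <- if (kind == "snp_selection") e$snp_selections
               else e$individual_selections
        if (!(name %in% tbl$name))
            stop(sprintf("unknown %s: %s", kind, name), call. = FALSE)
        deps <- .dependentsOfSelection(store, kind, name)
        if ((length(deps$children) || length(deps$sets)) && !cascade)
            stop(sprintf("%s %s has dependents (%s); use cascade = TRUE",
                         kind, name,
                         paste(c(deps$children, deps$sets), collapse = ", ")),
                 call. = FALSE)
        dropSets(deps$sets)
        dropSelection(kind, c(deps$children, name))
    } else if (kind == "genotype_record") {
        key <- suppressWarnings(as.integer(name))
        if (is.na(key) || !(key %in% e$genotype_records$record_key))
            stop(sprintf("unknown genotype record: %s", name), call. = FALSE)
        dropRecords(key)
    } else if (kind == "individual") {
        i <- match(name, e$individuals$sample_id)
        if (is.na(i))
            stop(sprintf("unknown individual: %s", name), call. = FALSE)
        skey <- e$individuals$sample_key[i]
        dropRecords(e$genotype_records$record_key[
            e$genotype_records$sample_key == skey])
        e$individuals <- e$individuals[-i, , drop = FALSE]
        removed["individuals"] <- removed["individuals"] + 1L
    } else {  # panel
        if (!(name %in% e$panels$name))
            stop(sprintf("unknown panel: %s", name), call. = FALSE)
        dropSets(e$genotype_sets$name[e$genotype_sets$panel == name])
        dropSelection("snp_selection",
                      e$snp_selections$name[e$snp_selections$panel == name])
        dropSelection("individual_selection",
            e$individual_selections$name[e$individual_selections$panel == name])
        dropRecords(e$genotype_records$record_key[
            e$genotype_records$panel == name])
        keepS <- e$snps$panel != name
        removed["snps"] <- removed["snps"] + sum(!keepS)
        e$snps <- e$snps[keepS, , drop = FALSE]
        e$panels <- e$panels[e$panels$name != name, , drop = FALSE]
        removed["panels"] <- removed["panels"] + 1L
        dropComments(name)
    }
    .autosave(store)
    removed
}

#' Per-table storage report
#'
#' Row and byte counts per table plus the grand total. Genotype payload
#' bytes are exact (the sum of \code{ceiling(panel size / 4)} over stored
#' records, which equals the summed payload lengths); selection vectors are
#' costed at 1 bit per SNP (packed bytes) and 4 bytes per individual key;
#' the remaining tables are costed by their in-memory object size.
#'
#' @param store a [GenotypeStore-class].
#' @return data.frame with columns \code{table}, \code{rows}, \code{bytes};
#'   attribute \code{total_bytes} holds the sum.
#' @export
storageReport <- function(store) {
    e <- store@env
    payloadBytes <- sum(vapply(e$payloads, length, 0))
    ssBytes <- sum(vapply(e$ss_bits, length, 0))
    isBytes <- 4 * sum(vapply(e$is_keys, length, 0))
    tabBytes <- function(df) as.numeric(object.size(df))
    out <- data.frame(
        table = c("panels", "snps", "individuals", "genotype_data",
                  "snp_selections", "individual_selections", "genotype_sets",
                  "phenotypes", "comments"),
        rows = c(nrow(e$panels), nrow(e$snps), nrow(e$individuals),
                 nrow(e$genotype_records), nrow(e$snp_selections),
                 nrow(e$individual_selections), nrow(e$genotype_sets),
                 nrow(e$phenotypes), nrow(e$comments)),
        bytes = c(tabBytes(e$panels), tabBytes(e$snps), tabBytes(e$individuals),
                  payloadBytes, ssBytes, isBytes,
                  tabBytes(e$genotype_sets), tabBytes(e$phenotypes),
                  tabBytes(e$comments)),
        stringsAsFactors = FALSE)
    if (nrow(e$panels) == 0L && nrow(e$phenotypes) == 0L &&
        nrow(e$comments) == 0L)
        out$bytes[] <- c(0, 0, 0, payloadBytes, ssBytes, isBytes, 0, 0, 0)
    attr(out, "total_bytes") <- sum(out$bytes)
    out
}

#' Validate referential integrity of a store
#'
#' Full-scan check of every invariant the schema promises: payload lengths
#' match panel sizes, selections reference existing panels and records,
#' genotype sets reference existing selections on the same panel, selection
#' bit vectors have panel length, individual-selection keys are distinct,
#' parent chains are acyclic, and all rows carry timestamps.
#'
#' @param store a [GenotypeStore-class].
#' @return \code{TRUE} invisibly, or an error describing the first violation.
#' @export
validateStore <- function(store) {
    e <- store@env
    fail <- function(...) stop(sprintf(...), call. = FALSE)
    sizes <- e$panels$size[match(e$genotype_records$panel, e$panels$name)]
    if (anyNA(sizes)) fail("genotype record references unknown panel")
    for (i in seq_len(nrow(e$genotype_records))) {
        pay <- e$payloads[[as.character(e$genotype_records$record_key[i])]]
        if (is.null(pay)) fail("record %d has no payload",
                               e$genotype_records$record_key[i])
        if (length(pay) != ceiling(sizes[i] / 4))
            fail("record %d payload length %d != ceiling(%d/4)",
                 e$genotype_records$record_key[i], length(pay), sizes[i])
    }
    if (!all(e$genotype_records$sample_key %in% e$individuals$sample_key))
        fail("genotype record references unknown individual")
    for (i in seq_len(nrow(e$snp_selections))) {
        nm <- e$snp_selections$name[i]
        size <- e$panels$size[match(e$snp_selections$panel[i], e$panels$name)]
        if (is.na(size)) fail("snp selection %s references unknown panel", nm)
        if (length(e$ss_bits[[nm]]) != ceiling(size / 8))
            fail("snp selection %s has wrong bit-vector length", nm)
    }
    for (i in seq_len(nrow(e$individual_selections))) {
        nm <- e$individual_selections$name[i]
        keys <- e$is_keys[[nm]]
        if (anyDuplicated(keys))
            fail("individual selection %s has duplicate keys", nm)
        if (!all(keys %in% e$genotype_records$record_key))
            fail("individual selection %s references missing records", nm)
    }
    gs <- e$genotype_sets
    bad <- !(gs$snp_selection %in% e$snp_selections$name) |
           !(gs$individual_selection %in% e$individual_selections$name)
    if (any(bad)) fail("genotype set %s references missing selections",
                       gs$name[bad][1])
    ssp <- e$snp_selections$panel[match(gs$snp_selection, e$snp_selections$name)]
    isp <- e$individual_selections$panel[match(gs$individual_selection,
                                               e$individual_selections$name)]
    if (any(ssp != isp)) fail("genotype set %s mixes panels",
                              gs$name[ssp != isp][1])
    for (tbl in .STORE_TABLES) {
        df <- e[[tbl]]
        if (nrow(df) && (!("created" %in% names(df)) || anyNA(df$created)))
            fail("table %s has rows without timestamps", tbl)
    }
    # acyclic parent chains ending at an import-created selection
    for (tbl in c("snp_selections", "individual_selections")) {
        df <- e[[tbl]]
        for (nm in df$name) {
            seen <- character()
            cur <- nm
            while (!is.na(cur)) {
                if (cur %in% seen) fail("cycle in parent chain at %s", cur)
                seen <- c(seen, cur)
                cur <- df$parent[match(cur, df$name)]
            }
        }
    }
    invisible(TRUE)
}

## ---- internal selection/set constructors (shared by ingest/subsets) ----

.newSnpSelection <- function(store, panel, activeBits, source,
                             parent = NA_character_) {
    e <- store@env
    nm <- .nextName(store, "ss")
    e$snp_selections <- rbind(e$snp_selections,
        data.frame(name = nm, panel = panel, source = source,
                   parent = parent, created = .now()))
    e$ss_bits[[nm]] <- activeBits
    nm
}

.newIndividualSelection <- function(store, panel, keys, source,
                                    parent = NA_character_) {
    e <- store@env
    nm <- .nextName(store, "is")
    e$individual_selections <- rbind(e$individual_selections,
        data.frame(name = nm, panel = panel, source = source,
                   parent = parent, created = .now()))
    e$is_keys[[nm]] <- as.integer(keys)
    nm
}

.newGenotypeSet <- function(store, panel, ssName, isName,
                            comment = NA_character_) {
    e <- store@env
    nm <- .nextName(store, "gs")
    e$genotype_sets <- rbind(e$genotype_sets,
        data.frame(name = nm, panel = panel, snp_selection = ssName,
                   individual_selection = isName, comment = comment,
                   created = .now()))
    nm
}

.getSet <- function(store, setName) {
    e <- store@env
    i <- match(setName, e$genotype_sets$name)
    if (is.na(i)) stop(sprintf("unknown genotype set: %s", setName),
                       call. = FALSE)
    gs <- e$genotype_sets[i, , drop = FALSE]
    size <- .panelRow(store, gs$panel)$size
    list(name = gs$name, panel = gs$panel, size = size,
         ss = gs$snp_selection, is = gs$individual_selection,
         bits = e$ss_bits[[gs$snp_selection]],
         keys = e$is_keys[[gs$individual_selection]])
}
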