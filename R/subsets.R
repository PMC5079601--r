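## Derived genotype sets: list-based selection and database-side filters
## (duplicate records, chromosomes, no-call rates, minor allele frequency),
## each creating one new named set with hierarchical provenance. A filter
## that leaves one dimension untouched lets the new set reference the
## parent's selection for that dimension, so subsets cost almost nothing.

.keysSampleIds <- function(store, keys) {
    e <- store@env
    skey <- e$genotype_records$sample_key[match(keys,
                                                e$genotype_records$record_key)]
    e$individuals$sample_id[match(skey, e$individuals$sample_key)]
}

.setPayloads <- function(store, keys) {
    store@env$payloads[as.character(keys)]
}

#' Per-SNP genotype statistics for a genotype set
#'
#' Counts of the four genotype states per active SNP over the set's samples,
#' with allele frequencies over called genotypes: the allele-1 frequency is
#' \eqn{(2 n_0 + n_1) / (2 (n_0 + n_1 + n_3))} and the minor allele
#' frequency is the smaller of it and its complement. SNPs with no called
#' genotypes get \code{NA} frequencies.
#'
#' @param store a [GenotypeStore-class].
#' @param setName genotype set name.
#' @return data.frame, one row per active SNP: \code{vector_index},
#'   \code{snp_name}, \code{chromosome}, \code{n_hom1}, \code{n_het},
#'   \code{n_nocall}, \code{n_hom2}, \code{freq_allele1}, \code{maf}.
#' @export
snpSetStats <- function(store, setName) {
    set <- .getSet(store, setName)
    scan <- cpp_scan_stats(.setPayloads(store, set$keys), set$size, set$bits)
    act <- which(.unpackSelBits(set$bits, set$size))
    snps <- .panelSnps(store, set$panel)
    n0 <- scan$counts[1, act]; n1 <- scan$counts[2, act]
    n2 <- scan$counts[3, act]; n3 <- scan$counts[4, act]
    called <- n0 + n1 + n3
    f1 <- ifelse(called > 0, (2 * n0 + n1) / (2 * called), NA_real_)
    data.frame(vector_index = act, snp_name = snps$snp_name[act],
               chromosome = snps$chromosome[act],
               n_hom1 = n0, n_het = n1, n_nocall = n2, n_hom2 = n3,
               freq_allele1 = f1, maf = pmin(f1, 1 - f1),
               stringsAsFactors = FALSE)
}

.deriveSet <- function(store, parent, ssName, isName, comment) {
    gs <- .newGenotypeSet(store, parent$panel, ssName, isName, comment)
    .autosave(store)
    gs
}

#' Derive a genotype set from sample and SNP lists
#'
#' Builds a subset of a parent genotype set from an explicit sample keep
#' list and/or a SNP list (see [readSelectionLists()]). The new individual
#' selection keeps the parent's records whose sample IDs are listed, in
#' parent order; the new SNP selection is the parent's bits AND-ed with the
#' list. A one-column SNP list keeps exactly the named SNPs; a two-column
#' name/flag list only switches off the SNPs flagged \code{0}. Identifiers
#' not present in the parent raise an error naming the offenders, and a
#' selection that would come out empty is refused. The parent is unchanged.
#'
#' @param store a [GenotypeStore-class].
#' @param parentSet parent genotype set name.
#' @param samples character vector of sample IDs to keep, or NULL.
#' @param snpFlags named logical vector of SNP keep flags (as returned in
#'   \code{readSelectionLists()$snpFlags}), or NULL.
#' @param comment optional comment on the new set.
#' @return name of the new genotype set.
#' @export
subsetByLists <- function(store, parentSet, samples = NULL, snpFlags = NULL,
                          comment = NA_character_) {
    if (is.null(samples) && is.null(snpFlags))
        stop("at least one of samples, snpFlags is required", call. = FALSE)
    parent <- .getSet(store, parentSet)
    isName <- parent$is
    ssName <- parent$ss
    if (!is.null(samples)) {
        sids <- .keysSampleIds(store, parent$keys)
        missing <- setdiff(samples, sids)
        if (length(missing))
            stop(sprintf("sample ID(s) not in %s: %s", parentSet,
                         paste(head(missing, 5), collapse = ", ")),
                 call. = FALSE)
        keys <- parent$keys[sids %in% samples]
        if (!length(keys))
            stop("refusing to create an empty individual selection",
                 call. = FALSE)
        isName <- .newIndividualSelection(store, parent$panel, keys,
            sprintf("sample list on %s", parentSet), parent = parent$is)
    }
    if (!is.null(snpFlags)) {
        snps <- .panelSnps(store, parent$panel)
        missing <- setdiff(names(snpFlags), snps$snp_name)
        if (length(missing))
            stop(sprintf("SNP name(s) not on panel %s: %s", parent$panel,
                         paste(head(missing, 5), collapse = ", ")),
                 call. = FALSE)
        act <- .unpackSelBits(parent$bits, parent$size)
        dialect <- attr(snpFlags, "dialect")
        if (is.null(dialect))
            dialect <- if (any(!snpFlags)) "flags" else "names"
        flags <- if (dialect == "flags") {
            f <- rep.int(TRUE, parent$size)      # unlisted SNPs keep their bit
            f[match(names(snpFlags), snps$snp_name)] <- unname(snpFlags)
            f
        } else {
            seq_len(parent$size) %in%
                match(names(snpFlags)[snpFlags], snps$snp_name)
        }
        act <- act & flags
        if (!any(act))
            stop("refusing to create an empty SNP selection", call. = FALSE)
        ssName <- .newSnpSelection(store, parent$panel, .packSelBits(act),
            sprintf("SNP list on %s", parentSet), parent = parent$ss)
    }
    .deriveSet(store, parent, ssName, isName, comment)
}

#' Derive a genotype set without duplicate records
#'
#' Keeps exactly one genotype record per external sample ID: the record with
#' the earliest insertion timestamp (ties broken by record key), a stable
#' deterministic choice. The SNP selection is inherited unchanged from the
#' parent. A parent without duplicates still yields a new named set (with a
#' copied individual selection).
#'
#' @inheritParams subsetByLists
#' @return name of the new genotype set.
#' @export
removeDuplicates <- function(store, parentSet, comment = NA_character_) {
    parent <- .getSet(store, parentSet)
    e <- store@env
    rec <- e$genotype_records[match(parent$keys, e$genotype_records$record_key),
                              , drop = FALSE]
    sid <- .keysSampleIds(store, parent$keys)
    ord <- order(rec$created, rec$record_key)
    first <- !duplicated(sid[ord])
    keep <- sort(match(rec$record_key[ord][first], parent$keys))
    keys <- parent$keys[keep]
    isName <- .newIndividualSelection(store, parent$panel, keys,
        sprintf("remove duplicates on %s", parentSet), parent = parent$is)
    .deriveSet(store, parent, parent$ss, isName, comment)
}

#' Derive a genotype set excluding chromosomes
#'
#' Sets the SNP-selection bits of all SNPs on the excluded chromosomes to 0;
#' the individual selection is inherited. Labels absent from the panel map
#' produce a warning; excluding every active SNP is refused.
#'
#' @inheritParams subsetByLists
#' @param exclude character vector of chromosome labels to drop (labels are
#'   text, e.g. \code{"W"}, \code{"X"}, \code{"MT"}).
#' @return name of the new genotype set.
#' @export
filterChromosomes <- function(store, parentSet, exclude,
                              comment = NA_character_) {
    parent <- .getSet(store, parentSet)
    snps <- .panelSnps(store, parent$panel)
    absent <- setdiff(exclude, unique(snps$chromosome))
    if (length(absent))
        warning(sprintf("chromosome label(s) not on panel %s: %s",
                        parent$panel, paste(absent, collapse = ", ")),
                call. = FALSE)
    act <- .unpackSelBits(parent$bits, parent$size)
    act <- act & !(snps$chromosome %in% exclude)
    if (!any(act))
        stop("refusing to create an empty SNP selection (all chromosomes excluded)",
             call. = FALSE)
    ssName <- .newSnpSelection(store, parent$panel, .packSelBits(act),
        sprintf("exclude chromosomes %s on %s",
                paste(exclude, collapse = ","), parentSet),
        parent = parent$ss)
    .deriveSet(store, parent, ssName, parent$is, comment)
}

#' Derive a genotype set by no-call filtering
#'
#' Two-stage missingness filter. First, each sample's no-call frequency is
#' computed over the parent's active SNPs and samples exceeding
#' \code{sampleThreshold} are dropped; then each active SNP's no-call
#' frequency is computed over the retained samples and SNPs exceeding
#' \code{snpThreshold} are zeroed in the SNP selection. Comparisons are
#' strict (drop if frequency \eqn{>} threshold). Either stage may be skipped
#' by leaving its threshold NULL; the corresponding selection is then
#' inherited.
#'
#' @inheritParams subsetByLists
#' @param sampleThreshold,snpThreshold no-call frequency thresholds in
#'   \eqn{[0, 1]}; at least one must be given.
#' @return name of the new genotype set.
#' @export
filterNocall <- function(store, parentSet, sampleThreshold = NULL,
                         snpThreshold = NULL, comment = NA_character_) {
    if (is.null(sampleThreshold) && is.null(snpThreshold))
        stop("at least one of sampleThreshold, snpThreshold is required",
             call. = FALSE)
    for (t in c(sampleThreshold, snpThreshold))
        if (t < 0 || t > 1)
            stop("no-call thresholds must be in [0, 1]", call. = FALSE)
    parent <- .getSet(store, parentSet)
    isName <- parent$is
    ssName <- parent$ss
    keys <- parent$keys
    nActive <- .countSelBits(parent$bits, parent$size)
    if (!is.null(sampleThreshold)) {
        scan <- cpp_scan_stats(.setPayloads(store, keys), parent$size,
                               parent$bits)
        freq <- scan$sample_nocall / nActive
        keys <- keys[freq <= sampleThreshold]
        if (!length(keys))
            stop("refusing to create an empty individual selection (every sample exceeds the no-call threshold)",
                 call. = FALSE)
        isName <- .newIndividualSelection(store, parent$panel, keys,
            sprintf("no-call sample threshold %g on %s", sampleThreshold,
                    parentSet), parent = parent$is)
    }
    if (!is.null(snpThreshold)) {
        scan <- cpp_scan_stats(.setPayloads(store, keys), parent$size,
                               parent$bits)
        act <- .unpackSelBits(parent$bits, parent$size)
        freq <- scan$counts[3, ] / length(keys)
        act <- act & freq <= snpThreshold
        if (!any(act))
            stop("refusing to create an empty SNP selection (every SNP exceeds the no-call threshold)",
                 call. = FALSE)
        ssName <- .newSnpSelection(store, parent$panel, .packSelBits(act),
            sprintf("no-call SNP threshold %g on %s", snpThreshold, parentSet),
            parent = parent$ss)
    }
    .deriveSet(store, parent, ssName, isName, comment)
}

#' Derive a genotype set by minor-allele-frequency filtering
#'
#' Allele frequencies are computed per active SNP over the called genotypes
#' of the set's samples (allele-1 count \eqn{2 n_0 + n_1} over
#' \eqn{2 (n_0 + n_1 + n_3)} alleles); SNPs whose minor allele frequency
#' falls strictly below \code{threshold} are zeroed in the SNP selection.
#' SNPs with no called genotypes fail any threshold above zero. The
#' individual selection is inherited. Filters chain: applying 0.05 to the
#' result of 0.03 equals applying 0.05 directly while the sample set is
#' unchanged.
#'
#' @inheritParams subsetByLists
#' @param threshold MAF floor in \eqn{[0, 0.5]}.
#' @return name of the new genotype set.
#' @export
filterMaf <- function(store, parentSet, threshold,
                      comment = NA_character_) {
    if (threshold < 0 || threshold > 0.5)
        stop("MAF threshold must be in [0, 0.5]", call. = FALSE)
    parent <- .getSet(store, parentSet)
    scan <- cpp_scan_stats(.setPayloads(store, parent$keys), parent$size,
                           parent$bits)
    n0 <- scan$counts[1, ]; n1 <- scan$counts[2, ]; n3 <- scan$counts[4, ]
    called <- n0 + n1 + n3
    f1 <- ifelse(called > 0, (2 * n0 + n1) / (2 * called), NA_real_)
    maf <- pmin(f1, 1 - f1)
    act <- .unpackSelBits(parent$bits, parent$size)
    act <- act & !is.na(maf) & maf >= threshold
    if (threshold == 0)           # threshold 0 removes nothing, even no-calls
        act <- .unpackSelBits(parent$bits, parent$size)
    if (!any(act))
        stop("refusing to create an empty SNP selection (every SNP fails the MAF threshold)",
             call. = FALSE)
    ssName <- .newSnpSelection(store, parent$panel, .packSelBits(act),
        sprintf("MAF threshold %g on %s", threshold, parentSet),
        parent = parent$ss)
    .deriveSet(store, parent, ssName, parent$is, comment)
}

.chainDepth <- function(df, name) {
    d <- 0L
    cur <- df$parent[match(name, df$name)]
    while (!is.na(cur)) {
        d <- d + 1L
        cur <- df$parent[match(cur, df$name)]
    }
    d
}

#' Hierarchical provenance report of all genotype sets
#'
#' One row per genotype set, in creation order, with its selection names,
#' sample and active-SNP counts, derivation depth (the longest parent chain
#' of its selections) and the Source text of both selections. Printing
#' indents by depth, mirroring how hierarchical subset definitions are
#' usually displayed.
#'
#' @param store a [GenotypeStore-class].
#' @return data.frame of class \code{"provenanceReport"} with columns
#'   \code{set}, \code{panel}, \code{snp_selection},
#'   \code{individual_selection}, \code{n_samples}, \code{n_active_snps},
#'   \code{depth}, \code{source_ss}, \code{source_is}, \code{comment}.
#' @export
provenanceReport <- function(store) {
    e <- store@env
    gs <- e$genotype_sets
    n <- nrow(gs)
    out <- data.frame(set = gs$name, panel = gs$panel,
                      snp_selection = gs$snp_selection,
                      individual_selection = gs$individual_selection,
                      n_samples = integer(n), n_active_snps = integer(n),
                      depth = integer(n),
                      source_ss = character(n), source_is = character(n),
                      comment = gs$comment, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        size <- e$panels$size[match(gs$panel[i], e$panels$name)]
        out$n_samples[i] <- length(e$is_keys[[gs$individual_selection[i]]])
        out$n_active_snps[i] <- .countSelBits(e$ss_bits[[gs$snp_selection[i]]],
                                              size)
        out$depth[i] <- max(.chainDepth(e$snp_selections, gs$snp_selection[i]),
                            .chainDepth(e$individual_selections,
                                        gs$individual_selection[i]))
        out$source_ss[i] <- e$snp_selections$source[
            match(gs$snp_selection[i], e$snp_selections$name)]
        out$source_is[i] <- e$individual_selections$source[
            match(gs$individual_selection[i], e$individual_selections$name)]
    }
    class(out) <- c("provenanceReport", "data.frame")
    out
}

#' @export
print.provenanceReport <- function(x, ...) {
    if (!nrow(x)) {
        cat("no genotype sets\n")
        return(invisible(x))
    }
    for (i in seq_len(nrow(x))) {
        pad <- strrep("  ", x$depth[i])
        cat(sprintf("%s%s [%s]: %s + %s | %d samples, %d SNPs\n",
                    pad, x$set[i], x$panel[i], x$individual_selection[i],
                    x$snp_selection[i], x$n_samples[i], x$n_active_snps[i]))
        cat(sprintf("%s  Source: is: %s | ss: %s\n", pad, x$source_is[i],
                    x$source_ss[i]))
        if (!is.na(x$comment[i]))
            cat(sprintf("%s  Comment: %s\n", pad, x$comment[i]))
    }
    invisible(x)
}
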