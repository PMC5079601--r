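#' @useDynLib snpvault, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is setValidity show
#' @importFrom stats runif
#' @importFrom utils read.csv write.csv head object.size
NULL

#' Packed 2-bit genotype vector
#'
#' One sample's genotypes on one panel, packed at 2 bits per SNP: code 0 is
#' homozygous for allele 1, 1 heterozygous, 2 no-call, 3 homozygous for
#' allele 2. Code \eqn{i} (1-based) occupies bits \eqn{2((i-1) \bmod 4)} and
#' \eqn{2((i-1) \bmod 4)+1} of payload byte \eqn{\lfloor (i-1)/4 \rfloor},
#' least-significant bits first; pad bits of the final byte are zero. The
#' payload therefore occupies exactly \code{ceiling(nSnps/4)} bytes.
#'
#' @slot payload raw vector holding the packed codes.
#' @slot nSnps integer, number of genotypes encoded.
#'
#' @seealso [packCodes()], [unpackCodes()], [packedSize()]
#' @examples
#' pg <- packCodes(c(0L, 1L, 2L, 3L, 0L))
#' nSnps(pg)           # 5
#' length(payload(pg)) # 2 bytes
#' @export
setClass("PackedGenotypes",
    representation(payload = "raw", nSnps = "integer"))

setValidity("PackedGenotypes", function(object) {
    n <- object@nSnps
    if (length(n) != 1L || is.na(n) || n < 0L)
        return("nSnps must be a single non-negative integer")
    if (length(object@payload) != ceiling(n / 4))
        return(sprintf("payload must be ceiling(nSnps/4) = %d bytes, got %d",
                       ceiling(n / 4), length(object@payload)))
    TRUE
})

#' @rdname PackedGenotypes-class
#' @param x,object a \code{PackedGenotypes}
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname PackedGenotypes-class
#' @export
setMethod("nSnps", "PackedGenotypes", function(x) x@nSnps)

#' @rdname PackedGenotypes-class
#' @export
setGeneric("payload", function(x) standardGeneric("payload"))

#' @rdname PackedGenotypes-class
#' @export
setMethod("payload", "PackedGenotypes", function(x) x@payload)

setMethod("show", "PackedGenotypes", function(object) {
    cat(sprintf("PackedGenotypes: %d genotypes in %d bytes\n",
                object@nSnps, length(object@payload)))
    if (object@nSnps > 0) {
        k <- min(object@nSnps, 20L)
        codes <- unpackCodes(object, seq_len(k))
        cat("  codes: ", paste(codes, collapse = " "),
            if (object@nSnps > k) " ..." else "", "\n", sep = "")
    }
    invisible(NULL)
})

#' SNP genotype store
#'
#' Handle to an embedded SNP genotype database. The store keeps normalized
#' tables for panels, SNP maps, individuals, packed genotype records, SNP and
#' individual selection vectors, genotype sets, phenotypes and comments, all
#' rows timestamped. Data live in an environment (reference semantics, as for
#' a database connection); [saveStore()] serializes the whole store to its
#' single backing file and [initStore()] reopens it.
#'
#' @slot path character, backing file path, or \code{NA} for an in-memory
#'   store.
#' @slot env environment holding the tables.
#'
#' @seealso [initStore()], [addPanel()], [importData()], [exportSet()]
#' @export
setClass("GenotypeStore",
    representation(path = "character", env = "environment"))

.STORE_TABLES <- c("panels", "snps", "individuals", "genotype_records",
                   "snp_selections", "individual_selections", "genotype_sets",
                   "phenotypes", "comments")

setValidity("GenotypeStore", function(object) {
    missing <- setdiff(c(.STORE_TABLES, "payloads", "ss_bits", "is_keys",
                         "counters"), ls(object@env))
    if (length(missing))
        return(paste("store is missing tables:", paste(missing, collapse = ", ")))
    TRUE
})

setMethod("show", "GenotypeStore", function(object) {
    e <- object@env
    cat("GenotypeStore:",
        if (is.na(object@path)) "(in memory)" else object@path, "\n")
    cat(sprintf("  %d panel(s), %d individual(s), %d genotype record(s)\n",
                nrow(e$panels), nrow(e$individuals), nrow(e$genotype_records)))
    cat(sprintf("  %d genotype set(s), %d SNP / %d individual selection(s)\n",
                nrow(e$genotype_sets), nrow(e$snp_selections),
                nrow(e$individual_selections)))
    cat(sprintf("  genotype payload: %s bytes\n",
                format(sum(vapply(e$payloads, length, 0)), big.mark = ",")))
    invisible(NULL)
})

#' @rdname GenotypeStore-class
#' @param x,object a \code{GenotypeStore}
#' @export
setGeneric("storePath", function(x) standardGeneric("storePath"))

#' @rdname GenotypeStore-class
#' @export
setMethod("storePath", "GenotypeStore", function(x) x@path)
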