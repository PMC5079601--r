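#' Encode allele pairs as 2-bit genotype codes
#'
#' Maps observed biallelic genotypes onto the four 2-bit states used for
#' packed storage: 0 = homozygous for allele 1 of the SNP's coding, 1 =
#' heterozygous, 2 = no-call, 3 = homozygous for allele 2. Heterozygotes are
#' unordered: \code{(A,B)} and \code{(B,A)} both encode to 1. A genotype is a
#' no-call when either observed allele equals the missing token.
#'
#' All arguments are recycled to a common length, so a whole ped row can be
#' encoded in one call against per-SNP codings.
#'
#' @param obs1,obs2 character, the two observed allele labels per genotype.
#' @param allele1,allele2 character, the SNP coding (two distinct labels);
#'   \code{allele2} may be the placeholder \code{"0"} for a monomorphic SNP
#'   whose second allele has never been observed.
#' @param missing missing-genotype token (PLINK convention \code{"0"}).
#' @param snpNames optional SNP names used in error messages.
#' @return integer vector of codes in \code{0:3}.
#' @examples
#' encodeGenotype(c("A", "B", "0"), c("A", "A", "0"), "A", "B")  # 0 1 2
#' @export
encodeGenotype <- function(obs1, obs2, allele1, allele2, missing = "0",
                           snpNames = NULL) {
    n <- max(length(obs1), length(obs2), length(allele1), length(allele2))
    obs1 <- rep_len(as.character(obs1), n)
    obs2 <- rep_len(as.character(obs2), n)
    allele1 <- rep_len(as.character(allele1), n)
    allele2 <- rep_len(as.character(allele2), n)
    code <- rep.int(NA_integer_, n)
    miss <- obs1 == missing | obs2 == missing
    code[miss] <- 2L
    hom1 <- !miss & obs1 == allele1 & obs2 == allele1
    hom2 <- !miss & obs1 == allele2 & obs2 == allele2
    het <- !miss & ((obs1 == allele1 & obs2 == allele2) |
                    (obs1 == allele2 & obs2 == allele1))
    code[hom1] <- 0L
    code[het] <- 1L
    code[hom2] <- 3L
    bad <- is.na(code)
    if (any(bad)) {
        i <- which(bad)[1L]
        where <- if (!is.null(snpNames)) rep_len(snpNames, n)[i]
                 else sprintf("position %d", i)
        stop(sprintf(
            "allele mismatch at SNP %s: observed (%s,%s) not in coding (%s,%s)",
            where, obs1[i], obs2[i], allele1[i], allele2[i]), call. = FALSE)
    }
    code
}

#' Decode 2-bit genotype codes to allele pairs
#'
#' Inverse of [encodeGenotype()] up to heterozygote ordering: heterozygotes
#' are emitted in the canonical order (allele1, allele2) of the SNP's coding,
#' and code 2 yields the missing token twice.
#'
#' @param code integer codes in \code{0:3}; recycled with the codings.
#' @inheritParams encodeGenotype
#' @return character matrix with two columns (first and second allele).
#' @examples
#' decodeGenotype(c(3L, 2L), "A", "B")  # rows: B B / 0 0
#' @export
decodeGenotype <- function(code, allele1, allele2, missing = "0") {
    if (any(is.na(code)) || any(code < 0L | code > 3L))
        stop("invalid genotype code: codes must be in {0,1,2,3}", call. = FALSE)
    n <- max(length(code), length(allele1), length(allele2))
    code <- rep_len(as.integer(code), n)
    allele1 <- rep_len(as.character(allele1), n)
    allele2 <- rep_len(as.character(allele2), n)
    a <- character(n)
    b <- character(n)
    a[code == 0L] <- allele1[code == 0L]; b[code == 0L] <- allele1[code == 0L]
    a[code == 1L] <- allele1[code == 1L]; b[code == 1L] <- allele2[code == 1L]
    a[code == 2L] <- missing;             b[code == 2L] <- missing
    a[code == 3L] <- allele2[code == 3L]; b[code == 3L] <- allele2[code == 3L]
    cbind(a, b, deparse.level = 0)
}

#' Pack genotype codes into a 2-bit vector
#'
#' @param codes integer vector of genotype codes in \code{0:3} (empty
#'   allowed).
#' @return a [PackedGenotypes] whose payload occupies
#'   \code{ceiling(length(codes)/4)} bytes.
#' @examples
#' payload(packCodes(c(0L, 1L, 2L, 3L)))  # one byte, 0xe4
#' @export
packCodes <- function(codes) {
    codes <- as.integer(codes)
    new("PackedGenotypes", payload = cpp_pack(codes),
        nSnps = length(codes))
}

#' Unpack genotype codes from a 2-bit vector
#'
#' @param x a [PackedGenotypes].
#' @param positions optional integer vector of 1-based positions; codes are
#'   returned in ascending position order. Without it all \code{nSnps(x)}
#'   codes are returned in storage order.
#' @return integer vector of codes.
#' @export
unpackCodes <- function(x, positions = NULL) {
    stopifnot(is(x, "PackedGenotypes"))
    if (is.null(positions))
        return(cpp_unpack(x@payload, x@nSnps))
    positions <- sort(unique(as.integer(positions)))
    cpp_unpack_at(x@payload, positions - 1L, x@nSnps)
}

#' Storage-size arithmetic for packed genotypes
#'
#' \code{packedSize} gives the exact byte cost of a 2-bit packed record,
#' \code{ceiling(nSnps/4)}; \code{snpCapacity} is its inverse reading, the
#' number of genotypes a given number of bytes can hold (4 per byte);
#' \code{selectionBytes} sizes a 1-bit-per-SNP selection vector,
#' \code{ceiling(nSnps/8)}; \code{eavRowCount} gives the row count the
#' classical one-row-per-genotype schema would need for the same data
#' (\code{nSamples * nSnps}), for comparison.
#'
#' @param nSnps,nBytes,nSamples non-negative counts (may exceed
#'   \code{.Machine$integer.max}).
#' @return numeric count of bytes, genotypes or rows.
#' @examples
#' packedSize(800000)         # 200000 bytes = 1.6 million bits
#' snpCapacity(1e6)           # 4 million genotypes per (decimal) MB
#' selectionBytes(800000)     # 100000 bytes = 97.7 KiB
#' eavRowCount(96, 800000)    # 76.8 million rows for one 96-well plate
#' @export
packedSize <- function(nSnps) {
    nSnps <- as.numeric(nSnps)
    if (any(is.na(nSnps)) || any(nSnps < 0))
        stop("nSnps must be non-negative", call. = FALSE)
    ceiling(nSnps / 4)
}

#' @rdname packedSize
#' @export
snpCapacity <- function(nBytes) {
    nBytes <- as.numeric(nBytes)
    if (any(is.na(nBytes)) || any(nBytes < 0))
        stop("nBytes must be non-negative", call. = FALSE)
    4 * nBytes
}

#' @rdname packedSize
#' @export
selectionBytes <- function(nSnps) {
    nSnps <- as.numeric(nSnps)
    if (any(is.na(nSnps)) || any(nSnps < 0))
        stop("nSnps must be non-negative", call. = FALSE)
    ceiling(nSnps / 8)
}

#' @rdname packedSize
#' @export
eavRowCount <- function(nSamples, nSnps) {
    as.numeric(nSamples) * as.numeric(nSnps)
}

## ---- internal selection bit helpers (1 bit per SNP, LSB-first) ----

.packSelBits <- function(active) {
    # logical vector -> raw, padded with FALSE to a byte boundary
    n <- length(active)
    pad <- (8L - n %% 8L) %% 8L
    packBits(c(active, rep.int(FALSE, pad)), type = "raw")
}

.unpackSelBits <- function(bits, n) {
    as.logical(rawToBits(bits))[seq_len(n)]
}

.countSelBits <- function(bits, n) {
    sum(.unpackSelBits(bits, n))
}
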