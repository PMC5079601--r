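# Fixture builders and independent reference (oracle) implementations used
# across the suite. Oracles work on dense integer matrices and plain R so
# they share no code with the packed-vector paths they check.

# --- independent bit-level pack oracle: concatenate 2-bit fields LSB-first
oraclePack <- function(codes) {
    if (!length(codes)) return(raw(0))
    bits <- unlist(lapply(codes, function(c) as.integer(intToBits(c))[1:2]))
    pad <- (8 - length(bits) %% 8) %% 8
    packBits(as.logical(c(bits, rep(0L, pad))), type = "raw")
}

# --- dense-matrix fixture: codes is samples x SNPs in {0,1,2,3}
randomFixture <- function(nSamples = NULL, nSnps = NULL, nDup = NULL) {
    if (is.null(nSamples)) nSamples <- sample(5:50, 1)
    if (is.null(nSnps)) nSnps <- sample(10:200, 1)
    if (is.null(nDup)) nDup <- sample(0:min(3, floor(nSamples / 2)), 1)
    codes <- matrix(sample(0:3, nSamples * nSnps, replace = TRUE,
                           prob = c(.4, .25, .1, .25)),
                    nrow = nSamples)
    ids <- sprintf("ind%03d", seq_len(nSamples - nDup))
    if (nDup > 0) ids <- c(ids, sample(ids, nDup))
    chrom <- sort(sample(c("1", "2", "W"), nSnps, replace = TRUE))
    list(codes = codes, ids = ids, chrom = chrom)
}

# Build an in-memory store holding the fixture as one imported genotype set.
matrixStore <- function(fx, path = NA_character_) {
    store <- initStore(path)
    n <- ncol(fx$codes)
    addPanel(store, "p1", data.frame(
        chromosome = fx$chrom, snp_name = sprintf("s%04d", seq_len(n)),
        position_bp = seq_len(n) * 10, allele1 = "A", allele2 = "B",
        stringsAsFactors = FALSE))
    payloads <- lapply(seq_len(nrow(fx$codes)),
                       function(i) payload(packCodes(fx$codes[i, ])))
    gs <- importPacked(store, "p1", fx$ids, payloads, source = "fixture")
    list(store = store, gs = gs)
}

# Surviving rows (record keys, 1-based import order) and active SNP indices
# of a genotype set, read back through the reporting surface.
setSurvivors <- function(store, gs) {
    rep <- provenanceReport(store)
    row <- rep[rep$set == gs, ]
    list(rows = dumpSelection(store, row$individual_selection)$samples$record_key,
         snps = dumpSelection(store, row$snp_selection)$snps$vector_index)
}

# --- dense-matrix filter oracles -------------------------------------------
oracleDedupRows <- function(ids, rows) rows[!duplicated(ids[rows])]

oracleChromSnps <- function(chrom, active, exclude)
    setdiff(active, which(chrom %in% exclude))

oracleNocall <- function(codes, rows, active, sThr, snpThr) {
    miss <- codes[rows, active, drop = FALSE] == 2
    keepRows <- rows[rowMeans(miss) <= sThr]
    snpFreq <- colMeans(codes[keepRows, , drop = FALSE] == 2)
    list(rows = keepRows, snps = intersect(active, which(snpFreq <= snpThr)))
}

oracleMafSnps <- function(codes, rows, active, thr) {
    if (thr == 0) return(active)
    sub <- codes[rows, , drop = FALSE]
    keep <- vapply(seq_len(ncol(sub)), function(j) {
        g <- sub[, j]
        n0 <- sum(g == 0); n1 <- sum(g == 1); n3 <- sum(g == 3)
        called <- n0 + n1 + n3
        if (called == 0) return(FALSE)
        f <- (2 * n0 + n1) / (2 * called)
        min(f, 1 - f) >= thr
    }, logical(1))
    intersect(active, which(keep))
}

# Small handwritten map/ped text fixtures (Listing-3-like: 8 SNPs, 3 samples)
writeSmallMap <- function(path, coding = TRUE) {
    lines <- sprintf("%s\t%s\t0\t%d%s",
                     c("1", "1", "1", "2", "2", "2", "W", "W"),
                     paste0("snp", 1:8), (1:8) * 100,
                     if (coding) "\tA\tB" else "")
    writeLines(lines, path)
}

writeSmallPed <- function(path, genotypes, ids = c("23", "25", "35")) {
    # genotypes: character vector, one space-separated allele string per row
    writeLines(paste(ids, ids, 0, 0, 0, -9, genotypes), path)
}
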