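## Synthetic ped/map generation and an informational benchmark harness.
## Genotypes are drawn under Hardy-Weinberg equilibrium at per-SNP minor
## allele frequencies from a configurable sampler (default Uniform(0.05,
## 0.5)); calls go missing independently at a fixed no-call rate. All output
## is deterministic under a fixed seed.

.defaultMafSampler <- function(n) runif(n, 0.05, 0.5)

#' Generate a synthetic SNP map file
#'
#' Writes a 6-column map (chromosome, SNP name, cM 0, bp position, allele1,
#' allele2) with unique SNP names and strictly increasing positions within
#' each chromosome. With \code{coding = "AB"} every SNP is coded A/B; with
#' \code{"ACGT"} two distinct nucleotides are drawn per SNP.
#'
#' @param path output map path.
#' @param nSnps total SNP count; must equal \code{sum(chromosomes)}.
#' @param chromosomes named integer vector: SNPs per chromosome label
#'   (default: all on chromosome \code{"1"}).
#' @param coding \code{"AB"} or \code{"ACGT"}.
#' @param seed optional RNG seed for deterministic output.
#' @return the map data.frame (as [readMap()] would return), invisibly.
#' @export
genMap <- function(path, nSnps, chromosomes = NULL, coding = c("AB", "ACGT"),
                   seed = NULL) {
    coding <- match.arg(coding)
    if (!is.null(seed)) set.seed(seed)
    if (is.null(chromosomes)) chromosomes <- c("1" = nSnps)
    if (sum(chromosomes) != nSnps)
        stop(sprintf("chromosome SNP counts sum to %d, not nSnps = %d",
                     sum(chromosomes), nSnps), call. = FALSE)
    chrom <- rep(names(chromosomes), times = chromosomes)
    pos <- unlist(lapply(chromosomes, function(k)
        cumsum(sample.int(1000L, k, replace = TRUE))), use.names = FALSE)
    name <- sprintf("snp%0*d", max(6L, nchar(nSnps)), seq_len(nSnps))
    if (coding == "AB") {
        a1 <- rep.int("A", nSnps); a2 <- rep.int("B", nSnps)
    } else {
        nuc <- c("A", "C", "G", "T")
        a1 <- nuc[sample.int(4L, nSnps, replace = TRUE)]
        shift <- sample.int(3L, nSnps, replace = TRUE)
        a2 <- nuc[(match(a1, nuc) - 1L + shift) %% 4L + 1L]
    }
    writeLines(paste(chrom, name, 0L, pos, a1, a2, sep = "\t"), path)
    invisible(data.frame(chromosome = chrom, snp_name = name,
                         position_bp = as.numeric(pos), allele1 = a1,
                         allele2 = a2, vector_index = seq_len(nSnps),
                         stringsAsFactors = FALSE))
}

.genSampleIds <- function(nSamples, nDuplicateIds) {
    if (nDuplicateIds >= nSamples)
        stop("nDuplicateIds must be smaller than nSamples", call. = FALSE)
    nOrig <- nSamples - nDuplicateIds
    ids <- sprintf("S%0*d", max(5L, nchar(nSamples)), seq_len(nOrig))
    if (nDuplicateIds > 0)
        ids <- c(ids, sample(ids, nDuplicateIds))   # re-genotyped samples
    ids
}

#' Generate a synthetic PLINK ped file
#'
#' One row per sample with default leading columns (family = sample ID,
#' parents 0, sex 0, phenotype -9) and Hardy-Weinberg genotypes at per-SNP
#' minor allele frequencies drawn from \code{maf}. Each genotype is
#' independently a no-call with probability \code{nocallRate}. The last
#' \code{nDuplicateIds} rows re-use earlier sample IDs with freshly drawn
#' genotypes, emulating re-genotyped samples.
#'
#' @param path output ped path.
#' @param map map data.frame (from [genMap()] or [readMap()]); SNPs without
#'   an allele coding are generated as A/B.
#' @param nSamples number of ped rows.
#' @param maf per-SNP minor-allele-frequency sampler: a
#'   \code{function(n)} or a numeric vector recycled over SNPs. Default
#'   Uniform(0.05, 0.5).
#' @param nocallRate per-genotype missingness probability in \eqn{[0, 1]}.
#' @param nDuplicateIds number of rows that repeat an earlier sample ID.
#' @param seed optional RNG seed for deterministic output.
#' @return invisibly, a list with \code{sample_ids} and the realized
#'   \code{maf} vector.
#' @export
genPed <- function(path, map, nSamples, maf = .defaultMafSampler,
                   nocallRate = 0.01, nDuplicateIds = 0, seed = NULL) {
    if (nocallRate < 0 || nocallRate > 1)
        stop("nocallRate must be in [0, 1]", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(map)
    mafs <- if (is.function(maf)) maf(n) else rep_len(as.numeric(maf), n)
    if (any(mafs < 0 | mafs > 0.5))
        stop("minor allele frequencies must be in [0, 0.5]", call. = FALSE)
    ids <- .genSampleIds(nSamples, nDuplicateIds)
    a1 <- if (is.null(map$allele1) || anyNA(map$allele1)) rep.int("A", n)
          else map$allele1
    a2 <- if (is.null(map$allele2) || anyNA(map$allele2)) rep.int("B", n)
          else map$allele2
    lookup <- rbind(paste(a1, a1), paste(a1, a2), paste("0", "0"),
                    paste(a2, a2))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nSamples)) {
        codes <- cpp_unpack(cpp_sim_packed(mafs, nocallRate), n)
        writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                           lookup[cbind(codes + 1L, seq_len(n))]),
                         collapse = " "), con)
    }
    invisible(list(sample_ids = ids, maf = mafs))
}

#' Simulate and bulk-load genotype records for a stored panel
#'
#' Large-scale counterpart of [genPed()] + [importData()]: genotypes are
#' drawn with the same Hardy-Weinberg model but packed directly into 2-bit
#' payloads and loaded through [importPacked()], so panels of hundreds of
#' thousands of SNPs and thousands of samples never materialize as text.
#' Creates the usual full genotype set.
#'
#' @param store a [GenotypeStore-class].
#' @param panelName name of a previously imported panel.
#' @inheritParams genPed
#' @param comment optional comment on the created genotype set.
#' @return name of the new genotype set.
#' @export
importSimulated <- function(store, panelName, nSamples,
                            maf = .defaultMafSampler, nocallRate = 0.01,
                            nDuplicateIds = 0, comment = NA_character_,
                            seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    size <- .panelRow(store, panelName)$size
    mafs <- if (is.function(maf)) maf(size) else rep_len(as.numeric(maf), size)
    if (any(mafs < 0 | mafs > 0.5))
        stop("minor allele frequencies must be in [0, 0.5]", call. = FALSE)
    ids <- .genSampleIds(nSamples, nDuplicateIds)
    payloads <- vector("list", nSamples)
    for (i in seq_len(nSamples))
        payloads[[i]] <- cpp_sim_packed(mafs, nocallRate)
    importPacked(store, panelName, ids, payloads, comment = comment,
                 source = sprintf("simulated import (%d samples)", nSamples))
}

#' Informational import/export throughput benchmark
#'
#' For each panel size, simulates enough samples to reach
#' \code{totalSnpsPerBatch} genotypes, then times bulk import into an
#' in-memory store and PLINK export of the created set, repeated for
#' \code{batches} consecutive batches (the store keeps filling, as in
#' repeated deliveries from a genotyping service). Rates are reported, not
#' asserted — absolute throughput is hardware-dependent; only qualitative
#' scale relations are meaningful.
#'
#' @param panelSizes integer vector of panel sizes to test.
#' @param totalSnpsPerBatch total genotypes per batch (panel size times
#'   samples).
#' @param batches batches per panel size.
#' @param nocallRate per-genotype missingness for the simulated data.
#' @param export also time a PLINK export of each batch's set (skipping it
#'   keeps import-only benchmarks free of file I/O).
#' @return data.frame: \code{panel_size}, \code{batch}, \code{n_samples},
#'   \code{import_seconds}, \code{import_snps_per_sec},
#'   \code{export_seconds}, \code{export_snps_per_sec} (NA when
#'   \code{export = FALSE}). Empty input gives an empty table.
#' @export
benchmarkThroughput <- function(panelSizes, totalSnpsPerBatch, batches = 1L,
                                nocallRate = 0.01, export = TRUE) {
    out <- list()
    for (size in panelSizes) {
        nSamples <- max(1L, as.integer(round(totalSnpsPerBatch / size)))
        store <- initStore(NA)
        mapPath <- tempfile(fileext = ".map")
        genMap(mapPath, size)
        importPanel(store, mapPath, "bench")
        for (b in seq_len(batches)) {
            mafs <- .defaultMafSampler(size)
            # pre-generate unpacked codes; the timed import covers the
            # per-SNP packing plus the database insert, as a text import does
            codes <- lapply(seq_len(nSamples), function(i)
                cpp_unpack(cpp_sim_packed(mafs, nocallRate), size))
            ids <- sprintf("b%d_s%d", b, seq_len(nSamples))
            t1 <- proc.time()[["elapsed"]]
            payloads <- lapply(codes, cpp_pack)
            gs <- importPacked(store, "bench", ids, payloads,
                               source = sprintf("benchmark batch %d", b))
            t2 <- proc.time()[["elapsed"]]
            expSec <- NA_real_
            if (export) {
                prefix <- tempfile()
                exportSet(store, gs, "plink", prefix)
                expSec <- proc.time()[["elapsed"]] - t2
                unlink(paste0(prefix, c(".ped", ".map")))
            }
            nG <- as.numeric(size) * nSamples
            out[[length(out) + 1L]] <- data.frame(
                panel_size = size, batch = b, n_samples = nSamples,
                import_seconds = t2 - t1,
                import_snps_per_sec = nG / max(t2 - t1, 1e-9),
                export_seconds = expSec,
                export_snps_per_sec = nG / max(expSec, 1e-9))
        }
        unlink(mapPath)
    }
    if (!length(out))
        return(data.frame(panel_size = integer(), batch = integer(),
                          n_samples = integer(), import_seconds = numeric(),
                          import_snps_per_sec = numeric(),
                          export_seconds = numeric(),
                          export_snps_per_sec = numeric()))
    do.call(rbind, out)
}
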