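# The worked example used throughout: 8-SNP panel, samples 23/25/35, subset
# keeping SNPs 3, 4, 6, 8 for all three samples.
smallSubsetStore <- function(d) {
    writeSmallMap(file.path(d, "p1.map"))
    writeSmallPed(file.path(d, "p1.ped"), c(
        "A A B B A B 0 0 A A B B A B A A",
        "A A A A A A A A A A A A A A A B",
        "B B B B B B B B 0 0 B B B B B B"))
    st <- initStore(NA)
    importPanel(st, file.path(d, "p1.map"), "panel 1")
    gs <- importData(st, file.path(d, "p1.ped"), file.path(d, "p1.map"),
                     "panel 1")
    list(store = st, gs = gs)
}

test_that("list-based subsets intersect parent selections", {
    d <- withr::local_tempdir()
    s <- smallSubsetStore(d)
    flags <- setNames(rep(FALSE, 8), paste0("snp", 1:8))
    flags[c("snp3", "snp4", "snp6", "snp8")] <- TRUE
    gs3 <- subsetByLists(s$store, s$gs, samples = c("23", "25", "35"),
                         snpFlags = flags)
    sur <- setSurvivors(s$store, gs3)
    expect_identical(sur$snps, c(3L, 4L, 6L, 8L))
    expect_length(sur$rows, 3L)
    # keep-all lists reproduce the parent selections bit for bit
    all8 <- setNames(rep(TRUE, 8), paste0("snp", 1:8))
    attr(all8, "dialect") <- "names"
    gsAll <- subsetByLists(s$store, s$gs, samples = c("23", "25", "35"),
                           snpFlags = all8)
    repAll <- provenanceReport(s$store)
    newSs <- repAll$snp_selection[repAll$set == gsAll]
    expect_identical(s$store@env$ss_bits[[newSs]],
                     s$store@env$ss_bits[["ss_001"]])
    expect_identical(s$store@env$is_keys[[repAll$individual_selection[
        repAll$set == gsAll]]], s$store@env$is_keys[["is_001"]])
    # unknown identifiers are named; empty results refused
    expect_error(subsetByLists(s$store, s$gs, samples = c("23", "77")),
                 "not in gs_001: 77")
    bad <- setNames(TRUE, "snpX")
    expect_error(subsetByLists(s$store, s$gs, snpFlags = bad),
                 "not on panel")
    expect_error(subsetByLists(s$store, s$gs), "at least one")
    validateStore(s$store)
})

test_that("the two SNP-list dialects differ on unlisted SNPs", {
    d <- withr::local_tempdir()
    s <- smallSubsetStore(d)
    part <- setNames(c(TRUE, FALSE), c("snp1", "snp2"))
    attr(part, "dialect") <- "flags"
    gsF <- subsetByLists(s$store, s$gs, snpFlags = part)
    expect_identical(setSurvivors(s$store, gsF)$snps,
                     c(1L, 3L, 4L, 5L, 6L, 7L, 8L))   # only snp2 switched off
    part2 <- setNames(c(TRUE, TRUE), c("snp1", "snp2"))
    attr(part2, "dialect") <- "names"
    gsN <- subsetByLists(s$store, s$gs, snpFlags = part2)
    expect_identical(setSurvivors(s$store, gsN)$snps, c(1L, 2L))
})

test_that("duplicate removal keeps one earliest record per sample", {
    fx <- randomFixture(10, 20, 3)
    ms <- matrixStore(fx)
    gs2 <- removeDuplicates(ms$store, ms$gs)
    sur <- setSurvivors(ms$store, gs2)
    expect_identical(sur$rows, oracleDedupRows(fx$ids, seq_along(fx$ids)))
    # SNP selection is inherited by reference, not copied
    rep <- provenanceReport(ms$store)
    expect_identical(rep$snp_selection[rep$set == gs2],
                     rep$snp_selection[rep$set == ms$gs])
    # no duplicates: same keys under a new name
    fx0 <- randomFixture(6, 10, 0)
    ms0 <- matrixStore(fx0)
    gs0 <- removeDuplicates(ms0$store, ms0$gs)
    expect_identical(setSurvivors(ms0$store, gs0)$rows, seq_len(6))
    rep0 <- provenanceReport(ms0$store)
    newIs <- rep0$individual_selection[rep0$set == gs0]
    expect_false(newIs == "is_001")
    expect_identical(ms0$store@env$is_keys[[newIs]],
                     ms0$store@env$is_keys[["is_001"]])
    # a sample genotyped three times keeps exactly one record
    fx3 <- randomFixture(6, 10, 0)
    fx3$ids <- c("a", "a", "a", "b", "c", "d")
    ms3 <- matrixStore(fx3)
    gs3 <- removeDuplicates(ms3$store, ms3$gs)
    expect_identical(setSurvivors(ms3$store, gs3)$rows, c(1L, 4L, 5L, 6L))
})

test_that("chromosome exclusion zeroes exactly the targeted SNPs", {
    fx <- randomFixture(8, 40, 0)
    ms <- matrixStore(fx)
    gs2 <- expect_silent(filterChromosomes(ms$store, ms$gs, "W"))
    expect_identical(setSurvivors(ms$store, gs2)$snps,
                     oracleChromSnps(fx$chrom, seq_len(40), "W"))
    expect_warning(filterChromosomes(ms$store, gs2, "MT"),
                   "label\\(s\\) not on panel")
    expect_error(
        suppressWarnings(filterChromosomes(ms$store, ms$gs,
                                           c("1", "2", "W", "MT"))),
        "all chromosomes excluded")
    validateStore(ms$store)
})

test_that("no-call filtering drops samples first, then SNPs", {
    # sample with 1 no-call of 8 active SNPs exceeds a 0.05 threshold
    codes <- rbind(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 2L),
                   rep(0L, 8), rep(1L, 8), rep(3L, 8))
    fx <- list(codes = codes, ids = paste0("i", 1:4), chrom = rep("1", 8))
    ms <- matrixStore(fx)
    gs2 <- filterNocall(ms$store, ms$gs, sampleThreshold = 0.05,
                        snpThreshold = 0.5)
    expect_identical(setSurvivors(ms$store, gs2)$rows, c(2L, 3L, 4L))
    # thresholds of 1 remove nothing
    gs3 <- filterNocall(ms$store, ms$gs, 1, 1)
    sur <- setSurvivors(ms$store, gs3)
    expect_length(sur$rows, 4L)
    expect_length(sur$snps, 8L)
    # SNP stage uses frequencies over the retained samples only:
    # snp8 is missing in 1/4 samples but 0/3 after the sample stage
    gs4 <- filterNocall(ms$store, ms$gs, sampleThreshold = 0.05,
                        snpThreshold = 0.1)
    expect_length(setSurvivors(ms$store, gs4)$snps, 8L)
    expect_error(filterNocall(ms$store, ms$gs), "at least one")
    expect_error(filterNocall(ms$store, ms$gs, 1.5, NULL), "\\[0, 1\\]")
})

test_that("MAF filtering uses called-allele frequencies", {
    # codes 0,0,0,1 over 4 samples: minor allele frequency 1/8 = 0.125
    codes <- cbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L), c(2L, 2L, 2L, 2L),
                   c(1L, 1L, 3L, 3L))
    fx <- list(codes = codes, ids = paste0("i", 1:4), chrom = rep("1", 4))
    ms <- matrixStore(fx)
    stats <- snpSetStats(ms$store, ms$gs)
    # col4: allele1 count 2*0+2 = 2 of 8 called alleles -> MAF 0.25
    expect_equal(stats$maf, c(0.125, 0, NA, 0.25))
    gs2 <- filterMaf(ms$store, ms$gs, 0.03)
    expect_identical(setSurvivors(ms$store, gs2)$snps, c(1L, 4L))
    gs3 <- filterMaf(ms$store, ms$gs, 0.2)
    expect_identical(setSurvivors(ms$store, gs3)$snps, 4L)
    # threshold 0 removes nothing, monomorphic and all-missing included
    gs4 <- filterMaf(ms$store, ms$gs, 0)
    expect_length(setSurvivors(ms$store, gs4)$snps, 4L)
    expect_error(filterMaf(ms$store, ms$gs, 0.6), "\\[0, 0.5\\]")
    expect_error(filterMaf(ms$store, gs3, 0.51), "\\[0, 0.5\\]")
})

test_that("MAF filters chain: 0.03 then 0.05 equals 0.05 directly", {
    set.seed(606)
    for (rep in 1:5) {
        fx <- randomFixture(30, 80, 0)
        ms <- matrixStore(fx)
        a <- filterMaf(ms$store, filterMaf(ms$store, ms$gs, 0.03), 0.05)
        b <- filterMaf(ms$store, ms$gs, 0.05)
        expect_identical(setSurvivors(ms$store, a)$snps,
                         setSurvivors(ms$store, b)$snps)
    }
})

test_that("counts never increase along provenance chains", {
    set.seed(707)
    fx <- randomFixture(25, 60, 4)
    ms <- matrixStore(fx)
    g <- ms$gs
    g <- removeDuplicates(ms$store, g)
    g <- filterChromosomes(ms$store, g, "W")
    g <- filterNocall(ms$store, g, 0.3, 0.3)
    g <- filterMaf(ms$store, g, 0.05)
    rep <- provenanceReport(ms$store)
    expect_equal(nrow(rep), 5L)
    expect_true(all(diff(rep$n_samples) <= 0))
    expect_true(all(diff(rep$n_active_snps) <= 0))
    expect_true(all(diff(rep$depth) >= 0))
    # sources name the operation and the parent set
    expect_match(rep$source_is[2], "remove duplicates on gs_001")
    expect_match(rep$source_ss[3], "exclude chromosomes W on gs_002")
    expect_match(rep$source_ss[5], "MAF threshold 0.05 on gs_004")
    # parent chains terminate at the import-created selections
    expect_identical(
        s <- ms$store@env$snp_selections$parent[
            match(rep$snp_selection[3], ms$store@env$snp_selections$name)],
        "ss_001")
    validateStore(ms$store)
})

test_that("empty store yields an empty provenance report", {
    st <- initStore(NA)
    rep <- provenanceReport(st)
    expect_equal(nrow(rep), 0L)
    expect_output(print(rep), "no genotype sets")
})
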