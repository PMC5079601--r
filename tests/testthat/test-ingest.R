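test_that("map-first ordering is enforced and import creates the full set", {
    d <- withr::local_tempdir()
    writeSmallMap(file.path(d, "p1.map"))
    writeSmallPed(file.path(d, "p1.ped"), c(
        "A A B B A B 0 0 A A B B A B A A",
        "A A A A A A A A A A A A A A A A",
        "B B B B B B B B 0 0 B B B B B B"))
    st <- initStore(NA)
    expect_error(importData(st, file.path(d, "p1.ped"), file.path(d, "p1.map"),
                            "panel 1"), "unknown panel")
    importPanel(st, file.path(d, "p1.map"), "panel 1")
    gs <- importData(st, file.path(d, "p1.ped"), file.path(d, "p1.map"),
                     "panel 1", comment = "batch 1")
    expect_identical(gs, "gs_001")
    rep <- provenanceReport(st)
    expect_identical(rep$individual_selection, "is_001")
    expect_identical(rep$snp_selection, "ss_001")
    expect_equal(rep$n_samples, 3L)
    expect_equal(rep$n_active_snps, 8L)
    expect_identical(rep$comment, "batch 1")
    validateStore(st)
})

test_that("two panels import independently with their own selections", {
    d <- withr::local_tempdir()
    writeSmallMap(file.path(d, "p1.map"))
    writeLines(sprintf("2\tq%d\t0\t%d\tA\tB", 1:4, 1:4), file.path(d, "p2.map"))
    writeSmallPed(file.path(d, "p1.ped"),
                  rep("A A A B B B 0 0 A A A A B B A B", 3))
    writeSmallPed(file.path(d, "p2.ped"), rep("A A A B B B 0 0", 2),
                  ids = c("23", "99"))
    st <- initStore(NA)
    importPanel(st, file.path(d, "p1.map"), "panel 1")
    importPanel(st, file.path(d, "p2.map"), "panel 2")
    gs1 <- importData(st, file.path(d, "p1.ped"), file.path(d, "p1.map"),
                      "panel 1")
    gs2 <- importData(st, file.path(d, "p2.ped"), file.path(d, "p2.map"),
                      "panel 2")
    rep <- provenanceReport(st)
    expect_equal(rep$n_active_snps[rep$set == gs1], 8L)
    expect_equal(rep$n_active_snps[rep$set == gs2], 4L)
    # sample 23 appears on both panels: one individual, not a duplicate
    expect_equal(sum(st@env$individuals$sample_id == "23"), 1L)
    expect_equal(nrow(findDuplicateSamples(st, "panel 1")), 0L)
    expect_equal(nrow(findDuplicateSamples(st, "panel 2")), 0L)
})

test_that("the stored map must match the import map exactly", {
    d <- withr::local_tempdir()
    writeSmallMap(file.path(d, "p1.map"))
    writeSmallPed(file.path(d, "p1.ped"),
                  rep("A A A A A A A A A A A A A A A A", 3))
    st <- initStore(NA)
    importPanel(st, file.path(d, "p1.map"), "panel 1")
    other <- readLines(file.path(d, "p1.map"))
    other[3] <- sub("snp3", "snpX", other[3])
    writeLines(other, file.path(d, "other.map"))
    expect_error(importData(st, file.path(d, "p1.ped"),
                            file.path(d, "other.map"), "panel 1"),
                 "does not match stored panel")
    # cM differences are tolerated
    cmdiff <- sub("\t0\t", "\t12.5\t", readLines(file.path(d, "p1.map")))
    writeLines(cmdiff, file.path(d, "cm.map"))
    expect_silent(importData(st, file.path(d, "p1.ped"),
                             file.path(d, "cm.map"), "panel 1"))
})

test_that("failed imports leave no partial state", {
    d <- withr::local_tempdir()
    writeSmallMap(file.path(d, "p1.map"))
    st <- initStore(NA)
    importPanel(st, file.path(d, "p1.map"), "panel 1")
    writeSmallPed(file.path(d, "bad.ped"), c(
        "A A A A A A A A A A A A A A A A",
        "A A A A T T A A A A A A A A A A"))   # T not in the A/B coding
    expect_error(importData(st, file.path(d, "bad.ped"),
                            file.path(d, "p1.map"), "panel 1"),
                 "allele mismatch.*snp3")
    expect_equal(nrow(st@env$genotype_records), 0L)
    expect_equal(nrow(st@env$individuals), 0L)
    expect_equal(nrow(st@env$genotype_sets), 0L)
    writeLines(character(), file.path(d, "empty.ped"))
    expect_error(importData(st, file.path(d, "empty.ped"),
                            file.path(d, "p1.map"), "panel 1"),
                 "no data rows")
    validateStore(st)
})

test_that("allele codings are inferred from uncoded maps and persisted", {
    d <- withr::local_tempdir()
    writeSmallMap(file.path(d, "p1.map"), coding = FALSE)
    # snp1: G first (hom), then T -> (G,T); snp2: het first, lexicographic
    # tie-break -> (C,G); snp3 monomorphic A; snp4..8 A/B-style mixes
    writeSmallPed(file.path(d, "p1.ped"), c(
        "G G G C A A T T C C A G T C A A",
        "T G C C A A T A C A A A C C A C",
        "G G C G A A A A C C G G T T C C"))
    st <- initStore(NA)
    importPanel(st, file.path(d, "p1.map"), "panel")
    gs <- importData(st, file.path(d, "p1.ped"), file.path(d, "p1.map"),
                     "panel")
    snps <- st@env$snps
    expect_identical(snps$allele1[1], "G")   # first observed
    expect_identical(snps$allele2[1], "T")
    expect_identical(snps$allele1[2], "C")   # het-first tie: lexicographic
    expect_identical(snps$allele2[2], "G")
    expect_identical(snps$allele1[3], "A")   # monomorphic: placeholder second
    expect_identical(snps$allele2[3], "0")
    expect_true(all(snps$coding_set))
    # exports are stable under the persisted coding
    exportSet(st, gs, "plink", file.path(d, "o1"))
    exportSet(st, gs, "plink", file.path(d, "o2"))
    expect_identical(readLines(file.path(d, "o1.ped")),
                     readLines(file.path(d, "o2.ped")))
    # a later import may not silently reassign a monomorphic coding
    writeSmallPed(file.path(d, "p2.ped"),
                  "G G C C T T T T C C A A C C A A", ids = "99")
    expect_error(importData(st, file.path(d, "p2.ped"), file.path(d, "p1.map"),
                            "panel"), "allele mismatch.*snp3")
})

test_that("bulk packed import equals the ped text path", {
    d <- withr::local_tempdir()
    set.seed(505)
    map <- genMap(file.path(d, "m.map"), 30, seed = 11)
    genPed(file.path(d, "m.ped"), map, 12, nocallRate = 0.05, seed = 12)
    stText <- initStore(NA)
    importPanel(stText, file.path(d, "m.map"), "p")
    gsText <- importData(stText, file.path(d, "m.ped"), file.path(d, "m.map"),
                         "p")
    # re-pack the same rows through the bulk path
    rows <- readPed(file.path(d, "m.ped"), 30)
    codes <- matrix(encodeGenotype(as.vector(t(rows$a1)),
                                   as.vector(t(rows$a2)),
                                   rep(map$allele1, 12),
                                   rep(map$allele2, 12)),
                    nrow = 12, byrow = TRUE)
    stBulk <- initStore(NA)
    importPanel(stBulk, file.path(d, "m.map"), "p")
    gsBulk <- importPacked(stBulk, "p", rows$ped$individual_id,
                           lapply(seq_len(12),
                                  function(i) payload(packCodes(codes[i, ]))))
    expect_identical(stBulk@env$payloads, stText@env$payloads)
    expect_identical(stBulk@env$individuals$sample_id,
                     stText@env$individuals$sample_id)
    exportSet(stBulk, gsBulk, "0125", file.path(d, "b"))
    exportSet(stText, gsText, "0125", file.path(d, "t"))
    expect_identical(readLines(file.path(d, "b.0125")),
                     readLines(file.path(d, "t.0125")))
})
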