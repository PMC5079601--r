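test_that("all four map dialects parse to the same records", {
    d <- withr::local_tempdir()
    base <- data.frame(chromosome = c("1", "1", "W"),
                       snp_name = c("rs1", "rs2", "rs3"),
                       position_bp = c(100, 200, 50))
    p3 <- file.path(d, "m3.map")
    writeLines(paste(base$chromosome, base$snp_name, base$position_bp), p3)
    p4 <- file.path(d, "m4.map")
    writeLines(paste(base$chromosome, base$snp_name, 0, base$position_bp), p4)
    p4c <- file.path(d, "m4c.map")
    writeLines(paste(base$chromosome, base$snp_name, base$position_bp, "AB"),
               p4c)
    p6 <- file.path(d, "m6.map")
    writeLines(paste(base$chromosome, base$snp_name, 0, base$position_bp,
                     "A", "B"), p6)
    m3 <- readMap(p3); m4 <- readMap(p4); m4c <- readMap(p4c); m6 <- readMap(p6)
    for (m in list(m3, m4, m4c, m6)) {
        expect_identical(m$snp_name, base$snp_name)
        expect_identical(m$position_bp, base$position_bp)
        expect_identical(m$vector_index, 1:3)
    }
    expect_true(all(is.na(m3$allele1)))
    expect_true(all(is.na(m4$allele1)))
    expect_identical(m4c$allele1, rep("A", 3))
    expect_identical(m6$allele2, rep("B", 3))
    # 5-column variants: PLINK + "GC" token and 3-column + "A T"
    p5a <- file.path(d, "m5a.map")
    writeLines(paste(base$chromosome, base$snp_name, 0, base$position_bp,
                     "GC"), p5a)
    expect_identical(readMap(p5a)$allele1, rep("G", 3))
    p5b <- file.path(d, "m5b.map")
    writeLines(paste(base$chromosome, base$snp_name, base$position_bp,
                     "A", "T"), p5b)
    expect_identical(readMap(p5b)$allele2, rep("T", 3))
})

test_that("malformed maps are rejected with line context", {
    d <- withr::local_tempdir()
    p <- file.path(d, "bad.map")
    writeLines(c("1 rs1 0 100", "1 rs2 200"), p)
    expect_error(readMap(p), "inconsistent column count.*line 2")
    writeLines(c("1 rs1 0 1e2.5"), p)
    expect_error(readMap(p), "non-integer bp")
    writeLines(c("1 rs1 0 100", "1 rs1 0 200"), p)
    expect_error(readMap(p), "duplicate SNP name")
    writeLines(c("1 rs1 100 A A"), p)
    expect_error(readMap(p), "alleles must differ")
})

test_that("ped reading validates field counts and passes missing through", {
    d <- withr::local_tempdir()
    ped <- file.path(d, "t.ped")
    writeSmallPed(ped, c(
        "A A B B A B 0 0 A A B B A B A A",
        "A A A A A A A A A A A A A A A A",
        "B B B B B B B B 0 0 B B B B B B"))
    rows <- readPed(ped, 8)
    expect_equal(nrow(rows$ped), 3L)
    expect_identical(rows$ped$individual_id, c("23", "25", "35"))
    expect_identical(rows$a1[1, 4], "0")
    expect_identical(dim(rows$a1), c(3L, 8L))
    writeLines("23 23 0 0 0 -9 A A B B", ped)   # 2 pairs on an 8-SNP panel
    expect_error(readPed(ped, 8), "line 1: expected 22 fields")
})

test_that("ped/map writing round-trips token-for-token", {
    d <- withr::local_tempdir()
    set.seed(404)
    snps <- data.frame(chromosome = c("1", "1", "2", "W"),
                       snp_name = paste0("rs", 1:4),
                       position_bp = c(10, 20, 30, 40),
                       allele1 = c("A", "G", "T", "A"),
                       allele2 = c("B", "C", "A", "C"),
                       coding_set = TRUE)
    codes <- matrix(sample(0:3, 12, replace = TRUE), nrow = 3)
    ped <- data.frame(family_id = c("f1", "f2", "f3"),
                      individual_id = c("i1", "i2", "i3"),
                      paternal_id = "0", maternal_id = "0", sex = c("1", "2", "0"),
                      phenotype = "-9")
    writePedMap(ped, codes, snps, file.path(d, "out"))
    back <- readPed(file.path(d, "out.ped"), 4)
    recoded <- encodeGenotype(as.vector(t(back$a1)), as.vector(t(back$a2)),
                              rep(snps$allele1, 3), rep(snps$allele2, 3))
    expect_identical(matrix(recoded, nrow = 3, byrow = TRUE), codes)
    m <- readMap(file.path(d, "out.map"))
    expect_identical(m$snp_name, snps$snp_name)
    expect_identical(m$position_bp, snps$position_bp)
    expect_true(all(is.na(m$allele1)))   # exported maps are plain 4-column
    expect_error(writePedMap(ped[0, ], codes[0, , drop = FALSE], snps,
                             file.path(d, "e")), "empty sample selection")
})

test_that("0125 output maps codes 0,1,3,2 to digits 0,1,2,5", {
    d <- withr::local_tempdir()
    snps <- data.frame(chromosome = "1", snp_name = paste0("rs", 1:4),
                       position_bp = 1:4, allele1 = "A", allele2 = "B")
    write0125("s1", matrix(c(0L, 1L, 3L, 2L), nrow = 1), snps,
              file.path(d, "x"))
    expect_identical(readLines(file.path(d, "x.0125")), "s1\t0125")
    write0125("s2", matrix(rep(2L, 4), nrow = 1), snps, file.path(d, "y"))
    expect_identical(readLines(file.path(d, "y.0125")), "s2\t5555")
    # equivalence with ped output under a re-encoding oracle
    set.seed(405)
    codes <- matrix(sample(0:3, 20, replace = TRUE), nrow = 5)
    ids <- paste0("s", 1:5)
    ped <- data.frame(family_id = ids, individual_id = ids, paternal_id = "0",
                      maternal_id = "0", sex = "0", phenotype = "-9")
    writePedMap(ped, codes, snps, file.path(d, "p"))
    write0125(ids, codes, snps, file.path(d, "q"))
    back <- readPed(file.path(d, "p.ped"), 4)
    recoded <- matrix(encodeGenotype(as.vector(t(back$a1)),
                                     as.vector(t(back$a2)),
                                     rep(snps$allele1, 5),
                                     rep(snps$allele2, 5)),
                      nrow = 5, byrow = TRUE)
    digits <- vapply(strsplit(sub(".*\t", "", readLines(file.path(d, "q.0125"))),
                              ""), function(ch)
        paste(ch, collapse = ""), character(1))
    want <- apply(recoded, 1, function(g)
        paste(c("0", "1", "5", "2")[g + 1], collapse = ""))
    expect_identical(digits, unname(want))
})

test_that("selection-list files support both SNP dialects", {
    d <- withr::local_tempdir()
    sl <- file.path(d, "samples.txt")
    writeLines(c("23", "25", "35"), sl)
    keep <- readSelectionLists(sampleListPath = sl)
    expect_identical(keep$samples, c("23", "25", "35"))
    expect_null(keep$snpFlags)
    # two-column dialect: 0 marks exclusion
    fl <- file.path(d, "snps.txt")
    writeLines(c("rs1 1", "rs2 0", "rs3 1"), fl)
    keep <- readSelectionLists(snpListPath = fl)
    expect_identical(as.vector(keep$snpFlags), c(TRUE, FALSE, TRUE))
    expect_identical(attr(keep$snpFlags, "dialect"), "flags")
    # one-column dialect: named SNPs are kept
    writeLines(c("rs2", "rs4"), fl)
    keep <- readSelectionLists(snpListPath = fl)
    expect_identical(names(keep$snpFlags), c("rs2", "rs4"))
    expect_identical(attr(keep$snpFlags, "dialect"), "names")
    writeLines(character(), sl)
    expect_error(readSelectionLists(sampleListPath = sl), "empty sample")
    writeLines(c("rs1 2"), fl)
    expect_error(readSelectionLists(snpListPath = fl), "malformed")
    expect_error(readSelectionLists(), "at least one")
})
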