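test_that("clinical reader applies the AMH exclusion rule literally", {
    f <- tempfile(fileext = ".csv")
    writeLines(c(
        "process_id,patient_id,age,bmi,amh,fsh,lh,e2,pcos,mii_count,prev_mii",
        "p1,w1,34,23,2.5,7,6,17,0,5,",
        "p2,w2,30,21,16.2,7,6,17,0,9,4",
        "p3,w3,38,25,1.1,7,6,17,1,2,1"), f)
    co <- suppressMessages(readClinicalTable(f, applyExclusions = TRUE))
    expect_equal(ncol(co), 2L)
    expect_equal(metadata(co)$exclusions$dropped, 1L)
    ## optional-field contract: empty cell stays missing, never imputed
    expect_true(is.na(clinicalData(co)$prev_mii[1]))
    expect_equal(clinicalData(co)$prev_mii[2], 1)
    ## without exclusions all three rows survive
    co2 <- suppressMessages(readClinicalTable(f, applyExclusions = FALSE))
    expect_equal(ncol(co2), 3L)
})

test_that("clinical reader errors name the offending column and row", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("process_id,patient_id,age,bmi,amh,fsh,lh,e2,pcos",
                 "p1,w1,34,23,2.5,7,6,17,0"), f)
    expect_error(suppressMessages(readClinicalTable(f)), "mii_count")
    f2 <- tempfile(fileext = ".csv")
    writeLines(c(
        "process_id,patient_id,age,bmi,amh,fsh,lh,e2,pcos,mii_count",
        "p1,w1,34,23,abc,7,6,17,0,5"), f2)
    expect_error(suppressMessages(readClinicalTable(f2)), "amh")
    expect_error(suppressMessages(readClinicalTable(f2)), "row 1")
})

test_that("VCF genotypes map GT codes to dosages with missing propagated", {
    panel <- toyPanel(3)
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "s1", "s2", sep = "\t"),
        paste("1", "1000", "tv01", "A", "G", ".", "PASS", ".", "GT",
              "0/1", "1/1", sep = "\t"),
        paste("1", "2000", "tv02", "A", "G", ".", "PASS", ".", "GT",
              "./.", "1/0", sep = "\t")), f)
    geno <- suppressWarnings(
        readGenotypesVcf(f, panel, c(p1 = "s1", p2 = "s2")))
    expect_equal(geno$dosage["tv01", ], c(p1 = 1L, p2 = 2L))
    expect_equal(unname(geno$dosage["tv02", "p1"]), NA_integer_)
    expect_equal(unname(geno$dosage["tv02", "p2"]), 1L)
    ## panel variant absent from the file -> all-missing row with warning
    expect_warning(readGenotypesVcf(f, panel, c(p1 = "s1")), "tv03")
    ## incomplete sample map -> mapping error listing the sample
    expect_error(
        suppressWarnings(readGenotypesVcf(f, panel, c(p1 = "nosuch"))),
        "nosuch")
})

test_that("multi-allelic records are rejected with their position", {
    panel <- toyPanel(1)
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", "s1", sep = "\t"),
        paste("1", "1000", "tv01", "A", "G,T", ".", "PASS", ".", "GT",
              "0/1", sep = "\t")), f)
    expect_error(readGenotypesVcf(f, panel, c(p1 = "s1")), "1000")
})

test_that("cohort round-trips through CSV + VCF + sample map", {
    co <- generateCohort(generatorConfig(nPatients = 12, seed = 5))
    d <- tempdir()
    writeCohort(co, file.path(d, "c.csv"), file.path(d, "g.vcf"),
                file.path(d, "m.json"))
    co2 <- suppressMessages(
        loadCohort(file.path(d, "c.csv"), file.path(d, "g.vcf"),
                   variantPanel(co), file.path(d, "m.json")))
    a <- as.data.frame(clinicalData(co))
    b <- as.data.frame(clinicalData(co2))
    for (nm in intersect(names(a), names(b)))
        expect_equal(as.vector(a[[nm]]), as.vector(b[[nm]]),
                     info = nm, tolerance = 1e-12)
    expect_identical(unname(dosageMatrix(co)), unname(dosageMatrix(co2)))
    expect_equal(variantPanel(co), variantPanel(co2))
})

test_that("MII bins are disjoint, exhaustive and match the worked example", {
    b <- binMiiCounts(c(0, 2, 3, 5, 9, 12))
    expect_equal(unname(b$sizes), c(2L, 1L, 1L, 1L, 1L))
    ## half-open upper edge of the fourth bin
    expect_equal(as.character(binMiiCounts(11)$assignment), "(7,11]")
    expect_equal(as.character(binMiiCounts(12)$assignment), ">11")
    ## MII = 2 falls in the first bin (the only exhaustive closure)
    expect_equal(as.character(binMiiCounts(2)$assignment), "<=2")
    expect_error(binMiiCounts(c(3, -1)), "nonnegative")
    ## partition completeness on arbitrary nonnegative integer vectors
    set.seed(1)
    for (i in 1:20) {
        v <- rpois(sample(1:200, 1), lambda = sample(1:15, 1))
        expect_equal(sum(binMiiCounts(v)$sizes), length(v))
    }
})

test_that("alt-presence view is idempotent and monotone in dosage", {
    ## 3 variants (rows) x 2 processes (columns)
    dos <- matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 3)
    co <- tinyCohort(dos, mii = c(4L, 7L), patients = c("w1", "w2"))
    ap <- altPresence(co)   # processes x variants
    expect_true(all(ap %in% c(0L, 1L) | is.na(ap)))
    expect_identical(altPresence(ap), ap)        # idempotent
    expect_true(is.na(ap["p2", "tv01"]))         # missing propagated
    ## monotone: dosage 1 and 2 both map to presence, 0 to absence
    expect_equal(unname(ap["p1", ]), c(0L, 1L, 1L))
    expect_equal(unname(ap["p2", c("tv02", "tv03")]), c(1L, 0L))
})

test_that("a synthetic study-sized table reproduces the group-2 structure", {
    co <- generateCohort(generatorConfig(seed = 17))
    expect_equal(ncol(co), 516L)
    expect_equal(length(unique(patientIds(co))), 264L)
    sizes <- binMiiCounts(co)$sizes
    expect_equal(sum(sizes), 516L)
    expect_true(all(sizes > 0))
})
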