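test_that("contingency table counts carriers per MII group by hand", {
    dos <- matrix(c(1L, 0L, 2L, 0L,
                    0L, 1L, 1L, 0L), nrow = 2, byrow = TRUE)
    co <- tinyCohort(dos, mii = c(1L, 2L, 12L, 13L))
    part <- binMiiCounts(co)
    tab <- suppressWarnings(
        buildContingency(co, part, c("tv01", "tv02")))
    expect_equal(tab["tv01", "<=2"], 1L)
    expect_equal(tab["tv01", ">11"], 1L)
    expect_equal(tab["tv02", "<=2"], 1L)
    expect_equal(tab["tv02", ">11"], 1L)
    expect_equal(sum(tab), 4L)
    ## missing genotypes are excluded from their cell
    dos2 <- dos; dos2[1, 1] <- NA
    co2 <- tinyCohort(dos2, mii = c(1L, 2L, 12L, 13L))
    tab2 <- suppressWarnings(
        buildContingency(co2, binMiiCounts(co2), c("tv01", "tv02")))
    expect_equal(tab2["tv01", "<=2"], 0L)
    ## all-reference variant -> flagged zero row
    dos3 <- rbind(dos, 0L)
    co3 <- tinyCohort(dos3, mii = c(1L, 2L, 12L, 13L))
    tab3 <- suppressWarnings(
        buildContingency(co3, binMiiCounts(co3),
                         c("tv01", "tv02", "tv03")))
    expect_equal(attr(tab3, "zero_rows"), "tv03")
})

test_that("CA total inertia equals Pearson chi-square over n", {
    ## independence: rows proportional to column margins
    indep <- outer(c(10, 20, 30), c(1, 2, 1))
    expect_equal(fitCA(indep)@totalInertia, 0, tolerance = 1e-12)
    ## 2x2 diagonal table: chi-square / n = 1 exactly
    diag2 <- matrix(c(10, 0, 0, 10), 2, 2,
                    dimnames = list(c("a", "b"), c("g1", "g2")))
    ca <- suppressWarnings(fitCA(diag2))
    expect_equal(ca@totalInertia, 1, tolerance = 1e-12)
    ## random tables against the chi-square oracle
    set.seed(33)
    for (i in 1:10) {
        tab <- matrix(rpois(20, 8) + 1, 4, 5)
        chi <- suppressWarnings(chisq.test(tab)$statistic)
        ca <- fitCA(tab)
        expect_equal(ca@totalInertia, unname(chi) / sum(tab),
                     tolerance = 1e-9)
        expect_lte(sum(ca@inertiaProp[1:2]), 1 + 1e-12)
    }
})

test_that("row coordinates reproduce chi-square distances", {
    set.seed(4)
    tab <- matrix(rpois(24, 10) + 1, 4, 6)
    ca <- fitCA(tab)
    P <- tab / sum(tab)
    prof <- P / rowSums(P)
    cmass <- colSums(P)
    chiD <- as.matrix(dist(prof %*% diag(1 / sqrt(cmass))))
    coordD <- as.matrix(dist(ca@rowCoord))
    expect_equal(coordD, chiD, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("CA agrees with an independent implementation", {
    skip_if_not_installed("MASS")
    set.seed(12)
    tab <- matrix(rpois(15, 12) + 1, 3, 5)
    ca <- fitCA(tab)
    mc <- MASS::corresp(tab, nf = 2)
    ## canonical correlations = singular values
    expect_equal(ca@singularValues[1:2], unname(mc$cor[1:2]),
                 tolerance = 1e-8)
    ## principal coordinates agree up to per-axis sign
    for (d in 1:2) {
        a <- ca@rowCoord[, d]
        b <- mc$rscore[, d] * mc$cor[d]
        expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
        expect_equal(unname(sort(abs(a))), unname(sort(abs(b))),
                     tolerance = 1e-8)
    }
})

test_that("proximity selection picks nearest variants with stable ties", {
    rc <- rbind(v1 = c(1, 0), v2 = c(0.1, 0.1), v3 = c(-1, 0.5),
                zz = c(0.1, -0.1))
    cc <- rbind(`<=2` = c(-1, 0), `>11` = c(0.1, 0.1))
    ca <- methods::new("CAResult", rowCoord = rc, colCoord = cc,
                       singularValues = c(0.5, 0.3),
                       totalInertia = 0.34, inertiaProp = c(0.7, 0.3))
    f <- selectProximalVariants(ca, ">11", k = 1)
    expect_equal(featureVariants(f), "v2")   # coincident point ranks first
    ## tie between v1-style symmetric points broken lexicographically
    rc2 <- rbind(b = c(1, 0), a = c(-0.8, 0.6), c = c(0, 0))
    ca2 <- methods::new("CAResult", rowCoord = rc2, colCoord = cc,
                        singularValues = c(0.5, 0.3),
                        totalInertia = 0.34, inertiaProp = c(0.7, 0.3))
    d <- attr(selectProximalVariants(ca2, ">11", k = 3), "distances")
    expect_equal(d$variant_id[1], "c")
    ## joint rotation/reflection leaves the selection unchanged
    th <- 0.83
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    ca3 <- methods::new("CAResult", rowCoord = rc %*% R,
                        colCoord = cc %*% R,
                        singularValues = c(0.5, 0.3),
                        totalInertia = 0.34, inertiaProp = c(0.7, 0.3))
    expect_equal(featureVariants(selectProximalVariants(ca3, ">11", k = 2)),
                 featureVariants(selectProximalVariants(ca, ">11", k = 2)))
    ## k larger than available -> all returned with warning
    expect_warning(selectProximalVariants(ca, ">11", k = 10), "available")
})

test_that("count feature evaluation sums alt-presence with NA propagation", {
    ap <- rbind(p1 = c(1L, 1L, 0L), p2 = c(0L, 0L, 0L),
                p3 = c(1L, 1L, 1L), p4 = c(NA, 1L, 1L))
    colnames(ap) <- c("v1", "v2", "v3")
    f <- methods::new("CountFeature", name = "f",
                      variantIds = c("v1", "v2", "v3"))
    v <- evaluateFeature(f, ap)
    expect_equal(unname(v), c(2L, 0L, 3L, NA))
    fBad <- methods::new("CountFeature", name = "f", variantIds = "v9")
    expect_error(evaluateFeature(fBad, ap), "v9")
})
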