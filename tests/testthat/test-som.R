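test_that("a map trained on one repeated vector collapses onto it", {
    v <- c(1L, 0L, 1L, 1L, 0L)
    ap <- matrix(rep(v, 40), 40, 5, byrow = TRUE,
                 dimnames = list(NULL, paste0("v", 1:5)))
    ## 2x2 grid: every node sits inside the initial neighborhood radius,
    ## so the whole map must collapse onto the single input vector
    som <- suppressWarnings(
        trainSOM(ap, somConfig(gridDim = c(2L, 2L), iterations = 4000,
                               seed = 2)))
    expect_lt(som@qe, 1e-3)
    expect_true(all(abs(t(som@weights) - v) < 0.05))
    ## on the default 6x6 grid the BMU still converges (QE ~ 0) even
    ## though far-away nodes need not
    som6 <- suppressWarnings(
        trainSOM(ap, somConfig(iterations = 4000, seed = 2)))
    expect_lt(som6@qe, 1e-3)
})

test_that("the BMU really is the nearest node and QE its mean distance", {
    set.seed(5)
    ap <- matrix(rbinom(60 * 8, 1, 0.4), 60, 8,
                 dimnames = list(NULL, paste0("v", 1:8)))
    som <- trainSOM(ap, somConfig(iterations = 3000, seed = 6))
    expect_equal(nrow(som@weights), 36L)  # 6 x 6 grid
    dists <- matrix(NA_real_, 60, 36)
    for (i in 1:60) for (j in 1:36)
        dists[i, j] <- sum(abs(ap[i, ] - som@weights[j, ]))
    ## BMU distance <= distance to every node, every observation
    expect_true(all(dists[cbind(1:60, som@bmu)] <= dists + 1e-12))
    ## oracle recomputation of the quantization error
    expect_equal(som@qe, mean(apply(dists, 1, min)), tolerance = 1e-12)
})

test_that("SOM training is reproducible under a fixed seed", {
    set.seed(9)
    ap <- matrix(rbinom(50 * 6, 1, 0.3), 50, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
    a <- trainSOM(ap, somConfig(iterations = 2000, seed = 42))
    b <- trainSOM(ap, somConfig(iterations = 2000, seed = 42))
    expect_identical(a@weights, b@weights)
    expect_identical(a@qe, b@qe)
})

test_that("node enrichment applies the share rule and ranks variants", {
    ## construct a model by hand: 20 observations, node 1 holds the first 10
    ap <- rbind(matrix(rep(c(1L, 0L), each = 10), 10, 2),
                matrix(rep(c(0L, 1L), each = 10), 10, 2))
    colnames(ap) <- c("vHot", "vCold")
    W <- matrix(0.5, 4, 2, dimnames = list(NULL, colnames(ap)))
    model <- methods::new("SomModel", weights = W, gridDim = c(2L, 2L),
                          bmu = rep(c(1L, 3L), each = 10), qe = 0,
                          config = list())
    mii <- c(rep(13L, 8), rep(1L, 2), rep(1L, 10))
    part <- binMiiCounts(mii)
    enr <- nodeEnrichment(model, part, ap, topM = 2,
                          enrichmentRatio = 2, minNodeSize = 10)
    n1 <- enr[[1]]
    ## node share 0.8 of ">11" vs population 0.4 -> enriched at ratio 2
    expect_equal(unname(n1$groupShares[">11"]), 0.8)
    expect_true(">11" %in% n1$enrichedFor)
    ## percentage difference: 1.0 in node vs 0.5 population
    cv <- n1$characteristicVariants
    expect_equal(cv$variant_id[1], "vHot")
    expect_equal(cv$pct_diff[1], 0.5)
    ## node 3 holds only low-MII processes and is not enriched for ">11"
    n2 <- enr[[2]]
    expect_false(">11" %in% n2$enrichedFor)
})

test_that("subset search enumerates 2^n - 1 subsets and honours the stub", {
    cands <- LETTERS[1:10]
    calls <- 0
    res <- subsetSearch(cands, function(s) {
        calls <<- calls + 1
        if (identical(sort(s), c("A", "C"))) 0.5 else 1 + length(s) / 100
    })
    expect_equal(calls, 1023L)              # 2^10 - 1
    expect_equal(nrow(res$trace), 1023L)
    expect_equal(res$best, c("A", "C"))
    ## tie-break: equal scores go to the smaller subset, then lexicographic
    res2 <- subsetSearch(c("B", "A"), function(s) 1)
    expect_equal(res2$best, "A")
    ## monotone callback: RMSE falls with every planted member included
    planted <- c("A", "B")
    res3 <- subsetSearch(LETTERS[1:6], function(s)
        2 - length(intersect(s, planted)) + 0.01 * length(s))
    expect_equal(sort(res3$best), planted)
    expect_error(subsetSearch(LETTERS[1:16], identity), "15")
})

test_that("standardized features freeze population moments exactly", {
    ap <- matrix(c(0L, 0L, 1L, 0L, 1L, 1L), 3, 2,
                 dimnames = list(NULL, c("v1", "v2")))
    ## raw counts {0, 1, 2} equally frequent -> z-scores +/- 1.2247
    f <- buildStandardizedFeature(c("v1", "v2"), ap)
    v <- evaluateFeature(f, ap)
    expect_equal(unname(v), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
    ## population mean 0 / SD 1 on the defining cohort (1/n convention)
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
    ## frozen constants are reused verbatim on new data
    apNew <- matrix(c(1L, 1L), 1, 2,
                    dimnames = list(NULL, c("v1", "v2")))
    expect_equal(unname(evaluateFeature(f, apNew)),
                 (2 - f@center) / f@scale)
    ## degenerate population -> error
    apConst <- matrix(1L, 4, 2, dimnames = list(NULL, c("v1", "v2")))
    expect_error(buildStandardizedFeature(c("v1", "v2"), apConst),
                 "zero variance")
    ## a 6-member feature stays within [0, 6] raw range
    set.seed(2)
    ap6 <- matrix(rbinom(120, 1, 0.5), 20, 6,
                  dimnames = list(NULL, paste0("v", 1:6)))
    f6 <- buildStandardizedFeature(paste0("v", 1:6), ap6)
    raw <- evaluateFeature(methods::new("CountFeature", name = "r",
                                        variantIds = paste0("v", 1:6)), ap6)
    expect_true(all(raw >= 0 & raw <= 6))
    expect_lt(abs(mean(evaluateFeature(f6, ap6))), 1e-9)
})
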