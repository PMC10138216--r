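test_that("error metrics follow their closed forms", {
    m <- errorMetrics(c(3, 3), c(2, 4))
    expect_equal(m$rmse, 1)
    expect_equal(m$mae, 1)
    expect_equal(m$mape, 0.375)
    perfect <- errorMetrics(c(2, 4), c(2, 4))
    expect_equal(unlist(perfect[c("rmse", "mae", "mape")]),
                 c(rmse = 0, mae = 0, mape = 0))
    ## zero actuals are excluded from MAPE only
    z <- errorMetrics(c(1, 3), c(0, 4))
    expect_equal(z$mape, 0.25)
    expect_equal(attr(z, "mapeExcluded"), 1L)
    allZero <- errorMetrics(c(1, 1), c(0, 0))
    expect_true(is.na(allZero$mape))
    expect_true(attr(allZero, "mapeUndefined"))
    expect_error(errorMetrics(numeric(0), numeric(0)), "empty")
    ## RMSE >= MAE on arbitrary inputs
    set.seed(3)
    for (i in 1:10) {
        p <- rnorm(50, 6, 3); a <- rpois(50, 6)
        mm <- errorMetrics(p, a)
        expect_gte(mm$rmse, mm$mae)
    }
})

test_that("the trivial benchmark RMSE is the population SD", {
    b <- trivialBaseline(c(2, 4, 6))
    expect_equal(b$rmse, sqrt(8 / 3))
    expect_equal(attr(b, "prediction"), 4)
    expect_equal(trivialBaseline(rep(5, 10))$rmse, 0)
})

test_that("grouped cross-validation never splits a patient across folds", {
    co <- generateCohort(generatorConfig(nPatients = 80, seed = 15))
    cd <- as.data.frame(clinicalData(co))
    fit <- trainGbmCv(cd[, c("amh", "age")], unname(miiCounts(co)),
                      patientIds(co), testModelConfig(seed = 2))
    byPatient <- tapply(fit$folds, patientIds(co),
                        function(f) length(unique(f)))
    expect_true(all(byPatient == 1L))
    ## determinism: identical seed reproduces folds and metrics exactly
    fit2 <- trainGbmCv(cd[, c("amh", "age")], unname(miiCounts(co)),
                       patientIds(co), testModelConfig(seed = 2))
    expect_identical(fit$folds, fit2$folds)
    expect_identical(fit$metrics, fit2$metrics)
    expect_error(trainGbmCv(cd[1:6, c("amh", "age")],
                            unname(miiCounts(co))[1:6],
                            patientIds(co)[1:6],
                            modelConfig(seed = 1)),
                 "fold")
})

test_that("a strong single predictor crushes the trivial baseline", {
    set.seed(6)
    n <- 400
    x <- rnorm(n, 6, 3)
    y <- pmax(0, round(x + rnorm(n, 0, 0.4)))
    fit <- trainGbmCv(data.frame(x = x), y, paste0("w", seq_len(n)),
                      testModelConfig(seed = 8, nTrees = 100))
    expect_lt(fit$metrics$rmse, 0.4 * trivialBaseline(y)$rmse)
})

test_that("pure-noise features stay near the trivial baseline", {
    rel <- vapply(1:5, function(s) {
        set.seed(s)
        n <- 300
        X <- data.frame(a = rnorm(n), b = rnorm(n), c = rbinom(n, 1, .4))
        y <- rpois(n, 6)
        fit <- trainGbmCv(X, y, paste0("w", seq_len(n)),
                          testModelConfig(seed = s))
        fit$metrics$rmse / trivialBaseline(y)$rmse
    }, numeric(1))
    ## within a few percent of the benchmark, never dramatically below
    expect_true(all(rel > 0.95))
    expect_true(all(rel < 1.25))
})

test_that("forward selection accepts planted signal and resists noise", {
    hits <- 0; noiseAccepted <- 0
    for (s in 1:3) {
        set.seed(s * 7)
        n <- 500
        planted <- rnorm(n, 6, 3)
        cand <- data.frame(planted = planted, n1 = rnorm(n), n2 = rnorm(n),
                           n3 = rbinom(n, 1, 0.3))
        y <- pmax(0, round(planted + rnorm(n, 0, 1)))
        sel <- forwardSelect(cand, y, paste0("w", seq_len(n)),
                             testModelConfig(seed = s))
        hits <- hits + ("planted" %in% sel$selected)
        noiseAccepted <- noiseAccepted +
            length(setdiff(sel$selected, "planted"))
        ## selection soundness: every accepted step strictly reduced RMSE
        acc <- sel$trace[sel$trace$accepted, ]
        expect_true(all(acc$rmse_with < acc$rmse_before))
    }
    expect_equal(hits, 3L)
    expect_lte(noiseAccepted, 2L)
    ## empty candidate list -> baseline-only outcome
    empty <- forwardSelect(data.frame(), rpois(20, 5), paste0("w", 1:20),
                           testModelConfig(seed = 1))
    expect_equal(empty$selected, character(0))
})

test_that("the combination search enumerates 2^n - 1 subsets", {
    set.seed(9)
    n <- 150
    clin <- data.frame(amh = rnorm(n, 3, 1))
    y <- rpois(n, 5)
    ## five genetic features -> 31 subsets; seven -> the familiar 127
    gen5 <- as.data.frame(matrix(rbinom(n * 5, 1, .5), n, 5))
    colnames(gen5) <- paste0("g", 1:5)
    res5 <- geneticCombinationSearch(gen5, clin, y, paste0("w", seq_len(n)),
                                     testModelConfig(seed = 3, nTrees = 10))
    expect_equal(nrow(res5$table), 2^5 - 1)
    gen7 <- as.data.frame(matrix(rbinom(n * 7, 1, .5), n, 7))
    colnames(gen7) <- paste0("g", 1:7)
    res7 <- geneticCombinationSearch(gen7, clin, y, paste0("w", seq_len(n)),
                                     testModelConfig(seed = 3, nTrees = 10))
    expect_equal(nrow(res7$table), 127L)
    expect_true(all(lengths(strsplit(res7$table$subset, "\\+")) ==
                    res7$table$size))
    one <- geneticCombinationSearch(gen5[, 1, drop = FALSE], clin, y,
                                    paste0("w", seq_len(n)),
                                    testModelConfig(seed = 3, nTrees = 10))
    expect_equal(nrow(one$table), 1L)
})

test_that("constant features carry zero Shapley importance", {
    set.seed(4)
    n <- 200
    X <- data.frame(x = rnorm(n), const = rep(1, n))
    y <- pmax(0, round(8 + X$x * 2 + rnorm(n, 0, .2)))
    fit <- trainGbmCv(X, y, paste0("w", seq_len(n)),
                      testModelConfig(seed = 5))
    imp <- shapImportance(fit, X)
    expect_equal(imp$feature[1], "x")
    expect_equal(imp$mean_abs_shap[imp$feature == "const"], 0)
})

test_that("per-patient explanations are additive and schema-checked", {
    set.seed(10)
    n <- 250
    X <- data.frame(amh = rlnorm(n, 1, .6), age = round(rnorm(n, 34, 4)))
    y <- pmax(0, round(2 * X$amh + rnorm(n)))
    fit <- trainGbmCv(X, y, paste0("w", seq_len(n)),
                      testModelConfig(seed = 11))
    for (i in c(1, 7, 42)) {
        ex <- explainPatient(fit, X[i, ])
        expect_lt(abs(ex$baseValue + sum(ex$contributions) -
                      ex$prediction), 1e-6)
    }
    ## missing feature values are allowed and still additive
    row <- X[3, ]; row$age <- NA
    ex <- explainPatient(fit, row)
    expect_lt(abs(ex$baseValue + sum(ex$contributions) - ex$prediction),
              1e-6)
    expect_error(explainPatient(fit, data.frame(bogus = 1)), "schema")
})

test_that("a constant model yields an all-zero decomposition", {
    n <- 80
    X <- data.frame(x = rnorm(n))
    y <- rep(4, n)
    fit <- trainGbmCv(X, y, paste0("w", seq_len(n)),
                      testModelConfig(seed = 12))
    ex <- explainPatient(fit, X[1, , drop = FALSE])
    expect_equal(unname(ex$contributions), 0, tolerance = 1e-8)
    expect_equal(ex$prediction, 4, tolerance = 1e-6)
})
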