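## Gradient-boosted prediction of the MII count: grouped cross-validation,
## error metrics, greedy clinical forward selection, the exhaustive
## genetic-feature combination search, and per-patient explanation.

#' Model configuration
#'
#' Boosting hyperparameters: 100 gradient-boosted decision trees with five
#' leaves each and a maximum depth of 16, squared-error (l2) loss, five
#' cross-validation folds grouped by patient. The learning rate (0.1) and
#' other knobs beyond those five are package defaults, surfaced here.
#'
#' @param nTrees,maxLeaves,maxDepth,learningRate boosting parameters.
#' @param nFolds cross-validation folds (grouped by patient).
#' @param seed mandatory seed (fold assignment; training is deterministic
#'   single-threaded).
#' @return config list for [trainGbmCv()].
#' @export
modelConfig <- function(nTrees = 100, maxLeaves = 5, maxDepth = 16,
                        learningRate = 0.1, nFolds = 5, seed) {
    if (missing(seed)) stop("modelConfig needs an explicit seed")
    stopifnot(nTrees >= 1, nFolds >= 2)
    list(nTrees = as.integer(nTrees), maxLeaves = as.integer(maxLeaves),
         maxDepth = as.integer(maxDepth), learningRate = learningRate,
         nFolds = as.integer(nFolds), seed = as.integer(seed))
}

.xgbParams <- function(config) {
    list(objective = "reg:squarederror", eta = config$learningRate,
         max_depth = config$maxDepth, tree_method = "hist",
         grow_policy = "lossguide", max_leaves = config$maxLeaves,
         nthread = 1, seed = config$seed)
}

#' Prediction error metrics
#'
#' RMSE (root mean squared error), MAE (mean absolute error) and MAPE (mean
#' absolute percentage error, as a fraction). MAPE is computed over
#' observations with a nonzero actual count only; the number of excluded
#' zero-outcome rows is attached as attribute \code{"mapeExcluded"}. When
#' every actual is zero, MAPE is NA (flagged).
#'
#' @param predicted,actual equal-length numeric vectors; actuals must be
#'   nonnegative.
#' @return named list \code{rmse}, \code{mae}, \code{mape}.
#' @examples
#' errorMetrics(c(3, 3), c(2, 4))  # RMSE 1, MAE 1, MAPE 0.375
#' @export
errorMetrics <- function(predicted, actual) {
    if (!length(predicted)) stop("empty prediction vector")
    stopifnot(length(predicted) == length(actual), all(actual >= 0))
    err <- predicted - actual
    nz <- actual > 0
    mape <- if (any(nz)) mean(abs(err[nz]) / actual[nz]) else NA_real_
    out <- list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), mape = mape)
    attr(out, "mapeExcluded") <- sum(!nz)
    if (!any(nz)) attr(out, "mapeUndefined") <- TRUE
    class(out) <- "cvMetrics"
    out
}

#' @export
print.cvMetrics <- function(x, ...) {
    cat(sprintf("RMSE %.3f  MAE %.3f  MAPE %s oocytes\n", x$rmse, x$mae,
                if (is.na(x$mape)) "NA" else sprintf("%.3f", x$mape)))
    invisible(x)
}

#' Trivial mean-predictor benchmark
#'
#' Predicts the population mean MII count for every process. Its RMSE equals
#' the population standard deviation (1/n denominator); every fitted model
#' must beat this benchmark to be considered useful.
#'
#' @param x a [StimCohort-class] or a numeric outcome vector (>= 2 values).
#' @return \code{cvMetrics} list, with the constant prediction attached as
#'   attribute \code{"prediction"}.
#' @export
trivialBaseline <- function(x) {
    y <- if (methods::is(x, "StimCohort")) unname(miiCounts(x)) else x
    if (length(y) < 2) stop("need at least 2 processes")
    out <- errorMetrics(rep(mean(y), length(y)), y)
    attr(out, "prediction") <- mean(y)
    out
}

## patient-grouped fold assignment, deterministic given seed
.groupedFolds <- function(patientIds, nFolds, seed) {
    patients <- unique(patientIds)
    perm <- withr::with_seed(seed, sample(patients))
    pf <- stats::setNames(rep_len(seq_len(nFolds), length(perm)), perm)
    folds <- unname(pf[patientIds])
    sizes <- tabulate(folds, nFolds)
    if (any(sizes < 5))
        stop("fold with fewer than 5 observations; reduce nFolds or ",
             "enlarge the cohort")
    folds
}

#' Train the boosted model with grouped cross-validation
#'
#' Five-fold (by default) cross-validation with folds grouped by patient, so
#' that no patient contributes processes to more than one fold; metrics are
#' computed on the pooled out-of-fold predictions, and a final model is
#' refit on all data for explanation. Missing feature values are consumed
#' natively by the boosted trees. Identical seed (and data) reproduces the
#' fold assignment and the metrics exactly.
#'
#' @param features data.frame or matrix of model features (NA allowed;
#'   logicals are coerced to numeric).
#' @param outcome MII counts.
#' @param patients patient id per row (grouping for folds).
#' @param config a [modelConfig()].
#' @return list with \code{metrics} (pooled out-of-fold), \code{foldMetrics},
#'   \code{predictions} (out-of-fold), \code{folds}, \code{model} (refit on
#'   all data), \code{featureNames}, \code{config}.
#' @export
trainGbmCv <- function(features, outcome, patients, config) {
    X <- .featureMatrix(features)
    stopifnot(nrow(X) == length(outcome), length(patients) == length(outcome))
    folds <- .groupedFolds(patients, config$nFolds, config$seed)
    params <- .xgbParams(config)
    pred <- rep(NA_real_, length(outcome))
    foldMetrics <- vector("list", config$nFolds)
    for (f in seq_len(config$nFolds)) {
        inTrain <- folds != f
        dtr <- xgboost::xgb.DMatrix(X[inTrain, , drop = FALSE],
                                    label = outcome[inTrain], missing = NA,
                                    nthread = 1)
        fit <- xgboost::xgb.train(params, dtr, nrounds = config$nTrees,
                                  verbose = 0)
        pred[!inTrain] <- predict(fit, xgboost::xgb.DMatrix(
            X[!inTrain, , drop = FALSE], missing = NA, nthread = 1))
        foldMetrics[[f]] <- errorMetrics(pred[!inTrain], outcome[!inTrain])
    }
    dAll <- xgboost::xgb.DMatrix(X, label = outcome, missing = NA,
                                 nthread = 1)
    final <- xgboost::xgb.train(params, dAll, nrounds = config$nTrees,
                                verbose = 0)
    list(metrics = errorMetrics(pred, outcome), foldMetrics = foldMetrics,
         predictions = pred, folds = folds, model = final,
         featureNames = colnames(X), config = config)
}

.featureMatrix <- function(features) {
    df <- as.data.frame(features)
    for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
    X <- as.matrix(df)
    if (is.null(colnames(X))) stop("features must be named")
    X
}

#' Greedy forward selection of clinical features
#'
#' Candidates are ordered by decreasing absolute Pearson correlation with
#' the outcome (pairwise-complete), then added one at a time; a candidate is
#' kept iff the cross-validated RMSE (identical patient-grouped folds at
#' every step) strictly decreases. The trivial mean predictor is the
#' starting benchmark.
#'
#' @param candidates data.frame of candidate feature columns.
#' @param outcome,patients as in [trainGbmCv()].
#' @param config a [modelConfig()].
#' @return list with \code{selected} (character), \code{trace} (data.frame
#'   with candidate, univariate r, RMSE before/with, accepted flag) and
#'   \code{metrics} of the final selected model (the baseline metrics when
#'   nothing is accepted).
#' @export
forwardSelect <- function(candidates, outcome, patients, config) {
    base <- trivialBaseline(outcome)
    if (ncol(as.data.frame(candidates)) == 0)
        return(list(selected = character(0),
                    trace = data.frame(), metrics = base))
    df <- as.data.frame(candidates)
    rs <- vapply(df, function(v)
        suppressWarnings(stats::cor(as.numeric(v), outcome,
                                    use = "pairwise.complete.obs")),
        numeric(1))
    rs[is.na(rs)] <- 0
    ord <- order(-abs(rs))
    selected <- character(0)
    bestRmse <- base$rmse
    bestMetrics <- base
    rows <- list()
    for (i in ord) {
        cand <- colnames(df)[i]
        fit <- trainGbmCv(df[, c(selected, cand), drop = FALSE], outcome,
                          patients, config)
        accept <- fit$metrics$rmse < bestRmse
        rows[[length(rows) + 1L]] <-
            data.frame(candidate = cand, pearson_r = rs[i],
                       rmse_before = bestRmse, rmse_with = fit$metrics$rmse,
                       accepted = accept)
        if (accept) {
            selected <- c(selected, cand)
            bestRmse <- fit$metrics$rmse
            bestMetrics <- fit$metrics
        }
    }
    list(selected = selected, trace = do.call(rbind, rows),
         metrics = bestMetrics)
}

#' Exhaustive combination search over genetic features
#'
#' Appends every non-empty subset of the genetic feature columns to the
#' fixed clinical feature set, retrains with identical folds, and returns
#' the subset minimizing the cross-validated RMSE (ties: smaller subset,
#' then lexicographic). With n genetic features the score table has
#' 2^n - 1 rows.
#'
#' @param genetic data.frame of genetic feature columns (1-7 columns).
#' @param clinical data.frame of the selected clinical features.
#' @param outcome,patients,config as in [trainGbmCv()].
#' @return list with \code{best} (character vector), \code{bestMetrics},
#'   \code{clinicalMetrics} (same folds, clinical features only) and
#'   \code{table} (all subsets with their RMSE).
#' @export
geneticCombinationSearch <- function(genetic, clinical, outcome, patients,
                                     config) {
    gdf <- as.data.frame(genetic)
    stopifnot(ncol(gdf) >= 1, ncol(gdf) <= 7)
    clinicalMetrics <- if (ncol(as.data.frame(clinical)) == 0)
        trivialBaseline(outcome)  # empty clinical set: mean predictor
    else trainGbmCv(clinical, outcome, patients, config)$metrics
    res <- subsetSearch(colnames(gdf), function(sub) {
        trainGbmCv(cbind(as.data.frame(clinical), gdf[, sub, drop = FALSE]),
                   outcome, patients, config)$metrics$rmse
    })
    bestFit <- trainGbmCv(cbind(as.data.frame(clinical),
                                gdf[, res$best, drop = FALSE]),
                          outcome, patients, config)
    tab <- res$trace
    names(tab)[names(tab) == "score"] <- "cv_rmse"
    list(best = res$best, bestMetrics = bestFit$metrics,
         clinicalMetrics = clinicalMetrics, table = tab,
         bestFit = bestFit)
}

#' Global feature importance by mean absolute Shapley value
#'
#' Ranks the model's features by the mean absolute TreeSHAP contribution
#' over the supplied observations (double-precision implementation, see
#' [treeShap()]); the per-observation contribution matrix is attached for
#' beeswarm-style displays.
#'
#' @param fit result of [trainGbmCv()] (or an \code{xgb.Booster} plus
#'   feature matrix).
#' @param features the feature table to explain (defaults semantics: must
#'   match the model schema).
#' @return data.frame \code{feature, mean_abs_shap} sorted decreasing, with
#'   attribute \code{"contributions"}.
#' @export
shapImportance <- function(fit, features) {
    model <- if (inherits(fit, "xgb.Booster")) fit else fit$model
    X <- .featureMatrix(features)
    fn <- if (inherits(fit, "xgb.Booster")) colnames(X) else fit$featureNames
    if (!identical(colnames(X), fn))
        stop("feature table does not match the model schema")
    phi <- treeShap(model, X)
    contrib <- phi[, seq_len(ncol(X)), drop = FALSE]
    out <- data.frame(feature = colnames(X),
                      mean_abs_shap = colMeans(abs(contrib)))
    out <- out[order(-out$mean_abs_shap, out$feature), ]
    rownames(out) <- NULL
    attr(out, "contributions") <- phi
    out
}

#' Explain one patient's prediction
#'
#' Additive Shapley decomposition of a single prediction: base value
#' (expected prediction) plus one contribution per feature reconstructs
#' f(x); the reconstruction is verified internally to 1e-6.
#'
#' @param fit result of [trainGbmCv()].
#' @param featureRow single-row data.frame (or named vector) matching the
#'   model schema; missing values allowed.
#' @return list with \code{prediction}, \code{baseValue},
#'   \code{contributions} (named numeric) and \code{waterfall} (data.frame
#'   ordered by decreasing absolute contribution).
#' @export
explainPatient <- function(fit, featureRow) {
    if (is.vector(featureRow)) featureRow <- as.data.frame(as.list(featureRow))
    X <- .featureMatrix(featureRow)
    if (!identical(colnames(X), fit$featureNames))
        stop("feature row does not match the model schema: expected ",
             paste(fit$featureNames, collapse = ", "))
    phi <- treeShap(fit$model, X)
    p <- length(fit$featureNames)
    contributions <- stats::setNames(phi[1, seq_len(p)], fit$featureNames)
    base <- phi[1, p + 1]
    pred <- predictFromTrees(fit$model, X)
    stopifnot(abs(base + sum(contributions) - pred) < 1e-6)
    wf <- data.frame(feature = names(contributions),
                     value = as.numeric(X[1, ]),
                     contribution = unname(contributions))
    wf <- wf[order(-abs(wf$contribution)), ]
    rownames(wf) <- NULL
    list(prediction = unname(pred), baseValue = unname(base),
         contributions = contributions, waterfall = wf)
}
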