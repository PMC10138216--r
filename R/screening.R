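## Per-variant pre-selection: distribution tests on MII counts split by
## carrier status, and shadow-feature ("Boruta") importance ranking with a
## random-forest or SHAP-GBM importance engine.

#' Mann-Whitney U test with explicit exactness rule
#'
#' Thin wrapper used by the screening tests: the exact null distribution is
#' used when both groups have at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction applies.
#'
#' @param x,y numeric samples (carrier / non-carrier MII counts).
#' @param alternative as in [stats::wilcox.test()].
#' @return list with \code{U} (statistic for \code{x}), \code{p} and
#'   \code{exact} flag.
#' @export
mannWhitney <- function(x, y, alternative = "two.sided") {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- length(x) <= 8 && length(y) <= 8 && !ties
    ht <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = alternative,
                           exact = exact, correct = TRUE))
    list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Per-variant distribution tests
#'
#' For each requested variant, splits the MII counts by carrier status
#' (alt-presence; processes with a missing genotype at that variant are
#' excluded) and applies the two-sample Kolmogorov-Smirnov test and the
#' Mann-Whitney U test. A variant is significant in a direction only when
#' both tests fall below \code{alpha}; the direction compares carrier vs
#' non-carrier median MII. Monomorphic variants, or splits with fewer than
#' two observations on either side, are flagged untestable rather than
#' raising an error. No multiple-testing correction is applied by default
#' (\code{adjust = "none"}); a Benjamini-Hochberg option is available.
#'
#' @param cohort a genotyped [StimCohort-class].
#' @param variants variant ids to test (default: all panel variants).
#' @param alpha significance level (default 0.05).
#' @param adjust p-adjustment method applied to both test families before
#'   calling direction, \code{"none"} (default) or any
#'   [stats::p.adjust.methods] name.
#' @return data.frame with one row per variant: carrier counts, KS and MW
#'   statistics and p-values, \code{direction} (\code{higher}/\code{lower}/
#'   \code{none}) and \code{testable}.
#' @export
variantDistributionTests <- function(cohort, variants = NULL, alpha = 0.05,
                                     adjust = "none") {
    ap <- altPresence(cohort)
    if (is.null(variants)) variants <- colnames(ap)
    stopifnot(all(variants %in% colnames(ap)))
    mii <- unname(miiCounts(cohort))
    one <- function(v) {
        g <- ap[, v]
        ok <- !is.na(g)
        alt <- mii[ok & g == 1L]
        ref <- mii[ok & g == 0L]
        if (length(alt) < 2 || length(ref) < 2)
            return(data.frame(variant_id = v, n_ref_carriers = length(ref),
                              n_alt_carriers = length(alt),
                              ks_statistic = NA_real_, ks_p = NA_real_,
                              mwu_statistic = NA_real_, mwu_p = NA_real_,
                              testable = FALSE))
        ks <- suppressWarnings(stats::ks.test(alt, ref, exact = FALSE))
        mw <- mannWhitney(alt, ref)
        data.frame(variant_id = v, n_ref_carriers = length(ref),
                   n_alt_carriers = length(alt),
                   ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                   mwu_statistic = mw$U, mwu_p = mw$p, testable = TRUE)
    }
    res <- do.call(rbind, lapply(variants, one))
    ksAdj <- stats::p.adjust(res$ks_p, method = adjust)
    mwAdj <- stats::p.adjust(res$mwu_p, method = adjust)
    res$direction <- "none"
    sig <- res$testable & !is.na(ksAdj) & ksAdj < alpha & mwAdj < alpha
    if (any(sig)) {
        med <- vapply(which(sig), function(i) {
            g <- ap[, res$variant_id[i]]
            ok <- !is.na(g)
            stats::median(mii[ok & g == 1L]) -
                stats::median(mii[ok & g == 0L])
        }, numeric(1))
        res$direction[which(sig)] <-
            ifelse(med > 0, "higher", ifelse(med < 0, "lower", "none"))
    }
    attr(res, "alpha") <- alpha
    res
}

.borutaEngineRF <- function(X, y, cfg) {
    X[is.na(X)] <- 0L  # ranger takes no missing values; alt-presence -> 0
    fit <- ranger::ranger(x = X, y = y, num.trees = cfg$numTrees,
                          importance = "permutation", num.threads = 1,
                          seed = cfg$.iterSeed)
    fit$variable.importance
}

.borutaEngineShapGbm <- function(X, y, cfg) {
    d <- xgboost::xgb.DMatrix(X, label = y, missing = NA, nthread = 1)
    params <- list(objective = "reg:squarederror", eta = cfg$eta,
                   max_depth = cfg$maxDepth, tree_method = "hist",
                   grow_policy = "lossguide", max_leaves = cfg$maxLeaves,
                   nthread = 1, seed = cfg$.iterSeed)
    fit <- xgboost::xgb.train(params, d, nrounds = cfg$nrounds, verbose = 0)
    contrib <- predict(fit, d, predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, seq_len(ncol(X)), drop = FALSE]))
    stats::setNames(imp, colnames(X))
}

#' Shadow-feature importance ranking (Boruta scheme)
#'
#' Each iteration appends a permuted ("shadow") copy of every feature, fits
#' the chosen importance engine on the augmented matrix, and scores a hit for
#' every real feature whose importance exceeds the best shadow importance.
#' After \code{maxIter} iterations a two-sided binomial test at \code{alpha}
#' declares features with significantly more (fewer) than half hits confirmed
#' (rejected); undecided features are resolved by comparing their median
#' importance with the median best-shadow importance. The returned score is
#' the hit fraction. Columns are processed in canonical (sorted-name) order
#' so the result is invariant to the column order of the input.
#'
#' @param X numeric feature matrix (alt-presence columns; an extra clinical
#'   column such as AMH may be appended by the caller). Missing values are
#'   imputed to 0 for the random-forest engine and passed through natively to
#'   the gradient-boosting engine.
#' @param y outcome vector (MII counts).
#' @param engine \code{"rf"} (random-forest permutation importance) or
#'   \code{"shap-gbm"} (gradient-boosted trees, mean absolute Shapley value).
#' @param maxIter number of shadow iterations (default 100).
#' @param alpha binomial-test level (default 0.05).
#' @param seed mandatory seed; fixed seed reproduces decisions exactly.
#' @param numTrees,nrounds,eta,maxDepth,maxLeaves engine hyperparameters.
#' @return data.frame ranked by score (hit fraction), with columns
#'   \code{variant_id, score, median_importance, decision} and attribute
#'   \code{"method"}.
#' @export
borutaRank <- function(X, y, engine = c("rf", "shap-gbm"), maxIter = 100,
                       alpha = 0.05, seed, numTrees = 100, nrounds = 100,
                       eta = 0.1, maxDepth = 16, maxLeaves = 5) {
    engine <- match.arg(engine)
    if (missing(seed)) stop("borutaRank needs an explicit seed")
    stopifnot(!is.null(colnames(X)), nrow(X) == length(y))
    X <- X[, sort(colnames(X)), drop = FALSE]  # canonical order
    p <- ncol(X); n <- nrow(X)
    cfg <- list(numTrees = numTrees, nrounds = nrounds, eta = eta,
                maxDepth = maxDepth, maxLeaves = maxLeaves)
    engineFun <- switch(engine, rf = .borutaEngineRF,
                        `shap-gbm` = .borutaEngineShapGbm)
    hits <- stats::setNames(integer(p), colnames(X))
    impHist <- matrix(NA_real_, maxIter, p,
                      dimnames = list(NULL, colnames(X)))
    bestShadow <- numeric(maxIter)
    withr::with_seed(seed, {
        for (it in seq_len(maxIter)) {
            Xs <- X
            for (cn in colnames(X))  # name order fixes the RNG assignment
                Xs[, cn] <- X[sample.int(n), cn]
            colnames(Xs) <- paste0(".shadow.", colnames(X))
            cfg$.iterSeed <- sample.int(.Machine$integer.max, 1)
            imp <- engineFun(cbind(X, Xs), y, cfg)
            real <- imp[colnames(X)]
            real[is.na(real)] <- 0
            shadow <- imp[colnames(Xs)]
            shadow[is.na(shadow)] <- 0
            bestShadow[it] <- max(shadow)
            hits <- hits + (real > bestShadow[it])
            impHist[it, ] <- real
        }
    })
    pUp <- stats::pbinom(hits - 1L, maxIter, 0.5, lower.tail = FALSE)
    pDown <- stats::pbinom(hits, maxIter, 0.5)
    pBin <- pmin(1, 2 * pmin(pUp, pDown))
    medImp <- apply(impHist, 2, stats::median)
    decision <- ifelse(pBin < alpha & hits > maxIter / 2, "confirmed",
                ifelse(pBin < alpha & hits < maxIter / 2, "rejected",
                       ifelse(medImp > stats::median(bestShadow),
                              "confirmed", "rejected")))
    out <- data.frame(variant_id = colnames(X), score = hits / maxIter,
                      median_importance = medImp, decision = decision,
                      row.names = NULL)
    out <- out[order(-out$score, -out$median_importance, out$variant_id), ]
    rownames(out) <- NULL
    attr(out, "method") <- paste0("boruta-", engine)
    attr(out, "iterations") <- maxIter
    out
}

#' Combine several variant rankings into a top-k selection
#'
#' Aggregates two or more rankings over the same variant set by mean rank
#' (lower is better); ties are broken by mean score (higher is better), then
#' by variant id lexicographically. The top \code{k} variants survive.
#'
#' @param rankings list of data.frames as returned by [borutaRank()] (must
#'   rank identical variant sets).
#' @param k number of survivors (default 20).
#' @return data.frame of the k top variants with \code{mean_rank},
#'   \code{mean_score} and per-input ranks.
#' @export
combineRankings <- function(rankings, k = 20) {
    stopifnot(length(rankings) >= 2)
    ids <- sort(rankings[[1]]$variant_id)
    for (r in rankings)
        if (!identical(sort(r$variant_id), ids))
            stop("rankings cover different variant sets")
    rankMat <- vapply(rankings, function(r) {
        match(ids, r$variant_id)
    }, numeric(length(ids)))
    scoreMat <- vapply(rankings, function(r) {
        r$score[match(ids, r$variant_id)]
    }, numeric(length(ids)))
    out <- data.frame(variant_id = ids,
                      mean_rank = rowMeans(rankMat),
                      mean_score = rowMeans(scoreMat))
    out <- cbind(out, stats::setNames(as.data.frame(rankMat),
                                      paste0("rank_", seq_along(rankings))))
    out <- out[order(out$mean_rank, -out$mean_score, out$variant_id), ]
    rownames(out) <- NULL
    utils::head(out, k)
}
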