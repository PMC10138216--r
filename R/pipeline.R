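## End-to-end orchestration: screening -> CA / SOM / haplotype feature
## construction -> clinical forward selection -> genetic combination search
## -> final clinical-genetic model -> per-patient explanation.

#' Pipeline configuration
#'
#' Stage parameters for [runPipeline()], with the study defaults. Every
#' stochastic stage receives a seed derived deterministically from the
#' single master seed, so one seed reproduces the full report.
#'
#' @param seed master seed (mandatory).
#' @param topK variants surviving the combined ranking (default 20).
#' @param alpha significance level for the distribution tests.
#' @param borutaIter shadow-feature iterations per ranking run.
#' @param caK variants in the CA proximity feature (default 3).
#' @param caTargetGroup MII group the CA feature targets (default ">11").
#' @param somIterations SOM training iterations (default 100,000).
#' @param somTopM characteristic variants per enriched node (default 10),
#'   also the candidate pool cap for the SOM subset search.
#' @param blockMethod haplotype block rule (default four-gamete).
#' @param hapFreqFloor candidate-haplotype frequency floor (default 0.05).
#' @param nHapFeatures reduced-haplotype features carried into the
#'   combination search (default 3).
#' @param clinicalCandidates candidate clinical columns for forward
#'   selection.
#' @param model a [modelConfig()]; defaults to the study hyperparameters
#'   with a seed derived from \code{seed}.
#' @return config list of class \code{"stimPipelineConfig"}.
#' @export
pipelineConfig <- function(seed, topK = 20, alpha = 0.05, borutaIter = 100,
                           caK = 3, caTargetGroup = ">11",
                           somIterations = 100000L, somTopM = 10,
                           blockMethod = "four-gamete", hapFreqFloor = 0.05,
                           nHapFeatures = 3,
                           clinicalCandidates = c("amh", "afc_day1", "age",
                                                  "prev_mii", "prev_denuded",
                                                  "pcos", "bmi", "fsh", "lh",
                                                  "e2", "stim_days",
                                                  "gonadotropin_dose"),
                           model = NULL) {
    if (missing(seed)) stop("pipelineConfig needs a master seed")
    seed <- as.integer(seed)
    if (is.null(model)) model <- modelConfig(seed = seed + 11L)
    cfg <- list(seed = seed, topK = topK, alpha = alpha,
                borutaIter = borutaIter, caK = caK,
                caTargetGroup = caTargetGroup,
                somIterations = as.integer(somIterations), somTopM = somTopM,
                blockMethod = blockMethod, hapFreqFloor = hapFreqFloor,
                nHapFeatures = nHapFeatures,
                clinicalCandidates = clinicalCandidates, model = model)
    class(cfg) <- "stimPipelineConfig"
    cfg
}

.stageSeed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Run the full clinical-genetic pipeline
#'
#' Executes, on one cohort: (1) the trivial benchmark and greedy forward
#' selection of clinical features; (2) per-variant distribution tests;
#' (3) three shadow-feature ranking runs (random forest on variants,
#' SHAP-GBM on variants, random forest on variants plus AMH) combined by
#' mean rank into a top-k pre-selection; (4) correspondence analysis of the
#' variant-by-MII-group table and the proximity count feature; (5) SOM
#' training, node enrichment and the exhaustive subset search for the
#' standardized count feature; (6) haplotype block detection, candidate
#' screening and decision-tree reduction into binary features; (7) the
#' exhaustive genetic-feature combination search on top of the selected
#' clinical features, with clinical-only and clinical-genetic metrics
#' compared on identical patient-grouped folds; (8) Shapley importance and
#' an example per-patient explanation. Any stage failure aborts with the
#' stage name attached.
#'
#' @param cohort a genotyped [StimCohort-class] (e.g. from
#'   [generateCohort()] or [loadCohort()]).
#' @param config a [pipelineConfig()].
#' @return report list of class \code{"stimPipelineReport"}; see the
#'   elements \code{metrics}, \code{clinicalSelection}, \code{screening},
#'   \code{features}, \code{combinationSearch}, \code{importance},
#'   \code{exampleExplanation}, \code{seeds}.
#' @export
runPipeline <- function(cohort, config) {
    stopifnot(methods::is(cohort, "StimCohort"),
              inherits(config, "stimPipelineConfig"))
    report <- list(seeds = list(master = config$seed))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    y <- unname(miiCounts(cohort))
    patients <- patientIds(cohort)
    cd <- as.data.frame(clinicalData(cohort))
    ap <- altPresence(cohort)
    partition <- binMiiCounts(cohort)
    report$partition <- partition$sizes

    ## 1. benchmark + clinical forward selection
    report$baseline <- stage("trivial-baseline", trivialBaseline(y))
    clinCand <- cd[, intersect(config$clinicalCandidates, colnames(cd)),
                   drop = FALSE]
    sel <- stage("clinical-selection",
                 forwardSelect(clinCand, y, patients, config$model))
    report$clinicalSelection <- sel
    clinFeat <- clinCand[, sel$selected, drop = FALSE]

    ## 2. per-variant distribution tests
    tests <- stage("variant-tests",
                   variantDistributionTests(cohort, alpha = config$alpha))
    report$screening <- list(
        tests = tests,
        nHigher = sum(tests$direction == "higher"),
        nLower = sum(tests$direction == "lower"))

    ## 3. shadow-feature rankings and combined top-k
    rankings <- stage("boruta-rankings", {
        apImp <- ap
        r1 <- borutaRank(ap, y, engine = "rf", maxIter = config$borutaIter,
                         alpha = config$alpha,
                         seed = .stageSeed(config, 101))
        r2 <- borutaRank(ap, y, engine = "shap-gbm",
                         maxIter = config$borutaIter, alpha = config$alpha,
                         seed = .stageSeed(config, 102))
        withAmh <- cbind(ap, amh = cd$amh)
        r3 <- borutaRank(withAmh, y, engine = "rf",
                         maxIter = config$borutaIter, alpha = config$alpha,
                         seed = .stageSeed(config, 103))
        r3 <- r3[r3$variant_id != "amh", ]  # rank variants, not the anchor
        list(rf = r1, shapGbm = r2, rfWithAmh = r3)
    })
    combined <- stage("combine-rankings",
                      combineRankings(rankings, k = config$topK))
    topVariants <- combined$variant_id
    report$screening$rankings <- rankings
    report$screening$combined <- combined

    ## helper: CV RMSE of clinical features + one extra numeric feature
    evalWithFeature <- function(values, name = "candidate") {
        if (is.null(values)) {
            if (ncol(clinFeat) == 0) return(report$baseline$rmse)
            return(trainGbmCv(clinFeat, y, patients,
                              config$model)$metrics$rmse)
        }
        df <- cbind(clinFeat, stats::setNames(data.frame(values), name))
        trainGbmCv(df, y, patients, config$model)$metrics$rmse
    }

    ## 4. correspondence analysis feature
    caFeatures <- stage("ca-feature", {
        tab <- buildContingency(cohort, partition, topVariants)
        ca <- fitCA(tab)
        feat <- selectProximalVariants(ca, config$caTargetGroup,
                                       k = config$caK, name = "IV_CA")
        list(table = tab, ca = ca, feature = feat)
    })
    report$ca <- list(totalInertia = caFeatures$ca@totalInertia,
                      inertiaProp = caFeatures$ca@inertiaProp,
                      variants = featureVariants(caFeatures$feature))

    ## 5. SOM feature via exhaustive subset search
    somPart <- stage("som-feature", {
        scfg <- somConfig(iterations = config$somIterations,
                          seed = .stageSeed(config, 104))
        som <- trainSOM(ap[, topVariants, drop = FALSE], scfg)
        enr <- nodeEnrichment(som, partition, ap[, topVariants,
                                                 drop = FALSE],
                              topM = config$somTopM)
        extreme <- c(partition$labels[1], partition$labels[5])
        cand <- character(0)
        for (e in enr)
            if (length(intersect(e$enrichedFor, extreme)))
                cand <- c(cand, e$characteristicVariants$variant_id)
        cand <- utils::head(unique(cand), config$somTopM)
        if (length(cand) < 2) cand <- utils::head(topVariants,
                                                  config$somTopM)
        search <- subsetSearch(cand, function(sub) {
            f <- buildStandardizedFeature(sub, ap, name = "IV_SOM")
            evalWithFeature(evaluateFeature(f, ap), "IV_SOM")
        })
        feat <- buildStandardizedFeature(search$best, ap, name = "IV_SOM")
        list(som = som, enrichment = enr, candidates = cand,
             search = search, feature = feat)
    })
    report$som <- list(qe = somPart$som@qe, candidates = somPart$candidates,
                       bestSubset = somPart$search$best,
                       searchTrace = somPart$search$trace)

    ## 6. haplotype blocks, screening, reduction
    hapPart <- stage("haplotype-features", {
        blocks <- detectBlocks(cohort, method = config$blockMethod)
        screen <- screenHaplotypes(blocks, cohort, function(values, name) {
            if (is.null(values)) evalWithFeature(NULL)
            else evalWithFeature(values, "hap_candidate")
        }, freqFloor = config$hapFreqFloor)
        feats <- list()
        if (nrow(screen) > 0) {
            byBlock <- screen[!duplicated(screen$block), , drop = FALSE]
            byBlock <- utils::head(byBlock, config$nHapFeatures)
            for (i in seq_len(nrow(byBlock))) {
                blk <- blocks[[byBlock$block[i]]]
                red <- reduceHaplotype(
                    blk$variants, ap,
                    name = "tmp", seed = .stageSeed(config, 105 + i))
                red@name <- sprintf("IV%d_%d", length(blk$variants),
                                    length(featureVariants(red)))
                feats[[red@name]] <- red
            }
        }
        list(blocks = blocks, screen = screen, features = feats)
    })
    report$haplotypes <- list(
        nBlocks = length(hapPart$blocks),
        nCandidates = nrow(hapPart$screen),
        screen = hapPart$screen,
        reduced = lapply(hapPart$features, function(f)
            list(name = featureName(f), variants = featureVariants(f),
                 baseline = f@baseline, frequency = f@frequency)))

    ## 7. genetic combination search on identical folds
    geneticFeats <- c(list(IV_CA = caFeatures$feature,
                           IV_SOM = somPart$feature),
                      hapPart$features)
    gdf <- as.data.frame(lapply(geneticFeats, evaluateFeature, cohort = ap))
    colnames(gdf) <- names(geneticFeats)
    combo <- stage("genetic-combination-search",
                   geneticCombinationSearch(gdf, clinFeat, y, patients,
                                            config$model))
    report$combinationSearch <- combo[c("best", "table")]
    report$features <- geneticFeats
    report$metrics <- list(
        baseline = report$baseline,
        clinical = combo$clinicalMetrics,
        clinicalGenetic = combo$bestMetrics,
        rmseReduction = combo$clinicalMetrics$rmse - combo$bestMetrics$rmse)

    ## 8. explanation of the final model
    finalFeatures <- cbind(clinFeat, gdf[, combo$best, drop = FALSE])
    finalFit <- combo$bestFit
    imp <- stage("shap-importance", shapImportance(finalFit, finalFeatures))
    report$importance <- imp
    ex <- stage("example-explanation",
                explainPatient(finalFit, finalFeatures[1, , drop = FALSE]))
    ex$process_id <- processIds(cohort)[1]
    ex$cumulativeGeneticImpact <-
        sum(ex$contributions[intersect(names(ex$contributions),
                                       combo$best)])
    report$exampleExplanation <- ex
    class(report) <- "stimPipelineReport"
    report
}

#' @export
print.stimPipelineReport <- function(x, ...) {
    cat("stimMII pipeline report (seed", x$seeds$master, ")\n")
    cat(sprintf("  trivial baseline RMSE: %.3f\n", x$baseline$rmse))
    cat("  clinical features:",
        paste(x$clinicalSelection$selected, collapse = ", "), "\n")
    cat(sprintf("  clinical model:        RMSE %.3f\n",
                x$metrics$clinical$rmse))
    cat("  genetic features:", paste(x$combinationSearch$best,
                                     collapse = ", "), "\n")
    cat(sprintf("  clinical-genetic:      RMSE %.3f (reduction %.3f)\n",
                x$metrics$clinicalGenetic$rmse, x$metrics$rmseReduction))
    cat("  significant variants:", x$screening$nHigher, "higher /",
        x$screening$nLower, "lower MII\n")
    invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the machine-readable parts of a report (metrics, selections,
#' feature definitions, seeds, score tables) as deterministic JSON.
#'
#' @param report a \code{stimPipelineReport}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
    out <- list(
        seeds = report$seeds,
        partition = as.list(report$partition),
        baseline_rmse = report$baseline$rmse,
        clinical_features = report$clinicalSelection$selected,
        clinical_rmse = report$metrics$clinical$rmse,
        genetic_features = report$combinationSearch$best,
        clinical_genetic_rmse = report$metrics$clinicalGenetic$rmse,
        rmse_reduction = report$metrics$rmseReduction,
        n_significant_higher = report$screening$nHigher,
        n_significant_lower = report$screening$nLower,
        top_variants = report$screening$combined$variant_id,
        ca = report$ca, som_qe = report$som$qe,
        som_best_subset = report$som$bestSubset,
        haplotype_features = report$haplotypes$reduced,
        importance = report$importance,
        combination_table = report$combinationSearch$table)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
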