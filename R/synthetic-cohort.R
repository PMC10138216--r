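## Synthetic cohorts with the statistical structure the pipeline assumes:
## clinical marginals matching the genotyped study group, panel allele
## frequencies, founder-haplotype LD blocks, structurally missing
## previous-stimulation data, and a negative-binomial MII outcome with
## planted clinical and genetic effects.

#' Default variant panel
#'
#' The 19 distinct panel variants whose population allele frequencies are
#' published for the genotyped study group (reproduction-related genes
#' LHCGR, PRLR, ESR1, ESR2, GDF9, FSHB, FSHR), plus \code{nNull} independent
#' null variants with no outcome effect, so that screening specificity is
#' testable. Null variants get synthetic ids \code{nv001...}, deterministic
#' allele frequencies cycling over 0.05-0.50, and positions spaced 100 kb
#' apart on chromosome 7. For published variants whose ref/alt bases are not
#' printed, placeholder alleles are used; allele letters are never consumed
#' downstream (all feature engineering runs on dosage / alt-presence).
#'
#' @param nNull number of null variants appended (default 100).
#' @return panel data.frame (see [validatePanel()]), sorted by chromosome
#'   and position.
#' @export
defaultPanel <- function(nNull = 100) {
    core <- data.frame(
        variant_id = c("rs11887058", "rs80111020", "rs6166",
                       "rs387032", "rs401694", "rs112461", "rs1057828",
                       "rs56251626", "rs62355478", "rs78373811",
                       "rs186609463",
                       "rs11739194", "rs75061517", "rs17166294", "rs30177",
                       "rs2273207", "rs2207396", "rs676349", "rs928554"),
        gene_symbol = c("LHCGR", "FSHR", "FSHR",
                        rep("PRLR", 8),
                        rep("GDF9", 4),
                        "ESR1", "ESR1", "FSHB", "ESR2"),
        chromosome = c("2", "2", "2", rep("5", 8), rep("5", 4),
                       "6", "6", "11", "14"),
        position = c(48729336L, 48962060L, 48962782L,
                     35061629L, 35062516L, 35063190L, 35064413L,
                     35064922L, 35065548L, 35068146L, 35069864L,
                     132865538L, 132866082L, 132866205L, 132866719L,
                     152061190L, 152061247L, 30234435L, 64227477L),
        ref_allele = c("C", "A", "C",
                       "T", "C", "A", "C", "C", "C", "G", "G",
                       "T", "T", "T", "C",
                       "A", "G", "A", "C"),
        alt_allele = c("T", "G", "T",
                       "C", "T", "T", "T", "T", "T", "A", "A",
                       "C", "C", "C", "G",
                       "G", "A", "G", "T"),
        alt_frequency = c(0.428, 1 - 0.909, 0.701,
                          1 - 0.845, 1 - 0.765, 0.242, 1 - 0.939,
                          1 - 0.936, 1 - 0.992, 1 - 0.913, 1 - 0.985,
                          0.515, 1 - 0.689, 0.288, 0.924,
                          0.117, 0.356, 0.523, 0.731))
    if (nNull > 0) {
        nulls <- data.frame(
            variant_id = sprintf("nv%03d", seq_len(nNull)),
            gene_symbol = "NULL_REGION",
            chromosome = "7",
            position = 1000000L + 100000L * seq_len(nNull),
            ref_allele = "A",
            alt_allele = "G",
            alt_frequency = rep(seq(0.05, 0.50, by = 0.05),
                                length.out = nNull))
        core <- rbind(core, nulls)
    }
    core <- core[order(core$chromosome, core$position), ]
    rownames(core) <- NULL
    validatePanel(core)
}

#' Default LD blocks for the synthetic generator
#'
#' Three founder-haplotype blocks mirroring the gene regions from which the
#' haplotype features derive: an FSHR pair, an eight-variant PRLR run and a
#' three-variant GDF9 run. Variants not covered by a block are sampled
#' independently.
#'
#' @param nFounders founder haplotypes per block pool (default 200; pool
#'   allele frequencies are rounded to multiples of 1/nFounders, so larger
#'   pools track rare configured frequencies more faithfully).
#' @return list of blocks, each \code{list(variants, dPrime, nFounders)}.
#' @export
defaultLdBlocks <- function(nFounders = 200) {
    list(list(variants = c("rs80111020", "rs6166"),
              dPrime = 1, nFounders = nFounders),
         list(variants = c("rs387032", "rs401694", "rs112461", "rs1057828",
                           "rs56251626", "rs62355478", "rs78373811",
                           "rs186609463"),
              dPrime = 1, nFounders = nFounders),
         list(variants = c("rs75061517", "rs17166294", "rs30177"),
              dPrime = 1, nFounders = nFounders))
}

#' Default planted effects
#'
#' Linear-predictor coefficients for the synthetic MII outcome: intercept,
#' clinical effects (AMH on the log1p scale, AFC, age) and a list of planted
#' genetic effects, each either a count feature over a variant set or a
#' binary haplotype feature with baseline alt-presence states. The defaults
#' plant a modest count effect on the three CA-derived variants and a
#' haplotype effect on the FSHR pair; coefficients are free parameters of the
#' generator (no study-reported effect sizes exist in outcome units).
#'
#' @return effects list with elements \code{beta0, betaAMH, betaAFC, betaAge,
#'   dispersion, genetic}.
#' @export
defaultEffects <- function() {
    list(beta0 = 1.25, betaAMH = 0.48, betaAFC = 0.012, betaAge = -0.012,
         dispersion = 5,
         genetic = list(
             list(name = "countCA", type = "count",
                  variants = c("rs11887058", "rs112461", "rs2207396"),
                  beta = 0.06),
             list(name = "hapFSHR", type = "haplotype",
                  variants = c("rs80111020", "rs6166"),
                  baseline = c(0L, 1L), beta = 0.12)))
}

#' Generator configuration
#'
#' Assembles and validates the configuration consumed by [generateCohort()]
#' and [sampleGenotypesWithLD()]. Defaults emulate the genotyped study group:
#' 264 patients, 516 processes (a deterministic 252 of the 264 patients
#' contribute a second stimulation cycle), published clinical marginals
#' (AMH log-normal truncated at the 15 ng/mL exclusion bound, ages from a
#' discretized truncated normal), the [defaultPanel()] frequencies, the
#' [defaultLdBlocks()] and the [defaultEffects()].
#'
#' @param nPatients number of women.
#' @param secondCycleFraction fraction of patients with a second IVF process;
#'   \code{round(nPatients * secondCycleFraction)} patients get one.
#' @param panel variant panel with \code{alt_frequency} set.
#' @param ldBlocks list of founder-haplotype blocks (disjoint variant sets).
#' @param effects planted-effect list, see [defaultEffects()].
#' @param clinical named list of clinical marginal parameters; see the
#'   implementation for fields (means/SDs per covariate).
#' @param missingness list: \code{afc} = fraction of processes lacking the
#'   antral follicle count. Previous-stimulation fields are structurally
#'   missing for every first cycle.
#' @param recomb per-founder probability of breaking block LD (0 = complete
#'   LD within blocks).
#' @param seed mandatory integer seed; identical configuration and seed
#'   reproduce the cohort exactly.
#' @return validated config list of class \code{"stimGeneratorConfig"}.
#' @export
generatorConfig <- function(nPatients = 264,
                            secondCycleFraction = 252 / 264,
                            panel = defaultPanel(),
                            ldBlocks = defaultLdBlocks(),
                            effects = defaultEffects(),
                            clinical = list(),
                            missingness = list(afc = 0.10),
                            recomb = 0,
                            seed) {
    if (missing(seed) || !is.finite(seed))
        stop("a seed is mandatory in the generator configuration")
    panel <- validatePanel(panel)
    if (anyNA(panel$alt_frequency))
        stop("every panel variant needs an alt_frequency for simulation")
    covered <- unlist(lapply(ldBlocks, `[[`, "variants"))
    if (anyDuplicated(covered))
        stop("ld blocks must cover disjoint variant sets")
    miss <- setdiff(covered, panel$variant_id)
    if (length(miss))
        stop("ld block variant(s) not in panel: ",
             paste(miss, collapse = ", "))
    defClin <- list(ageMean = 34.55, ageSD = 4.20, ageMin = 18, ageMax = 46,
                    bmiMean = 23.15, bmiSD = 4.11,
                    fshMean = 7.25, fshSD = 3.53,
                    lhMean = 6.10, lhSD = 4.63,
                    e2MeanLog = 2.46, e2SDLog = 0.84,
                    amhMeanLog = 0.829, amhSDLog = 0.883, amhMax = 15,
                    afcIntercept = 1.59, afcAmhSlope = 0.75, afcSize = 2.2,
                    stimDaysMean = 9.77, stimDaysSD = 3.10,
                    doseMean = 2347, doseSD = 795,
                    pcosPrev = 0.08, denudedExtra = 1.75)
    clinical <- utils::modifyList(defClin, clinical)
    if (!is.numeric(effects$dispersion) || effects$dispersion <= 0)
        stop("outcome dispersion must be positive")
    cfg <- list(nPatients = as.integer(nPatients),
                secondCycleFraction = secondCycleFraction,
                panel = panel, ldBlocks = ldBlocks, effects = effects,
                clinical = clinical, missingness = missingness,
                recomb = recomb, seed = as.integer(seed))
    class(cfg) <- "stimGeneratorConfig"
    cfg
}

## founder pool for one block: aligned allele runs give complete LD
## (haplotype patterns are nested, so any pair shows at most 3 gametes)
.makeFounders <- function(freqs, nFounders, recomb) {
    K <- nFounders
    founders <- vapply(freqs, function(f) {
        k <- round(f * K)
        c(rep(1L, k), rep(0L, K - k))
    }, integer(K))
    founders <- matrix(founders, nrow = K)
    if (recomb > 0) {
        redo <- which(stats::runif(K) < recomb)
        for (i in redo)
            founders[i, ] <- stats::rbinom(length(freqs), 1L, freqs)
    }
    founders
}

#' Sample a genotype matrix with block-structured LD
#'
#' Draws per-individual genotypes for the configured panel. Within each
#' block, two founder haplotypes are sampled per individual from an aligned
#' founder pool, which induces complete (or, with \code{recomb} > 0, partial)
#' linkage disequilibrium while preserving the configured marginal allele
#' frequencies; uncovered variants are independent binomial draws.
#'
#' @param config a [generatorConfig()].
#' @param n number of individuals.
#' @return list with \code{dosage} (variant x individual matrix in panel
#'   order), \code{panel} and \code{founders} (per-block founder pools, the
#'   ground truth for block-detection tests).
#' @export
sampleGenotypesWithLD <- function(config, n) {
    stopifnot(inherits(config, "stimGeneratorConfig"))
    withr::with_seed(config$seed, .sampleGenotypes(config, n))
}

.sampleGenotypes <- function(config, n) {
    panel <- config$panel
    p <- nrow(panel)
    dosage <- matrix(NA_integer_, p, n, dimnames = list(panel$variant_id))
    inBlock <- rep(FALSE, p)
    founders <- list()
    for (b in seq_along(config$ldBlocks)) {
        blk <- config$ldBlocks[[b]]
        idx <- match(blk$variants, panel$variant_id)
        inBlock[idx] <- TRUE
        nf <- if (is.null(blk$nFounders)) 200L else blk$nFounders
        pool <- .makeFounders(panel$alt_frequency[idx], nf, config$recomb)
        h1 <- sample.int(nf, n, replace = TRUE)
        h2 <- sample.int(nf, n, replace = TRUE)
        dosage[idx, ] <- t(pool[h1, , drop = FALSE] +
                           pool[h2, , drop = FALSE])
        founders[[b]] <- pool
    }
    for (i in which(!inBlock))
        dosage[i, ] <- stats::rbinom(n, 2L, panel$alt_frequency[i])
    list(dosage = dosage, panel = panel, founders = founders)
}

.evalPlantedFeature <- function(g, ap) {
    idx <- match(g$variants, colnames(ap))
    if (anyNA(idx)) stop("planted effect names unknown variant(s): ",
                         paste(g$variants[is.na(idx)], collapse = ", "))
    sub <- ap[, idx, drop = FALSE]
    if (g$type == "count") rowSums(sub)
    else if (g$type == "haplotype")
        as.integer(rowSums(sub == matrix(g$baseline, nrow(sub),
                                         length(g$baseline),
                                         byrow = TRUE)) ==
                   length(g$baseline))
    else stop("unknown planted feature type: ", g$type)
}

#' Generate a complete synthetic cohort
#'
#' Draws patient genotypes (see [sampleGenotypesWithLD()]), clinical
#' covariates and a negative-binomial MII outcome whose log-mean is
#' \deqn{\beta_0 + \beta_{AMH}\log(1+AMH) + \beta_{AFC}\,AFC +
#'   \beta_{age}\,age + \sum_g \beta_g\, g(genotype),}
#' with the planted genetic features evaluated on alt-presence. Second
#' stimulation cycles reuse the patient's genotype and AMH and carry the
#' first cycle's outcomes as previous-stimulation fields; first cycles have
#' those fields structurally missing. AMH never exceeds the 15 ng/mL
#' exclusion bound (truncated log-normal).
#'
#' @param config a [generatorConfig()].
#' @return a [StimCohort-class]; \code{metadata(x)$groundTruth} records the
#'   planted causal variant sets, coefficients and per-block founder pools,
#'   and \code{metadata(x)$generatorConfig} the configuration.
#' @examples
#' cfg <- generatorConfig(nPatients = 30, seed = 7)
#' cohort <- generateCohort(cfg)
#' cohort
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "stimGeneratorConfig"))
    withr::with_seed(config$seed, .generateCohort(config))
}

.rnormTrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- (x < lo | x > hi)))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
}

.generateCohort <- function(config) {
    nP <- config$nPatients
    cl <- config$clinical
    eff <- config$effects

    geno <- .sampleGenotypes(config, nP)
    apPat <- t(geno$dosage > 0) * 1L
    colnames(apPat) <- config$panel$variant_id

    ## patient-level covariates
    age <- round(.rnormTrunc(nP, cl$ageMean, cl$ageSD, cl$ageMin, cl$ageMax))
    bmi <- .rnormTrunc(nP, cl$bmiMean, cl$bmiSD, 15, 45)
    pcos <- stats::runif(nP) < cl$pcosPrev
    amh <- stats::rlnorm(nP, cl$amhMeanLog, cl$amhSDLog)
    while (any(bad <- amh > cl$amhMax))
        amh[bad] <- stats::rlnorm(sum(bad), cl$amhMeanLog, cl$amhSDLog)

    nSecond <- round(nP * config$secondCycleFraction)
    secondOf <- if (nSecond > 0) sort(sample.int(nP, nSecond)) else integer(0)
    patient <- c(seq_len(nP), secondOf)
    cycle <- c(rep(1L, nP), rep(2L, length(secondOf)))
    ord <- order(patient, cycle)
    patient <- patient[ord]; cycle <- cycle[ord]
    n <- length(patient)

    ## cycle-level covariates
    fsh <- .rnormTrunc(n, cl$fshMean, cl$fshSD, 0.1)
    lh <- .rnormTrunc(n, cl$lhMean, cl$lhSD, 0.1)
    e2 <- stats::rlnorm(n, cl$e2MeanLog, cl$e2SDLog)
    afc <- stats::rnbinom(n, size = cl$afcSize,
                          mu = exp(cl$afcIntercept +
                                   cl$afcAmhSlope * log1p(amh[patient])))
    stimDays <- round(.rnormTrunc(n, cl$stimDaysMean, cl$stimDaysSD, 5, 20))
    dose <- .rnormTrunc(n, cl$doseMean, cl$doseSD, 300, 6000)

    ## linear predictor and planted genetic effects
    lp <- eff$beta0 + eff$betaAMH * log1p(amh[patient]) +
        eff$betaAFC * afc + eff$betaAge * age[patient]
    planted <- list()
    for (g in eff$genetic) {
        val <- .evalPlantedFeature(g, apPat)[patient]
        lp <- lp + g$beta * val
        planted[[g$name]] <- g
    }
    if (any(!is.finite(lp)))
        stop("non-finite linear predictor; check effect configuration")
    mii <- stats::rnbinom(n, size = eff$dispersion, mu = exp(lp))
    denuded <- mii + stats::rpois(n, cl$denudedExtra)

    ## previous-stimulation fields: second cycles see the first cycle's yield
    prevMii <- rep(NA_integer_, n)
    prevDen <- rep(NA_integer_, n)
    isSecond <- cycle == 2L
    firstIdx <- match(patient[isSecond], patient[cycle == 1L])
    prevMii[isSecond] <- mii[which(cycle == 1L)[firstIdx]]
    prevDen[isSecond] <- denuded[which(cycle == 1L)[firstIdx]]

    if (config$missingness$afc > 0)
        afc[stats::runif(n) < config$missingness$afc] <- NA_integer_

    clinical <- data.frame(
        process_id = sprintf("proc%04d_%d", patient, cycle),
        patient_id = sprintf("pat%04d", patient),
        age = age[patient], bmi = round(bmi[patient], 1),
        amh = round(amh[patient], 3),
        fsh = round(fsh, 2), lh = round(lh, 2), e2 = round(e2, 1),
        afc_day1 = afc, pcos = pcos[patient],
        prev_mii = prevMii, prev_denuded = prevDen,
        stim_days = stimDays, gonadotropin_dose = round(dose),
        mii_count = mii, denuded_count = denuded)

    dosage <- geno$dosage[, patient, drop = FALSE]
    colnames(dosage) <- clinical$process_id
    cohort <- StimCohort(clinical, dosage, config$panel)
    metadata(cohort)$groundTruth <- list(planted = planted,
                                         effects = eff,
                                         founders = geno$founders)
    metadata(cohort)$generatorConfig <- config
    cohort
}
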