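# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A tiny hand-made cohort: explicit clinical rows and dosages.
tinyCohort <- function(dosage = NULL, mii = c(5L, 9L, 1L, 12L),
                       patients = c("w1", "w2", "w3", "w4")) {
    n <- length(mii)
    cl <- data.frame(process_id = paste0("p", seq_len(n)),
                     patient_id = patients,
                     age = rep(34, n), bmi = rep(23, n),
                     amh = seq(1, by = 0.5, length.out = n),
                     fsh = rep(7, n), lh = rep(6, n), e2 = rep(17, n),
                     pcos = rep(FALSE, n), mii_count = mii)
    if (is.null(dosage)) return(StimCohort(cl))
    panel <- toyPanel(nrow(dosage))
    rownames(dosage) <- panel$variant_id
    StimCohort(cl, dosage, panel)
}

toyPanel <- function(m, chromosome = "1") {
    validatePanel(data.frame(
        variant_id = sprintf("tv%02d", seq_len(m)),
        gene_symbol = "TOY",
        chromosome = chromosome,
        position = 1000L * seq_len(m),
        ref_allele = "A", alt_allele = "G",
        alt_frequency = rep(0.3, m)))
}

# Cohort of n individuals drawn from an explicit phased founder pool:
# ground-truth haplotypes known, so gamete counts can be tabulated directly.
founderCohort <- function(founders, n, seed, mii = NULL) {
    set.seed(seed)
    K <- nrow(founders); m <- ncol(founders)
    h1 <- sample.int(K, n, replace = TRUE)
    h2 <- sample.int(K, n, replace = TRUE)
    dosage <- t(founders[h1, , drop = FALSE] + founders[h2, , drop = FALSE])
    storage.mode(dosage) <- "integer"
    if (is.null(mii)) mii <- rep_len(c(1L, 5L, 9L, 13L), n)
    co <- tinyCohort(dosage, mii = mii,
                     patients = paste0("w", seq_len(n)))
    attr(co, "truePhase") <- list(h1 = founders[h1, , drop = FALSE],
                                  h2 = founders[h2, , drop = FALSE])
    co
}

# Direct two-locus gamete counting from known phase (oracle for the EM).
countGametes <- function(hapA, hapB) {
    tab <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    for (i in seq_along(hapA))
        tab[hapA[i] + 1, hapB[i] + 1] <- tab[hapA[i] + 1, hapB[i] + 1] + 1
    tab / sum(tab)
}

# Brute-force maximal four-gamete runs over contiguous intervals, given a
# logical recombinant-pair matrix computed independently of the package.
bruteForceFourGameteRuns <- function(recomb) {
    m <- nrow(recomb)
    valid <- function(i, j) {
        for (a in i:(j - 1)) for (b in (a + 1):j)
            if (recomb[a, b]) return(FALSE)
        TRUE
    }
    runs <- list(); i <- 1
    while (i <= m) {
        j <- i
        while (j < m && valid(i, j + 1)) j <- j + 1
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1
    }
    runs
}

# A generator config scaled for tests: fewer nulls, explicit planted effects.
testGenConfig <- function(nPatients, seed, geneticBeta = 0,
                          nNull = 20, dispersion = 5) {
    eff <- defaultEffects()
    eff$dispersion <- dispersion
    eff$genetic <- list(
        list(name = "plantedCount", type = "count",
             variants = c("rs11887058", "rs2207396"), beta = geneticBeta))
    generatorConfig(nPatients = nPatients, panel = defaultPanel(nNull),
                    effects = eff, seed = seed)
}

# Small boosted-model config so CV fits stay cheap in unit tests.
testModelConfig <- function(seed, nTrees = 40) {
    modelConfig(nTrees = nTrees, seed = seed)
}
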