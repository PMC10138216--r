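## Pairwise LD from unphased genotypes (two-locus EM), haplotype block
## detection (Gabriel confidence intervals, four-gamete rule, solid spine of
## LD), per-block haplotype frequencies (multi-locus EM, partition-ligation
## beyond 12 variants), candidate screening and decision-tree reduction to a
## binary feature.

## EM over the double-heterozygote phase ambiguity for one variant pair.
## n is the 3x3 genotype count table (dosage at A x dosage at B).
.twoLocusEM <- function(n, tol = 1e-6, maxIter = 1000) {
    nTot <- sum(n)
    ## fixed gamete contributions from unambiguous cells; haplotype order:
    ## 1 = ref/ref (ab), 2 = ref/alt (aB), 3 = alt/ref (Ab), 4 = alt/alt (AB)
    fixed <- c(
        2 * n[1, 1] + n[1, 2] + n[2, 1],            # ab
        2 * n[1, 3] + n[1, 2] + n[2, 3],            # aB
        2 * n[3, 1] + n[2, 1] + n[3, 2],            # Ab
        2 * n[3, 3] + n[3, 2] + n[2, 3])            # AB
    dh <- n[2, 2]                                    # double heterozygotes
    p <- rep(0.25, 4)
    iter <- 0L; converged <- FALSE
    repeat {
        iter <- iter + 1L
        ## E-step: resolve AB/ab vs Ab/aB
        denom <- p[4] * p[1] + p[3] * p[2]
        w <- if (denom > 0) p[4] * p[1] / denom else 0.5
        cnt <- fixed + dh * c(w, 1 - w, 1 - w, w)
        pNew <- cnt / (2 * nTot)
        if (max(abs(pNew - p)) < tol) { p <- pNew; converged <- TRUE; break }
        p <- pNew
        if (iter >= maxIter) break
    }
    list(p = stats::setNames(p, c("ab", "aB", "Ab", "AB")),
         iterations = iter, converged = converged)
}

.ldFromHapFreqs <- function(p) {
    pA <- p["Ab"] + p["AB"]  # alt frequency at locus A
    pB <- p["aB"] + p["AB"]  # alt frequency at locus B
    D <- p["AB"] - pA * pB
    Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    dPrime <- if (Dmax > 0) abs(D) / Dmax else NA_real_
    r2den <- pA * (1 - pA) * pB * (1 - pB)
    r2 <- if (r2den > 0) D^2 / r2den else NA_real_
    list(D = unname(D), dPrime = unname(dPrime), r2 = unname(r2),
         pA = unname(pA), pB = unname(pB))
}

#' Two-locus LD from unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by EM over the
#' double-heterozygote phase ambiguity (tolerance 1e-6, at most 1,000
#' iterations), then derives D, D' (absolute, normalized by the admissible
#' maximum) and r-squared. Individuals with a missing genotype at either
#' locus are excluded.
#'
#' @param x genotyped [StimCohort-class] or variant x individual dosage
#'   matrix.
#' @param pair character vector of two variant ids (same chromosome).
#' @return list with \code{hapFreqs} (sums to 1), \code{D}, \code{dPrime},
#'   \code{r2}, \code{nChromosomes}, \code{emIterations}, \code{converged},
#'   and \code{defined} (FALSE for a monomorphic member, in which case the
#'   LD measures are NA).
#' @export
estimateTwoLocusLD <- function(x, pair) {
    dos <- if (methods::is(x, "StimCohort")) dosageMatrix(x) else x
    stopifnot(length(pair) == 2, all(pair %in% rownames(dos)))
    a <- dos[pair[1], ]; b <- dos[pair[2], ]
    ok <- !is.na(a) & !is.na(b)
    n <- matrix(0L, 3, 3)
    for (i in which(ok)) n[a[i] + 1L, b[i] + 1L] <- n[a[i] + 1L, b[i] + 1L] + 1L
    if (sum(n) == 0) stop("no complete genotype pairs for ", pair[1], "/",
                          pair[2])
    em <- .twoLocusEM(n)
    ld <- .ldFromHapFreqs(em$p)
    mono <- ld$pA %in% c(0, 1) || ld$pB %in% c(0, 1)
    if (mono) ld$dPrime <- ld$r2 <- NA_real_
    list(pair = pair, hapFreqs = em$p, D = ld$D, dPrime = ld$dPrime,
         r2 = ld$r2, nChromosomes = 2L * sum(n),
         emIterations = em$iterations, converged = em$converged,
         defined = !mono)
}

## Likelihood-based confidence bounds on |D'| (Gabriel-style): allele
## frequencies fixed at their EM estimates, |D'| scanned on a grid with a
## flat prior, bounds at the 5th and 95th percentile of the normalized
## likelihood.
.dPrimeCI <- function(n, grid = seq(0, 1, by = 0.005)) {
    em <- .twoLocusEM(n)
    ld <- .ldFromHapFreqs(em$p)
    if (ld$pA %in% c(0, 1) || ld$pB %in% c(0, 1))
        return(c(low = NA_real_, high = NA_real_))
    sgn <- if (ld$D >= 0) 1 else -1
    pA <- ld$pA; pB <- ld$pB
    Dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    ll <- vapply(grid, function(dp) {
        D <- sgn * dp * Dmax
        p <- c(ab = (1 - pA) * (1 - pB) + D, aB = (1 - pA) * pB - D,
               Ab = pA * (1 - pB) - D, AB = pA * pB + D)
        if (any(p < -1e-12)) return(-Inf)
        p <- pmax(p, 1e-12)
        ## genotype cell probabilities under random union of gametes
        gp <- matrix(0, 3, 3)
        hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
        for (i in 1:4) for (j in 1:4) {
            cell <- hap[i, ] + hap[j, ]
            gp[cell[1] + 1, cell[2] + 1] <-
                gp[cell[1] + 1, cell[2] + 1] + p[i] * p[j]
        }
        sum(n * log(gp))
    }, numeric(1))
    w <- exp(ll - max(ll))
    cdf <- cumsum(w) / sum(w)
    c(low = grid[which(cdf >= 0.05)[1]], high = grid[which(cdf >= 0.95)[1]])
}

## pairwise statistics for a set of variants (rows of dos, genome order)
.pairwiseLD <- function(dos, needCI = FALSE) {
    m <- nrow(dos)
    ids <- rownames(dos)
    dP <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    fourth <- matrix(NA, m, m)      # all four haplotypes >= floor?
    ciLow <- ciHigh <- matrix(NA_real_, m, m)
    minFreq <- matrix(NA_real_, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        ld <- estimateTwoLocusLD(dos, c(ids[i], ids[j]))
        dP[i, j] <- dP[j, i] <- ld$dPrime
        minFreq[i, j] <- minFreq[j, i] <- min(ld$hapFreqs)
        if (needCI) {
            a <- dos[i, ]; b <- dos[j, ]
            ok <- !is.na(a) & !is.na(b)
            n <- matrix(0L, 3, 3)
            for (k in which(ok))
                n[a[k] + 1L, b[k] + 1L] <- n[a[k] + 1L, b[k] + 1L] + 1L
            ci <- .dPrimeCI(n)
            ciLow[i, j] <- ciLow[j, i] <- ci["low"]
            ciHigh[i, j] <- ciHigh[j, i] <- ci["high"]
        }
    }
    list(dPrime = dP, minHapFreq = minFreq, ciLow = ciLow, ciHigh = ciHigh)
}

#' Detect haplotype blocks
#'
#' Finds contiguous runs of panel variants (per chromosome, in genome order,
#' after a minor-allele-frequency filter) with little evidence of historical
#' recombination, by one of three rules with conventional defaults:
#' \describe{
#'   \item{four-gamete}{a pair is recombinant when all four two-locus
#'     haplotypes have EM frequency at or above \code{fourGameteFloor}
#'     (0.01); blocks are maximal runs with no recombinant internal pair.}
#'   \item{confidence-intervals}{Gabriel-style: a pair is in strong LD when
#'     the likelihood bounds on |D'| satisfy lower >= \code{ciStrongLow}
#'     (0.70) and upper >= \code{ciStrongHigh} (0.98); it shows strong
#'     recombination when the upper bound < \code{ciRecombHigh} (0.90); a
#'     run is a block when at least \code{ciInformativeFraction} (0.95) of
#'     its informative pairs are strong.}
#'   \item{solid-spine}{maximal runs whose first and last variant have
#'     |D'| >= \code{spineDPrime} (0.80) with each other and with every
#'     variant between them.}
#' }
#' Variants not captured by any multi-variant run are reported as singleton
#' blocks. Per-block haplotypes and frequencies are estimated by multi-locus
#' EM ([blockHaplotypeFrequencies()]).
#'
#' @param x genotyped [StimCohort-class] (variants must be sorted by
#'   chromosome and position; unsorted input is an error).
#' @param method one of \code{"four-gamete"}, \code{"confidence-intervals"},
#'   \code{"solid-spine"}.
#' @param maf minor-allele-frequency filter (default 0.05).
#' @param fourGameteFloor,ciStrongLow,ciStrongHigh,ciRecombHigh,
#'   ciInformativeFraction,spineDPrime rule thresholds, see above.
#' @param haplotypes also estimate per-block haplotype frequencies
#'   (default TRUE).
#' @return list of blocks; each block is a list with \code{method},
#'   \code{chromosome}, \code{variants} (ids, contiguous in genome order),
#'   and, when requested, \code{haplotypes} (data.frame with columns
#'   \code{haplotype} — an alt-presence string — and \code{frequency}).
#' @export
detectBlocks <- function(x,
                         method = c("four-gamete", "confidence-intervals",
                                    "solid-spine"),
                         maf = 0.05, fourGameteFloor = 0.01,
                         ciStrongLow = 0.70, ciStrongHigh = 0.98,
                         ciRecombHigh = 0.90, ciInformativeFraction = 0.95,
                         spineDPrime = 0.80, haplotypes = TRUE) {
    method <- match.arg(method)
    stopifnot(methods::is(x, "StimCohort"), nrow(x) > 0)
    panel <- variantPanel(x)
    ordered <- order(panel$chromosome, panel$position)
    if (!identical(ordered, seq_len(nrow(panel))))
        stop("panel variants must be sorted by chromosome and position")
    dosAll <- dosageMatrix(x)
    af <- rowMeans(dosAll, na.rm = TRUE) / 2
    keep <- pmin(af, 1 - af) >= maf
    blocks <- list()
    for (chrom in unique(panel$chromosome[keep])) {
        idx <- which(keep & panel$chromosome == chrom)
        ids <- panel$variant_id[idx]
        m <- length(ids)
        if (m == 1) {
            blocks[[length(blocks) + 1L]] <-
                list(method = method, chromosome = chrom, variants = ids)
            next
        }
        dos <- dosAll[ids, , drop = FALSE]
        ld <- .pairwiseLD(dos, needCI = method == "confidence-intervals")
        runs <- switch(method,
            `four-gamete` = .runsFourGamete(ld, fourGameteFloor),
            `solid-spine` = .runsSolidSpine(ld, spineDPrime),
            `confidence-intervals` = .runsGabriel(ld, ciStrongLow,
                                                  ciStrongHigh, ciRecombHigh,
                                                  ciInformativeFraction))
        covered <- rep(FALSE, m)
        for (r in runs) covered[r[1]:r[2]] <- TRUE
        for (i in which(!covered)) runs <- c(runs, list(c(i, i)))
        runs <- runs[order(vapply(runs, `[`, numeric(1), 1))]
        for (r in runs)
            blocks[[length(blocks) + 1L]] <-
                list(method = method, chromosome = chrom,
                     variants = ids[r[1]:r[2]])
    }
    if (haplotypes)
        for (b in seq_along(blocks))
            blocks[[b]]$haplotypes <-
                blockHaplotypeFrequencies(dosAll[blocks[[b]]$variants, ,
                                                 drop = FALSE])
    blocks
}

## maximal runs, scanning left to right, validity hereditary in all three
## rules so the greedy extension yields the unique maximal partition
.maximalRuns <- function(m, validInterval) {
    runs <- list(); i <- 1
    while (i <= m) {
        j <- i
        while (j < m && validInterval(i, j + 1)) j <- j + 1
        if (j > i) runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1
    }
    runs
}

.runsFourGamete <- function(ld, floor) {
    recomb <- !is.na(ld$minHapFreq) & ld$minHapFreq >= floor
    m <- nrow(recomb)
    .maximalRuns(m, function(i, j) !any(recomb[i:j, i:j]))
}

.runsSolidSpine <- function(ld, thr) {
    dP <- ld$dPrime
    m <- nrow(dP)
    ok <- function(i, j) {
        if (is.na(dP[i, j]) || dP[i, j] < thr) return(FALSE)
        if (j - i >= 2) {
            ks <- (i + 1):(j - 1)
            if (any(is.na(dP[i, ks])) || any(dP[i, ks] < thr)) return(FALSE)
            if (any(is.na(dP[ks, j])) || any(dP[ks, j] < thr)) return(FALSE)
        }
        TRUE
    }
    ## not hereditary in i for fixed j, so enumerate maximal valid intervals
    .nonOverlappingIntervals(m, ok)
}

.runsGabriel <- function(ld, low, high, recombHigh, frac) {
    strong <- !is.na(ld$ciLow) & ld$ciLow >= low & ld$ciHigh >= high
    recomb <- !is.na(ld$ciHigh) & ld$ciHigh < recombHigh
    m <- nrow(strong)
    ok <- function(i, j) {
        sub <- i:j
        s <- strong[sub, sub][upper.tri(diag(j - i + 1))]
        r <- recomb[sub, sub][upper.tri(diag(j - i + 1))]
        inf <- sum(s) + sum(r)
        inf > 0 && sum(s) / inf >= frac && strong[i, j]
    }
    .nonOverlappingIntervals(m, ok)
}

## longest-first selection of non-overlapping valid intervals (>= 2 variants)
.nonOverlappingIntervals <- function(m, ok) {
    cand <- list()
    for (len in m:2) for (i in seq_len(m - len + 1)) {
        j <- i + len - 1
        if (ok(i, j)) cand[[length(cand) + 1L]] <- c(i, j)
    }
    runs <- list()
    taken <- rep(FALSE, m)
    for (r in cand) {
        if (!any(taken[r[1]:r[2]])) {
            runs[[length(runs) + 1L]] <- r
            taken[r[1]:r[2]] <- TRUE
        }
    }
    runs
}

#' Multi-locus haplotype frequencies for one block
#'
#' EM over per-individual phase ambiguity: each individual's compatible
#' (unordered) haplotype pairs are enumerated from its heterozygous sites and
#' weighted by current frequency estimates. Exhaustive for blocks of up to 12
#' variants; longer blocks are handled by partition-ligation (halve the
#' block, estimate each half, retain the most frequent half-haplotypes, run
#' EM over their combinations). Individuals with a missing genotype inside
#' the block are excluded.
#'
#' @param dos variant x individual dosage matrix restricted to the block.
#' @param tol,maxIter EM controls.
#' @param plKeep half-haplotypes retained per side in partition-ligation.
#' @return data.frame with \code{haplotype} (alt-presence string over the
#'   block variants, e.g. \code{"010"}) and \code{frequency}, sorted by
#'   decreasing frequency; frequencies sum to 1 (up to pooling of haplotypes
#'   dropped by partition-ligation).
#' @export
blockHaplotypeFrequencies <- function(dos, tol = 1e-6, maxIter = 1000,
                                      plKeep = 8) {
    m <- nrow(dos)
    ok <- colSums(is.na(dos)) == 0
    dos <- dos[, ok, drop = FALSE]
    if (ncol(dos) == 0) stop("no complete individuals in block")
    if (m <= 12) return(.hapEM(dos, tol, maxIter))
    ## partition-ligation
    half <- floor(m / 2)
    left <- blockHaplotypeFrequencies(dos[1:half, , drop = FALSE], tol,
                                      maxIter, plKeep)
    right <- blockHaplotypeFrequencies(dos[(half + 1):m, , drop = FALSE],
                                       tol, maxIter, plKeep)
    keepL <- utils::head(left$haplotype, plKeep)
    keepR <- utils::head(right$haplotype, plKeep)
    allowed <- as.vector(outer(keepL, keepR, paste0))
    .hapEM(dos, tol, maxIter, allowed = allowed)
}

.hapString <- function(bits) paste(bits, collapse = "")

.compatiblePairs <- function(g, allowed = NULL) {
    ## g: dosage vector for one individual; returns list of c(hap1, hap2)
    het <- which(g == 1L)
    base <- ifelse(g == 2L, 1L, 0L)
    if (length(het) == 0) {
        pairs <- list(c(.hapString(base), .hapString(base)))
    } else {
        h <- length(het)
        pairs <- vector("list", 2^(h - 1))
        for (s in 0:(2^(h - 1) - 1)) {
            sel <- as.integer(intToBits(s))[seq_len(h)]
            sel[h] <- 0L  # fix last het site to break pair symmetry
            h1 <- base; h1[het] <- sel
            h2 <- base; h2[het] <- 1L - sel
            pairs[[s + 1]] <- c(.hapString(h1), .hapString(h2))
        }
    }
    if (!is.null(allowed))
        pairs <- Filter(function(pr) all(pr %in% allowed), pairs)
    pairs
}

.hapEM <- function(dos, tol, maxIter, allowed = NULL) {
    nInd <- ncol(dos)
    pairsByInd <- lapply(seq_len(nInd),
                         function(i) .compatiblePairs(dos[, i], allowed))
    drop <- lengths(pairsByInd) == 0
    pairsByInd <- pairsByInd[!drop]
    haps <- sort(unique(unlist(pairsByInd)))
    p <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
    iter <- 0L
    repeat {
        iter <- iter + 1L
        cnt <- stats::setNames(rep(0, length(haps)), haps)
        for (prs in pairsByInd) {
            w <- vapply(prs, function(pr) {
                pp <- p[pr[1]] * p[pr[2]]
                if (pr[1] != pr[2]) 2 * pp else pp
            }, numeric(1))
            if (sum(w) == 0) w <- rep(1, length(prs))
            w <- w / sum(w)
            for (k in seq_along(prs)) {
                cnt[prs[[k]][1]] <- cnt[prs[[k]][1]] + w[k]
                cnt[prs[[k]][2]] <- cnt[prs[[k]][2]] + w[k]
            }
        }
        pNew <- cnt / sum(cnt)
        if (max(abs(pNew - p)) < tol || iter >= maxIter) { p <- pNew; break }
        p <- pNew
    }
    out <- data.frame(haplotype = names(p), frequency = unname(p),
                      row.names = NULL)
    out <- out[order(-out$frequency, out$haplotype), ]
    rownames(out) <- NULL
    out
}

#' Screen block haplotypes for predictive impact
#'
#' Every block haplotype at or above the frequency floor becomes a candidate
#' binary feature: a process carries the haplotype when its alt-presence
#' pattern over the block variants matches the haplotype's allele string
#' (missing genotypes propagate to missing). Candidates are scored by the
#' supplied callback (cross-validated RMSE with a fixed fold assignment) and
#' ranked by RMSE reduction against the clinical-only model.
#'
#' @param blocks result of [detectBlocks()] with haplotypes.
#' @param cohort the genotyped [StimCohort-class].
#' @param evaluate function(values, name) -> CV RMSE of the model with the
#'   candidate feature added; \code{evaluate(NULL)} must return the
#'   clinical-only reference RMSE.
#' @param freqFloor candidate frequency floor (default 0.05).
#' @return data.frame ranked by decreasing RMSE reduction, with the
#'   corresponding \code{ReducedHaplotype} objects in attribute
#'   \code{"features"}.
#' @export
screenHaplotypes <- function(blocks, cohort, evaluate, freqFloor = 0.05) {
    ap <- altPresence(cohort)
    base <- evaluate(NULL)
    rows <- list(); feats <- list()
    for (bi in seq_along(blocks)) {
        blk <- blocks[[bi]]
        if (is.null(blk$haplotypes) || length(blk$variants) < 2) next
        hp <- blk$haplotypes[blk$haplotypes$frequency >= freqFloor, ,
                             drop = FALSE]
        for (hi in seq_len(nrow(hp))) {
            states <- as.integer(strsplit(hp$haplotype[hi], "")[[1]])
            name <- sprintf("block%d.%s", bi, hp$haplotype[hi])
            feat <- methods::new("ReducedHaplotype", name = name,
                                 variantIds = blk$variants,
                                 baseline = states,
                                 frequency = hp$frequency[hi])
            val <- evaluateFeature(feat, ap)
            rmse <- evaluate(val, name)
            rows[[length(rows) + 1L]] <-
                data.frame(block = bi, haplotype = hp$haplotype[hi],
                           frequency = hp$frequency[hi], cv_rmse = rmse,
                           rmse_reduction = base - rmse, name = name)
            feats[[name]] <- feat
        }
    }
    if (!length(rows)) {
        message("no candidate haplotypes above the frequency floor")
        out <- data.frame()
    } else {
        out <- do.call(rbind, rows)
        out <- out[order(-out$rmse_reduction, out$name), ]
        rownames(out) <- NULL
        if (all(out$rmse_reduction <= 0))
            message("no candidate haplotype reduces the clinical-only RMSE")
    }
    attr(out, "features") <- feats
    attr(out, "baselineRmse") <- base
    out
}

#' Reduce a haplotype block to a binary decision-tree feature
#'
#' Embeds the per-process alt-presence vectors over the block variants into
#' two dimensions (classical metric MDS on Manhattan/Hamming distances, a
#' deterministic embedding), clusters the embedding with K-means selecting k
#' in \code{kRange} by mean silhouette width, grows a classification tree to
#' purity predicting the cluster labels from the variants, and takes the
#' root-to-leaf path for the leaf capturing the largest cluster. The path
#' variants, with the allele states of the path's split sides, define the
#' reduced haplotype: value 1 iff every path variant matches its baseline
#' state (Eq.-style binary indicator), missing propagates.
#'
#' If the embedding is degenerate (all block genotype vectors identical) the
#' reduction is impossible and the modal alt-presence pattern over the full
#' block is returned as the feature, with a warning.
#'
#' @param blockVariants variant ids of the block (>= 2).
#' @param x genotyped [StimCohort-class] or alt-presence matrix.
#' @param name feature name.
#' @param kRange candidate cluster numbers (default 2:10).
#' @param seed seed for K-means restarts (embedding and tree are
#'   deterministic).
#' @return a \code{ReducedHaplotype} with the empirical frequency of value 1
#'   on the defining cohort; the chosen k, silhouette widths and cluster
#'   sizes are attached as attributes.
#' @export
reduceHaplotype <- function(blockVariants, x, name = "IVreduced",
                            kRange = 2:10, seed = 1) {
    stopifnot(length(blockVariants) >= 2)
    ap <- if (methods::is(x, "StimCohort")) altPresence(x) else as.matrix(x)
    stopifnot(all(blockVariants %in% colnames(ap)))
    sub <- ap[, blockVariants, drop = FALSE]
    complete <- stats::complete.cases(sub)
    subC <- sub[complete, , drop = FALSE]
    patterns <- apply(subC, 1, paste, collapse = "")
    if (length(unique(patterns)) < 2) {
        warning("degenerate embedding: all block genotypes identical; ",
                "returning the modal pattern over the full block")
        modal <- as.integer(strsplit(names(which.max(table(patterns))),
                                     "")[[1]])
        feat <- methods::new("ReducedHaplotype", name = name,
                             variantIds = blockVariants, baseline = modal,
                             frequency = NA_real_)
        v <- evaluateFeature(feat, ap)
        feat@frequency <- mean(v, na.rm = TRUE)
        return(feat)
    }
    dd <- stats::dist(subC, method = "manhattan")
    emb <- stats::cmdscale(dd, k = min(2, nrow(subC) - 1))
    if (ncol(emb) == 1) emb <- cbind(emb, 0)
    kMax <- min(max(kRange), length(unique(patterns)), nrow(subC) - 1)
    ks <- kRange[kRange <= kMax]
    sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
    fits <- list()
    withr::with_seed(seed, {
        for (i in seq_along(ks)) {
            km <- stats::kmeans(emb, centers = ks[i], nstart = 10,
                                iter.max = 100, algorithm = "Lloyd")
            fits[[i]] <- km
            sw <- cluster::silhouette(km$cluster, dd)
            sil[i] <- mean(sw[, "sil_width"])
        }
    })
    kBest <- which.max(sil)
    clu <- factor(fits[[kBest]]$cluster)
    df <- data.frame(.cluster = clu, subC, check.names = FALSE)
    tree <- rpart::rpart(.cluster ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                             cp = 0, minsplit = 2, minbucket = 1,
                             xval = 0, maxdepth = 30))
    frame <- tree$frame
    leaves <- which(frame$var == "<leaf>")
    largest <- names(which.max(table(clu)))
    predClass <- levels(clu)[frame$yval]
    target <- leaves[predClass[leaves] == largest]
    if (!length(target)) target <- leaves  # safety: purity should prevent
    target <- target[which.max(frame$n[target])]
    node <- as.integer(rownames(frame)[target])
    pth <- rpart::path.rpart(tree, nodes = node, print.it = FALSE)[[1]]
    pth <- pth[-1]  # drop "root"
    if (!length(pth)) {
        warning("tree has no splits; returning modal pattern")
        modal <- as.integer(strsplit(names(which.max(table(patterns))),
                                     "")[[1]])
        feat <- methods::new("ReducedHaplotype", name = name,
                             variantIds = blockVariants, baseline = modal,
                             frequency = NA_real_)
    } else {
        vars <- sub("[<>]=?.*$", "", pth)
        state <- ifelse(grepl(">=", pth), 1L, 0L)
        keep <- !duplicated(vars)
        feat <- methods::new("ReducedHaplotype", name = name,
                             variantIds = vars[keep],
                             baseline = state[keep],
                             frequency = NA_real_)
    }
    v <- evaluateFeature(feat, ap)
    feat@frequency <- mean(v, na.rm = TRUE)
    attr(feat, "k") <- ks[kBest]
    attr(feat, "silhouette") <- sil
    attr(feat, "clusterSizes") <- as.integer(table(clu))
    feat
}

#' @describeIn evaluateFeature binary reduced-haplotype indicator: 1 iff all
#'   path variants match their baseline alt-presence state; a missing
#'   genotype at any path variant yields NA.
#' @export
setMethod("evaluateFeature", signature("ReducedHaplotype", "StimCohort"),
          function(feature, cohort, ...) {
    evaluateFeature(feature, altPresence(cohort))
})

#' @describeIn evaluateFeature reduced haplotype on a raw matrix.
#' @export
setMethod("evaluateFeature", signature("ReducedHaplotype", "matrix"),
          function(feature, cohort, ...) {
    idx <- match(feature@variantIds, colnames(cohort))
    if (anyNA(idx))
        stop("path variant(s) absent from genotype matrix: ",
             paste(feature@variantIds[is.na(idx)], collapse = ", "))
    sub <- cohort[, idx, drop = FALSE]
    target <- matrix(feature@baseline, nrow(sub), length(idx), byrow = TRUE)
    eq <- sub == target
    out <- as.integer(rowSums(eq) == length(idx))
    out[apply(is.na(eq), 1, any)] <- NA_integer_
    out
})
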