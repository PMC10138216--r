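## Self-organizing map over binary genotype vectors, node enrichment for MII
## outcome groups, exhaustive subset search, and the standardized count
## feature frozen on the defining cohort.

#' SOM configuration
#'
#' Defaults: a 6x6 hexagonal grid, Gaussian neighborhood with initial sigma
#' 1.5, initial learning rate 0.7, 100,000 online training iterations and
#' the Manhattan distance. Sigma and learning rate decay linearly to a small
#' floor over the iteration budget (the decay schedule is an implementation
#' default; only the initial values are prescribed).
#'
#' @param gridDim integer c(nx, ny).
#' @param sigma initial Gaussian neighborhood radius (grid units).
#' @param learningRate initial online learning rate.
#' @param iterations number of online updates.
#' @param seed mandatory seed (weight initialisation and sample order).
#' @return config list for [trainSOM()].
#' @export
somConfig <- function(gridDim = c(6L, 6L), sigma = 1.5, learningRate = 0.7,
                      iterations = 100000L, seed) {
    if (missing(seed)) stop("somConfig needs an explicit seed")
    stopifnot(all(gridDim >= 1), sigma > 0, iterations >= 1)
    list(gridDim = as.integer(gridDim), sigma = sigma,
         learningRate = learningRate, iterations = as.integer(iterations),
         seed = as.integer(seed))
}

## hexagonal grid distances: odd-r offset coordinates -> cube coordinates,
## distance = (|dx| + |dy| + |dz|) / 2
.hexNodeDistances <- function(gridDim) {
    nx <- gridDim[1]; ny <- gridDim[2]
    col <- rep(seq_len(nx) - 1L, times = ny)
    row <- rep(seq_len(ny) - 1L, each = nx)
    cx <- col - (row - row %% 2L) / 2
    cz <- row
    cy <- -cx - cz
    nn <- nx * ny
    D <- matrix(0, nn, nn)
    for (i in seq_len(nn))
        D[i, ] <- (abs(cx - cx[i]) + abs(cy - cy[i]) + abs(cz - cz[i])) / 2
    attr(D, "coords") <- cbind(x = col, y = row)
    D
}

#' Train a self-organizing map on genotype vectors
#'
#' Online Kohonen training: at each iteration one observation is drawn, its
#' best matching unit (BMU, the node with the smallest Manhattan distance) is
#' found, and every node weight moves toward the observation with a Gaussian
#' neighborhood factor centred on the BMU. Missing alt-presence values are
#' imputed to 0 for map training only (reported via message); downstream
#' feature evaluation keeps missing as missing. The quantization error (QE)
#' is the mean BMU distance over the full data set after training.
#'
#' @param x processes x variants alt-presence matrix, or a genotyped
#'   [StimCohort-class].
#' @param config a [somConfig()].
#' @return a [SomModel-class].
#' @export
trainSOM <- function(x, config) {
    ap <- if (methods::is(x, "StimCohort")) altPresence(x) else as.matrix(x)
    nMissing <- sum(is.na(ap))
    if (nMissing > 0) {
        message("SOM input: ", nMissing,
                " missing genotype value(s) imputed to 0 for training only")
        ap[is.na(ap)] <- 0L
    }
    if (nrow(unique(ap)) == 1L)
        warning("all SOM input rows identical; map will collapse (QE ~ 0)")
    n <- nrow(ap); p <- ncol(ap)
    D <- .hexNodeDistances(config$gridDim)
    nn <- nrow(D)
    iters <- config$iterations
    withr::with_seed(config$seed, {
        W <- matrix(stats::runif(nn * p), nn, p)
        sampleIdx <- sample.int(n, iters, replace = TRUE)
        for (t in seq_len(iters)) {
            frac <- 1 - (t - 1) / iters
            sig <- max(config$sigma * frac, 0.05)
            lr <- max(config$learningRate * frac, 1e-3)
            M <- matrix(ap[sampleIdx[t], ], nn, p, byrow = TRUE)
            dist <- rowSums(abs(W - M))
            bmu <- which.min(dist)
            h <- lr * exp(-D[bmu, ]^2 / (2 * sig^2))
            W <- W + h * (M - W)
        }
    })
    colnames(W) <- colnames(ap)
    ## BMU and QE on the full data set
    bmu <- integer(n); bmuDist <- numeric(n)
    for (i in seq_len(n)) {
        dist <- rowSums(abs(W - matrix(ap[i, ], nn, p, byrow = TRUE)))
        bmu[i] <- which.min(dist)
        bmuDist[i] <- dist[bmu[i]]
    }
    methods::new("SomModel", weights = W, gridDim = config$gridDim,
                 bmu = bmu, qe = mean(bmuDist), config = config)
}

setMethod("show", "SomModel", function(object) {
    cat(sprintf("SomModel %dx%d hexagonal grid over %d variables\n",
                object@gridDim[1], object@gridDim[2], ncol(object@weights)))
    cat(sprintf("  %d observations mapped, quantization error %.4f\n",
                length(object@bmu), object@qe))
    invisible(NULL)
})

#' Node coordinates of a SOM grid
#' @param model a [SomModel-class].
#' @return matrix of (x, y) offset coordinates, one row per node.
#' @export
somNodeCoords <- function(model) {
    attr(.hexNodeDistances(model@gridDim), "coords")
}

#' Outcome-group enrichment per SOM node
#'
#' For each occupied node, computes the share of each MII group among the
#' observations mapped there and compares it with the population share. A
#' node is enriched for a group when its share is at least
#' \code{enrichmentRatio} times the population share and the node holds at
#' least \code{minNodeSize} observations (both thresholds are conventions of
#' this package; "over-represented" is not quantified in the source method).
#' For enriched nodes the characteristic variants are ranked by percentage
#' difference: alt-presence frequency within the node minus the population
#' frequency; the \code{topM} largest differences are reported.
#'
#' @param model a [SomModel-class] trained on the same observations.
#' @param partition [binMiiCounts()] result.
#' @param x the alt-presence matrix (or cohort) the map was trained on.
#' @param topM characteristic variants per enriched node (default 10).
#' @param enrichmentRatio,minNodeSize enrichment rule knobs.
#' @return list of per-node records: node index, grid coords, size, group
#'   shares, population shares, enriched groups, characteristic-variant
#'   data.frame (empty unless enriched).
#' @export
nodeEnrichment <- function(model, partition, x, topM = 10,
                           enrichmentRatio = 2, minNodeSize = 10) {
    ap <- if (methods::is(x, "StimCohort")) altPresence(x) else as.matrix(x)
    stopifnot(length(model@bmu) == nrow(ap),
              length(partition$assignment) == nrow(ap))
    groups <- partition$labels
    popShare <- as.numeric(table(partition$assignment)[groups]) /
        nrow(ap)
    names(popShare) <- groups
    popFreq <- colMeans(ap, na.rm = TRUE)
    coords <- somNodeCoords(model)
    out <- list()
    for (node in sort(unique(model@bmu))) {
        inNode <- model@bmu == node
        size <- sum(inNode)
        share <- as.numeric(table(partition$assignment[inNode])[groups])
        share[is.na(share)] <- 0
        share <- share / size
        names(share) <- groups
        enriched <- groups[share >= enrichmentRatio * popShare &
                           size >= minNodeSize & popShare > 0]
        vars <- data.frame(variant_id = character(0), node_freq = numeric(0),
                           pop_freq = numeric(0), pct_diff = numeric(0))
        if (length(enriched)) {
            nodeFreq <- colMeans(ap[inNode, , drop = FALSE], na.rm = TRUE)
            diff <- nodeFreq - popFreq
            ord <- order(-diff, names(diff))[seq_len(min(topM, length(diff)))]
            vars <- data.frame(variant_id = names(diff)[ord],
                               node_freq = unname(nodeFreq[ord]),
                               pop_freq = unname(popFreq[ord]),
                               pct_diff = unname(diff[ord]),
                               row.names = NULL)
        }
        out[[length(out) + 1L]] <-
            list(node = node, coords = coords[node, ], size = size,
                 groupShares = share, populationShares = popShare,
                 enrichedFor = enriched, characteristicVariants = vars)
    }
    out
}

#' Exhaustive subset search over candidate variants
#'
#' Enumerates every non-empty subset of the candidates (up to
#' \code{maxSize}), scores each with the supplied callback (typically the
#' cross-validated RMSE of the predictive model including the candidate
#' feature, with a fixed fold assignment) and returns the minimizer. Ties go
#' to the smaller subset, then lexicographic order. Bounded at 15 candidates
#' (32,767 evaluations) by design.
#'
#' @param candidates character vector of variant ids (length 1-15).
#' @param evaluate function(variantIds) -> numeric score (lower is better).
#' @param maxSize largest subset size considered (default: all sizes).
#' @return list with \code{best} (character vector), \code{score} and
#'   \code{trace} (data.frame of every evaluated subset, in evaluation
#'   order).
#' @export
subsetSearch <- function(candidates, evaluate, maxSize = NULL) {
    stopifnot(length(candidates) >= 1)
    if (length(candidates) > 15)
        stop("more than 15 candidates: exhaustive enumeration refused")
    if (is.null(maxSize)) maxSize <- length(candidates)
    candidates <- sort(candidates)
    subsets <- list()
    for (size in seq_len(maxSize))
        subsets <- c(subsets,
                     utils::combn(candidates, size, simplify = FALSE))
    scores <- vapply(subsets, evaluate, numeric(1))
    keys <- vapply(subsets, paste, character(1), collapse = "+")
    sizes <- lengths(subsets)
    ord <- order(scores, sizes, keys)
    best <- subsets[[ord[1]]]
    list(best = best, score = scores[ord[1]],
         trace = data.frame(subset = keys, size = sizes, score = scores,
                            row.names = NULL))
}

#' Build the standardized count feature
#'
#' The raw value is the per-process count of member variants carried as
#' alternative; the standardized value subtracts the population mean and
#' divides by the population (1/n) standard deviation, both frozen on the
#' defining cohort and reused verbatim for any new data.
#'
#' @param variants member variant ids (e.g. the winning [subsetSearch()]
#'   subset).
#' @param x defining cohort ([StimCohort-class]) or alt-presence matrix.
#' @param name feature name (default \code{"IV8-6"}).
#' @return a \code{StandardizedCountFeature}.
#' @export
buildStandardizedFeature <- function(variants, x, name = "IV8-6") {
    ap <- if (methods::is(x, "StimCohort")) altPresence(x) else as.matrix(x)
    raw <- evaluateFeature(methods::new("CountFeature", name = name,
                                        variantIds = variants), ap)
    ok <- !is.na(raw)
    m <- mean(raw[ok])
    s <- sqrt(mean((raw[ok] - m)^2))
    if (!is.finite(s) || s <= 0)
        stop("degenerate feature: zero variance on the defining cohort")
    methods::new("StandardizedCountFeature", name = name,
                 variantIds = variants, center = m, scale = s)
}

#' @describeIn evaluateFeature standardized count: (count - center) / scale
#'   with frozen constants; NA when any member genotype is missing.
#' @export
setMethod("evaluateFeature",
          signature("StandardizedCountFeature", "StimCohort"),
          function(feature, cohort, ...) {
    evaluateFeature(feature, altPresence(cohort))
})

#' @describeIn evaluateFeature standardized count on a raw matrix.
#' @export
setMethod("evaluateFeature", signature("StandardizedCountFeature", "matrix"),
          function(feature, cohort, ...) {
    raw <- evaluateFeature(methods::new("CountFeature", name = feature@name,
                                        variantIds = feature@variantIds),
                           cohort)
    (raw - feature@center) / feature@scale
})
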