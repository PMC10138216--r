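## Correspondence analysis of the variant x MII-group carrier table, and the
## count-type genetic feature built from variants proximal to a target group.

#' Build the variant-by-group carrier contingency table
#'
#' Entry (v, g) counts the processes in MII group g that carry at least one
#' alternative allele at variant v; processes with a missing genotype at v
#' are excluded from that cell. Empty groups are retained (with a warning),
#' all-zero variant rows are flagged in the \code{"zero_rows"} attribute.
#'
#' @param cohort a genotyped [StimCohort-class].
#' @param partition result of [binMiiCounts()] over the same processes.
#' @param variants candidate variant ids (subset of the panel).
#' @return integer matrix, rows = variants, columns = the five MII groups.
#' @export
buildContingency <- function(cohort, partition, variants) {
    ap <- altPresence(cohort)
    stopifnot(all(variants %in% colnames(ap)),
              length(partition$assignment) == nrow(ap))
    groups <- partition$labels
    tab <- matrix(0L, length(variants), length(groups),
                  dimnames = list(variants, groups))
    for (g in groups) {
        inG <- partition$assignment == g
        if (!any(inG)) {
            warning("empty MII group: ", g)
            next
        }
        tab[, g] <- colSums(ap[inG, variants, drop = FALSE] == 1L,
                            na.rm = TRUE)
    }
    zero <- rownames(tab)[rowSums(tab) == 0]
    if (length(zero)) attr(tab, "zero_rows") <- zero
    tab
}

#' Fit correspondence analysis
#'
#' Classical CA of a two-way table: the correspondence matrix is centred by
#' row and column masses, the standardized residuals are decomposed by SVD,
#' and rows and columns are both reported in principal coordinates (symmetric
#' map). Total inertia equals the Pearson chi-square of the table divided by
#' its grand total; the proportion of inertia per dimension is the squared
#' singular value over the total.
#'
#' Note the classical caveat of the symmetric map: row-to-column distances
#' are not chi-square distances in a strict sense, but row and column points
#' close together do correspond to strongly associated categories, which is
#' what the proximity rule of [selectProximalVariants()] uses.
#'
#' @param tab nonnegative matrix with at least two non-degenerate rows and
#'   columns (zero rows/columns are dropped with a warning).
#' @return a [CAResult-class].
#' @export
fitCA <- function(tab) {
    tab <- as.matrix(tab)
    keepR <- rowSums(tab) > 0
    keepC <- colSums(tab) > 0
    if (!all(keepR) || !all(keepC)) {
        warning("dropping ", sum(!keepR), " zero row(s) and ",
                sum(!keepC), " zero column(s) before CA")
        tab <- tab[keepR, keepC, drop = FALSE]
    }
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("CA needs at least 2 non-degenerate rows and columns")
    n <- sum(tab)
    P <- tab / n
    r <- rowSums(P)
    c <- colSums(P)
    S <- diag(1 / sqrt(r)) %*% (P - outer(r, c)) %*% diag(1 / sqrt(c))
    sv <- svd(S)
    pos <- sv$d > 1e-12
    d <- sv$d[pos]
    if (!length(d)) {  # perfect independence
        return(methods::new("CAResult",
                            rowCoord = matrix(0, nrow(tab), 0,
                                              dimnames = list(rownames(tab),
                                                              NULL)),
                            colCoord = matrix(0, ncol(tab), 0,
                                              dimnames = list(colnames(tab),
                                                              NULL)),
                            singularValues = numeric(0),
                            totalInertia = 0, inertiaProp = numeric(0)))
    }
    U <- sv$u[, pos, drop = FALSE]
    V <- sv$v[, pos, drop = FALSE]
    rowPC <- diag(1 / sqrt(r)) %*% U %*% diag(d, length(d))
    colPC <- diag(1 / sqrt(c)) %*% V %*% diag(d, length(d))
    dimnames(rowPC) <- list(rownames(tab), paste0("Dim", seq_along(d)))
    dimnames(colPC) <- list(colnames(tab), paste0("Dim", seq_along(d)))
    methods::new("CAResult", rowCoord = rowPC, colCoord = colPC,
                 singularValues = d, totalInertia = sum(d^2),
                 inertiaProp = d^2 / sum(d^2))
}

setMethod("show", "CAResult", function(object) {
    cat("CAResult:", nrow(object@rowCoord), "row points,",
        nrow(object@colCoord), "column points\n")
    cat(sprintf("  total inertia (chi-square/n): %.4f\n",
                object@totalInertia))
    if (length(object@inertiaProp))
        cat("  inertia explained:",
            paste(sprintf("%.1f%%", 100 * utils::head(object@inertiaProp, 3)),
                  collapse = ", "), "...\n")
    invisible(NULL)
})

#' Select variants proximal to a target MII group
#'
#' Ranks variants by Euclidean distance, in the plane of the first two
#' principal-coordinate dimensions, between each variant's row point and the
#' target group's column point; the k nearest variants define a
#' [GeneticFeature-class] of count type (number of member variants carried as
#' alternative). Ties in distance are broken by variant id. The selection is
#' invariant to joint reflection or rotation of the coordinate system, which
#' is arbitrary in CA.
#'
#' @param ca a [CAResult-class].
#' @param targetGroup column label, e.g. \code{">11"}.
#' @param k number of variants to select (default 3).
#' @param name feature name (default \code{"IV-CA"}).
#' @return a \code{CountFeature}; the full distance table is attached as
#'   attribute \code{"distances"}.
#' @export
selectProximalVariants <- function(ca, targetGroup, k = 3, name = "IV-CA") {
    stopifnot(methods::is(ca, "CAResult"))
    if (!targetGroup %in% rownames(ca@colCoord))
        stop("no column coordinates for group ", targetGroup)
    ndim <- min(2L, ncol(ca@rowCoord))
    if (ndim == 0) stop("CA result has no dimensions (independence)")
    rc <- ca@rowCoord[, seq_len(ndim), drop = FALSE]
    tc <- ca@colCoord[targetGroup, seq_len(ndim)]
    d <- sqrt(rowSums((rc - matrix(tc, nrow(rc), ndim, byrow = TRUE))^2))
    ord <- order(d, names(d))
    if (length(d) < k) {
        warning("only ", length(d), " variants available; returning all")
        k <- length(d)
    }
    sel <- names(d)[ord][seq_len(k)]
    feat <- methods::new("CountFeature", name = name, variantIds = sel)
    attr(feat, "distances") <- data.frame(variant_id = names(d)[ord],
                                          distance = unname(d[ord]),
                                          row.names = NULL)
    feat
}

#' @describeIn evaluateFeature count of member variants carried as
#'   alternative; NA when any member genotype is missing.
#' @export
setMethod("evaluateFeature", signature("CountFeature", "StimCohort"),
          function(feature, cohort, ...) {
    evaluateFeature(feature, altPresence(cohort))
})

#' @describeIn evaluateFeature method on a raw alt-presence matrix
#'   (processes x variants).
#' @export
setMethod("evaluateFeature", signature("CountFeature", "matrix"),
          function(feature, cohort, ...) {
    idx <- match(feature@variantIds, colnames(cohort))
    if (anyNA(idx))
        stop("feature member(s) absent from genotype matrix: ",
             paste(feature@variantIds[is.na(idx)], collapse = ", "))
    rowSums(cohort[, idx, drop = FALSE])
})
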