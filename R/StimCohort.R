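#' Construct a StimCohort
#'
#' Builds the package's central container from a clinical table and,
#' optionally, a genotype dosage matrix plus a variant panel.
#'
#' @param clinical data.frame or DataFrame with one row per IVF process.
#'   Must contain \code{process_id}, \code{patient_id} and \code{mii_count};
#'   clinical covariates (\code{age, bmi, amh, fsh, lh, e2, afc_day1, pcos,
#'   prev_mii, prev_denuded, stim_days, gonadotropin_dose}) are carried along
#'   when present. Optional fields are NA where missing, never imputed.
#' @param genotypes variant x process matrix of alternative-allele dosages in
#'   \{0, 1, 2, NA\}, or NULL for a clinical-only cohort. Columns must align
#'   with (or be named by) \code{clinical$process_id}.
#' @param variants variant panel data.frame (see [makePanel()]) describing the
#'   rows of \code{genotypes}.
#' @return a [StimCohort-class].
#' @examples
#' cl <- data.frame(process_id = c("p1", "p2"), patient_id = c("w1", "w2"),
#'                  age = c(34, 30), amh = c(2.1, 4.5), mii_count = c(5L, 9L))
#' StimCohort(cl)
#' @export
StimCohort <- function(clinical, genotypes = NULL, variants = NULL) {
    clinical <- as.data.frame(clinical)
    stopifnot(all(c("process_id", "patient_id", "mii_count") %in%
                  colnames(clinical)))
    clinical$process_id <- as.character(clinical$process_id)
    clinical$patient_id <- as.character(clinical$patient_id)
    if (is.null(genotypes)) {
        genotypes <- matrix(integer(0), nrow = 0, ncol = nrow(clinical),
                            dimnames = list(NULL, clinical$process_id))
        gr <- GRanges()
    } else {
        stopifnot(!is.null(variants), nrow(variants) == nrow(genotypes))
        variants <- validatePanel(variants)
        if (!is.null(colnames(genotypes))) {
            miss <- setdiff(clinical$process_id, colnames(genotypes))
            if (length(miss))
                stop("genotype columns missing for process(es): ",
                     paste(utils::head(miss, 5), collapse = ", "))
            genotypes <- genotypes[, clinical$process_id, drop = FALSE]
        } else {
            stopifnot(ncol(genotypes) == nrow(clinical))
            colnames(genotypes) <- clinical$process_id
        }
        gr <- GRanges(seqnames = as.character(variants$chromosome),
                      ranges = IRanges(start = variants$position, width = 1L))
        S4Vectors::mcols(gr) <- DataFrame(
            variant_id = variants$variant_id,
            gene_symbol = variants$gene_symbol,
            ref_allele = variants$ref_allele,
            alt_allele = variants$alt_allele,
            alt_frequency = variants$alt_frequency)
        names(gr) <- variants$variant_id
        rownames(genotypes) <- variants$variant_id
    }
    se <- SummarizedExperiment(
        assays = list(dosage = genotypes),
        rowRanges = gr,
        colData = DataFrame(clinical, row.names = clinical$process_id))
    methods::new("StimCohort", se)
}

#' Validate a variant panel table
#'
#' A panel is a data.frame with columns \code{variant_id} (dbSNP rsID,
#' unique), \code{gene_symbol}, \code{chromosome}, \code{position} (1-based,
#' positive), \code{ref_allele}, \code{alt_allele} (distinct from ref) and
#' optionally \code{alt_frequency} in [0, 1].
#'
#' @param panel data.frame.
#' @return the panel, with \code{alt_frequency} added (NA) when absent.
#' @export
validatePanel <- function(panel) {
    panel <- as.data.frame(panel)
    need <- c("variant_id", "gene_symbol", "chromosome", "position",
              "ref_allele", "alt_allele")
    miss <- setdiff(need, colnames(panel))
    if (length(miss))
        stop("panel lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(panel$variant_id))
        stop("variant_id must be unique within a panel")
    if (any(panel$position <= 0)) stop("positions must be positive")
    if (any(panel$ref_allele == panel$alt_allele))
        stop("ref_allele must differ from alt_allele")
    if (is.null(panel$alt_frequency)) panel$alt_frequency <- NA_real_
    bad <- !is.na(panel$alt_frequency) &
        (panel$alt_frequency < 0 | panel$alt_frequency > 1)
    if (any(bad)) stop("alt_frequency must lie in [0, 1]")
    panel
}

#' Accessors for StimCohort
#'
#' \code{dosageMatrix} returns the variant x process dosage matrix;
#' \code{altPresence} returns the process x variant binary alt-presence view
#' (\code{dosage > 0}, with missing propagated) used by every feature
#' computation; \code{clinicalData} the colData as a DataFrame;
#' \code{miiCounts}, \code{processIds}, \code{patientIds}, \code{variantIds}
#' the corresponding vectors.
#'
#' @param x a [StimCohort-class].
#' @param ... unused.
#' @name StimCohort-accessors
NULL

#' @rdname StimCohort-accessors
#' @export
setMethod("dosageMatrix", "StimCohort", function(x) assay(x, "dosage"))

#' @rdname StimCohort-accessors
#' @export
setMethod("altPresence", "StimCohort", function(x, ...) {
    d <- assay(x, "dosage")
    ap <- t(d > 0) * 1L
    storage.mode(ap) <- "integer"
    ap
})

#' @rdname StimCohort-accessors
#' @export
setMethod("altPresence", "matrix", function(x, ...) {
    ap <- (x > 0) * 1L
    storage.mode(ap) <- "integer"
    ap
})

#' @rdname StimCohort-accessors
#' @export
setMethod("miiCounts", "StimCohort", function(x) {
    stats::setNames(colData(x)$mii_count, colnames(x))
})

#' @rdname StimCohort-accessors
#' @export
setMethod("processIds", "StimCohort", function(x) colData(x)$process_id)

#' @rdname StimCohort-accessors
#' @export
setMethod("patientIds", "StimCohort", function(x) colData(x)$patient_id)

#' @rdname StimCohort-accessors
#' @export
setMethod("clinicalData", "StimCohort", function(x) colData(x))

#' @rdname StimCohort-accessors
#' @export
setMethod("variantIds", "StimCohort", function(x) {
    if (nrow(x) == 0) character(0) else rowData(x)$variant_id
})

#' Variant panel of a cohort
#'
#' Reconstructs the panel data.frame (see [validatePanel()]) from the
#' cohort's rowRanges.
#' @param x a [StimCohort-class].
#' @return data.frame, zero rows for a clinical-only cohort.
#' @export
variantPanel <- function(x) {
    stopifnot(methods::is(x, "StimCohort"))
    if (nrow(x) == 0)
        return(data.frame(variant_id = character(0),
                          gene_symbol = character(0),
                          chromosome = character(0),
                          position = integer(0),
                          ref_allele = character(0),
                          alt_allele = character(0),
                          alt_frequency = numeric(0)))
    rr <- rowRanges(x)
    data.frame(variant_id = rowData(x)$variant_id,
               gene_symbol = rowData(x)$gene_symbol,
               chromosome = as.character(GenomicRanges::seqnames(rr)),
               position = GenomicRanges::start(rr),
               ref_allele = rowData(x)$ref_allele,
               alt_allele = rowData(x)$alt_allele,
               alt_frequency = rowData(x)$alt_frequency,
               row.names = NULL)
}

setMethod("show", "StimCohort", function(object) {
    cat("StimCohort with", ncol(object), "IVF processes (",
        length(unique(patientIds(object))), "patients ) and",
        nrow(object), "panel variants\n")
    mii <- miiCounts(object)
    cat("  MII count: median", stats::median(mii), " range [",
        min(mii), ",", max(mii), "]\n")
    opt <- intersect(c("amh", "afc_day1", "prev_mii"),
                     colnames(colData(object)))
    for (f in opt)
        cat(sprintf("  %s: %d missing\n", f,
                    sum(is.na(colData(object)[[f]]))))
    invisible(NULL)
})

#' @rdname GeneticFeature-class
#' @export
setMethod("featureName", "GeneticFeature", function(x) x@name)

#' @rdname GeneticFeature-class
#' @export
setMethod("featureVariants", "GeneticFeature", function(x) x@variantIds)

setMethod("show", "GeneticFeature", function(object) {
    cat(class(object), sprintf("'%s'", object@name), "over",
        length(object@variantIds), "variant(s):",
        paste(object@variantIds, collapse = ", "), "\n")
    if (methods::is(object, "StandardizedCountFeature"))
        cat(sprintf("  center %.4f, scale %.4f\n",
                    object@center, object@scale))
    if (methods::is(object, "ReducedHaplotype"))
        cat("  baseline states:",
            paste(object@baseline, collapse = ""),
            sprintf(" population frequency %.3f\n", object@frequency))
    invisible(NULL)
})
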