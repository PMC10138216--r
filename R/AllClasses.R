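#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowRanges
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' StimCohort: aligned clinical records, genotypes and MII outcomes
#'
#' The central container of the package. A \code{StimCohort} extends
#' \linkS4class{RangedSummarizedExperiment}: columns are IVF processes
#' (one controlled ovarian stimulation each), rows are panel variants, and the
#' single \code{"dosage"} assay holds alternative-allele dosages in
#' \{0, 1, 2, NA\}. Clinical covariates, the observed MII oocyte count and the
#' patient identifier live in \code{colData}; variant annotation
#' (dbSNP identifier, gene symbol, ref/alt alleles, panel allele frequency)
#' lives in \code{rowRanges}. A cohort may carry no genotypes at all
#' (zero assay rows), e.g. when only the clinical table has been read.
#'
#' A patient may own several processes (first and second stimulation cycle),
#' which is why model cross-validation folds are always grouped by
#' \code{patient_id}.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; no extra slots.
#' @seealso [StimCohort()], [readClinicalTable()], [generateCohort()]
#' @export
setClass("StimCohort", contains = "RangedSummarizedExperiment")

.validStimCohort <- function(object) {
    msg <- NULL
    cd <- colData(object)
    needed <- c("process_id", "patient_id", "mii_count")
    miss <- setdiff(needed, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("mii_count" %in% colnames(cd)) {
        mii <- cd$mii_count
        if (any(!is.na(mii) & mii < 0))
            msg <- c(msg, "mii_count must be nonnegative")
    }
    if ("process_id" %in% colnames(cd) && anyDuplicated(cd$process_id))
        msg <- c(msg, "process_id values must be unique")
    if (nrow(object) > 0) {
        if (!"dosage" %in% names(assays(object)))
            msg <- c(msg, "genotyped cohort must carry a 'dosage' assay")
        else {
            d <- assay(object, "dosage")
            bad <- !is.na(d) & !(d %in% 0:2)
            if (any(bad))
                msg <- c(msg, "dosage entries must be in {0, 1, 2, NA}")
        }
        rid <- rowData(object)$variant_id
        if (is.null(rid))
            msg <- c(msg, "rowData lacks variant_id")
        else if (anyDuplicated(rid))
            msg <- c(msg, "variant_id values must be unique")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("StimCohort", .validStimCohort)

#' Genetic feature classes
#'
#' Engineered genetic features are small S4 objects that know how to compute
#' their per-process value from a cohort's genotypes via [evaluateFeature()]:
#' \describe{
#'   \item{\code{CountFeature}}{number of variants in \code{variantIds}
#'     carried as alternative (alt-presence sum); the correspondence-analysis
#'     feature is of this type.}
#'   \item{\code{StandardizedCountFeature}}{the same count, z-scored with
#'     centering/scale constants frozen on the defining cohort (population SD);
#'     the SOM-derived feature is of this type.}
#'   \item{\code{ReducedHaplotype}}{binary: 1 iff every path variant matches
#'     its baseline alt-presence state, 0 otherwise; the decision-tree-reduced
#'     haplotype features are of this type.}
#' }
#' Missing genotypes at any member variant propagate to a missing feature
#' value; the downstream boosted model handles missing values natively.
#'
#' @slot name feature name used as a model column.
#' @slot variantIds member variant identifiers (rsIDs).
#' @aliases CountFeature-class StandardizedCountFeature-class
#'   ReducedHaplotype-class
#' @name GeneticFeature-class
#' @export
setClass("GeneticFeature",
         representation("VIRTUAL", name = "character",
                        variantIds = "character"))

#' @rdname GeneticFeature-class
#' @export
setClass("CountFeature", contains = "GeneticFeature")

#' @slot center population mean of the raw count on the defining cohort.
#' @slot scale population (1/n) standard deviation of the raw count.
#' @rdname GeneticFeature-class
#' @export
setClass("StandardizedCountFeature", contains = "GeneticFeature",
         representation(center = "numeric", scale = "numeric"),
         validity = function(object) {
             if (length(object@scale) != 1L || !is.finite(object@scale) ||
                 object@scale <= 0)
                 "scale must be a single positive number" else TRUE
         })

#' @slot baseline integer vector of baseline alt-presence states (0 or 1),
#'   one per path variant, parallel to \code{variantIds}.
#' @slot frequency empirical frequency of value 1 on the defining cohort
#'   (NA until evaluated).
#' @rdname GeneticFeature-class
#' @export
setClass("ReducedHaplotype", contains = "GeneticFeature",
         representation(baseline = "integer", frequency = "numeric"),
         validity = function(object) {
             if (length(object@baseline) != length(object@variantIds))
                 return("baseline and variantIds lengths differ")
             if (any(!object@baseline %in% 0:1))
                 return("baseline states must be 0 or 1")
             TRUE
         })

#' Correspondence-analysis decomposition of a variant-by-group table
#'
#' Result of [fitCA()]: principal coordinates for rows (variants) and columns
#' (MII groups), singular values of the standardized residual matrix, the
#' total inertia (Pearson chi-square / n of the table) and the proportion of
#' inertia carried by each retained dimension.
#'
#' @slot rowCoord matrix of row principal coordinates (rows x dims).
#' @slot colCoord matrix of column principal coordinates (cols x dims).
#' @slot singularValues numeric vector.
#' @slot totalInertia total inertia = chi-square / n.
#' @slot inertiaProp proportion of inertia per dimension.
#' @export
setClass("CAResult",
         representation(rowCoord = "matrix", colCoord = "matrix",
                        singularValues = "numeric", totalInertia = "numeric",
                        inertiaProp = "numeric"))

#' Trained self-organizing map
#'
#' Result of [trainSOM()]: an online-trained SOM over binary alt-presence
#' vectors with hexagonal topology, Gaussian neighborhood and Manhattan
#' distance. \code{weights} has one row per node (row-major over the grid);
#' \code{qe} is the quantization error (mean Manhattan distance of each
#' observation to its best matching unit).
#'
#' @slot weights node-by-variable weight matrix.
#' @slot gridDim integer c(nx, ny).
#' @slot bmu integer vector: best matching unit (node index) per observation.
#' @slot qe quantization error.
#' @slot config the [somConfig()] list the map was trained with.
#' @export
setClass("SomModel",
         representation(weights = "matrix", gridDim = "integer",
                        bmu = "integer", qe = "numeric", config = "list"),
         validity = function(object) {
             if (nrow(object@weights) != prod(object@gridDim))
                 "weights rows must equal the number of grid nodes" else TRUE
         })
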