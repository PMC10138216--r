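#' Evaluate a genetic feature on a cohort
#'
#' Computes the per-process value of an engineered genetic feature from the
#' cohort's genotypes. Values are driven entirely by the alt-presence view
#' (dosage > 0); a missing genotype at any member variant yields a missing
#' feature value.
#'
#' @param feature a [GeneticFeature-class] object.
#' @param cohort a [StimCohort-class] with genotypes, or an alt-presence
#'   matrix (processes x variants, columns named by variant id).
#' @param ... unused.
#' @return numeric vector, one value per process (NA where undetermined).
#' @export
setGeneric("evaluateFeature",
           function(feature, cohort, ...) standardGeneric("evaluateFeature"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("altPresence", function(x, ...) standardGeneric("altPresence"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("miiCounts", function(x) standardGeneric("miiCounts"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("processIds", function(x) standardGeneric("processIds"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' @rdname StimCohort-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname GeneticFeature-class
#' @export
setGeneric("featureName", function(x) standardGeneric("featureName"))

#' @rdname GeneticFeature-class
#' @export
setGeneric("featureVariants", function(x) standardGeneric("featureVariants"))
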