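## Clinical CSV dialect: UTF-8, comma separator, '.' decimal, mandatory header
## row, empty string = missing. Optional fields stay NA; nothing is imputed at
## read time (the boosted model consumes missing values natively).

.MANDATORY_CLINICAL <- c("process_id", "patient_id", "age", "bmi", "amh",
                         "fsh", "lh", "e2", "pcos", "mii_count")
.OPTIONAL_CLINICAL <- c("afc_day1", "prev_mii", "prev_denuded", "stim_days",
                        "gonadotropin_dose", "denuded_count")
.NUMERIC_CLINICAL <- c("age", "bmi", "amh", "fsh", "lh", "e2", "mii_count",
                       .OPTIONAL_CLINICAL)

.parseNumericColumn <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad))
        stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                     x[bad[1]], col, bad[1]))
    out[x == ""] <- NA_real_
    out
}

#' Read the per-process clinical table
#'
#' Reads one row per IVF process and applies the cohort exclusion rule:
#' processes with AMH above 15 ng/mL, or with no detectable AMH, are dropped
#' when \code{applyExclusions} is TRUE. Optional fields (previous-stimulation
#' oocyte counts, antral follicle count, stimulation parameters) keep an
#' explicit NA where the cell is empty.
#'
#' @param path CSV file; mandatory columns \code{process_id, patient_id, age,
#'   bmi, amh, fsh, lh, e2, pcos, mii_count}; recognised optional columns
#'   \code{afc_day1, prev_mii, prev_denuded, stim_days, gonadotropin_dose,
#'   denuded_count}.
#' @param applyExclusions drop AMH > 15 or missing-AMH rows (default TRUE).
#' @return a clinical-only [StimCohort-class]. The number of rows read and
#'   dropped is reported via \code{message()} and stored in
#'   \code{metadata(x)$exclusions}.
#' @export
readClinicalTable <- function(path, applyExclusions = TRUE) {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
    miss <- setdiff(.MANDATORY_CLINICAL, colnames(raw))
    if (length(miss))
        stop("clinical table lacks mandatory column(s): ",
             paste(miss, collapse = ", "))
    keep <- intersect(c(.MANDATORY_CLINICAL, .OPTIONAL_CLINICAL),
                      colnames(raw))
    cl <- raw[, keep, drop = FALSE]
    for (col in intersect(.NUMERIC_CLINICAL, colnames(cl)))
        cl[[col]] <- .parseNumericColumn(cl[[col]], col)
    cl$pcos <- cl$pcos %in% c("1", "TRUE", "true", "T", "yes")
    nRead <- nrow(cl)
    nDropped <- 0L
    if (applyExclusions) {
        drop <- is.na(cl$amh) | cl$amh > 15
        nDropped <- sum(drop)
        cl <- cl[!drop, , drop = FALSE]
    }
    message(sprintf("read %d processes, dropped %d by AMH exclusion rule",
                    nRead, nDropped))
    if (any(cl$mii_count < 0, na.rm = TRUE))
        stop("mii_count must be nonnegative")
    cl$mii_count <- as.integer(cl$mii_count)
    cohort <- StimCohort(cl)
    metadata(cohort)$exclusions <- list(read = nRead, dropped = nDropped)
    cohort
}

#' Read panel genotypes from a VCF
#'
#' Extracts alternative-allele dosages for the panel variants from a VCF 4.x
#' file. GT codes map as 0/0 -> 0, 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> NA
#' (phased separators accepted). Panel variants absent from the file become
#' all-missing rows with a warning; multi-allelic records are rejected.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param panel variant panel data.frame (see [validatePanel()]); VCF records
#'   are matched to the panel by the ID column (rsID).
#' @param sampleMap named character vector mapping \code{process_id} (names)
#'   to VCF sample name (values), or path to a JSON object of the same shape.
#'   Several processes of one patient may map to the same sample.
#' @return list with \code{dosage} (variant x process integer matrix, rows in
#'   panel order, NA = missing) and \code{panel}.
#' @export
readGenotypesVcf <- function(path, panel, sampleMap) {
    panel <- validatePanel(panel)
    if (is.character(sampleMap) && length(sampleMap) == 1 &&
        file.exists(sampleMap))
        sampleMap <- unlist(jsonlite::read_json(sampleMap))
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    if (any(nAlt > 1)) {
        i <- which(nAlt > 1)[1]
        rr <- SummarizedExperiment::rowRanges(vcf)[i]
        stop(sprintf("multi-allelic record at %s:%d not supported",
                     as.character(GenomicRanges::seqnames(rr)),
                     GenomicRanges::start(rr)))
    }
    gt <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gt)) stop("VCF has no GT field")
    unmatched <- setdiff(unname(sampleMap), colnames(gt))
    if (length(unmatched))
        stop("sample-ID mapping incomplete; VCF lacks sample(s): ",
             paste(unmatched, collapse = ", "))
    code <- function(g) {
        g <- gsub("|", "/", g, fixed = TRUE)
        out <- rep(NA_integer_, length(g))
        out[g %in% "0/0"] <- 0L
        out[g %in% c("0/1", "1/0")] <- 1L
        out[g %in% "1/1"] <- 2L
        bad <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
        if (any(bad))
            stop("unrecognised GT code: ", g[which(bad)[1]])
        out
    }
    ids <- rownames(gt)
    dosage <- matrix(NA_integer_, nrow(panel), length(sampleMap),
                     dimnames = list(panel$variant_id, names(sampleMap)))
    present <- panel$variant_id %in% ids
    if (any(!present))
        warning(sum(!present), " panel variant(s) absent from VCF, ",
                "set to missing: ",
                paste(utils::head(panel$variant_id[!present], 5),
                      collapse = ", "))
    for (j in seq_along(sampleMap)) {
        col <- code(gt[, sampleMap[[j]]])
        dosage[panel$variant_id[present], j] <-
            col[match(panel$variant_id[present], ids)]
    }
    list(dosage = dosage, panel = panel)
}

#' Load a complete cohort from disk
#'
#' Convenience wrapper: reads the clinical CSV, the genotype VCF and the
#' process-to-sample map, and assembles a genotyped [StimCohort-class].
#'
#' @inheritParams readClinicalTable
#' @inheritParams readGenotypesVcf
#' @param vcfPath VCF file with panel genotypes.
#' @return a [StimCohort-class].
#' @export
loadCohort <- function(path, vcfPath, panel, sampleMap,
                       applyExclusions = TRUE) {
    cohort <- readClinicalTable(path, applyExclusions = applyExclusions)
    if (is.character(sampleMap) && length(sampleMap) == 1 &&
        file.exists(sampleMap))
        sampleMap <- unlist(jsonlite::read_json(sampleMap))
    sampleMap <- sampleMap[processIds(cohort)]
    if (anyNA(names(sampleMap)))
        stop("sample map lacks entries for some processes")
    geno <- readGenotypesVcf(vcfPath, panel, sampleMap)
    StimCohort(as.data.frame(clinicalData(cohort)), geno$dosage, geno$panel)
}

#' Write a cohort back to CSV + VCF + sample map
#'
#' Inverse of [loadCohort()]: emits the clinical CSV (empty cells for NA),
#' a VCF 4.2 with one sample per patient (genotypes are properties of the
#' woman, so processes of one patient share a column) and a JSON map from
#' process ids to VCF samples. Round-tripping through these files restores
#' the cohort field-by-field.
#'
#' @param cohort a [StimCohort-class].
#' @param csvPath,vcfPath,mapPath output paths; \code{vcfPath}/\code{mapPath}
#'   may be NULL for a clinical-only export.
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, csvPath, vcfPath = NULL, mapPath = NULL) {
    cl <- as.data.frame(clinicalData(cohort))
    cl <- cl[, intersect(c(.MANDATORY_CLINICAL, .OPTIONAL_CLINICAL),
                         colnames(cl)), drop = FALSE]
    cl$pcos <- as.integer(cl$pcos)
    utils::write.csv(cl, csvPath, row.names = FALSE, quote = FALSE,
                     na = "")
    if (!is.null(vcfPath) && nrow(cohort) > 0) {
        pid <- patientIds(cohort)
        firstIdx <- match(unique(pid), pid)
        samples <- unique(pid)
        d <- dosageMatrix(cohort)[, firstIdx, drop = FALSE]
        panel <- variantPanel(cohort)
        ord <- order(panel$chromosome, panel$position)
        gtcode <- c("0/0", "0/1", "1/1")
        lines <- c("##fileformat=VCFv4.2",
                   "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                   paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                           "FILTER", "INFO", "FORMAT", samples),
                         collapse = "\t"))
        for (i in ord) {
            gt <- ifelse(is.na(d[i, ]), "./.", gtcode[d[i, ] + 1L])
            lines <- c(lines,
                       paste(c(panel$chromosome[i], panel$position[i],
                               panel$variant_id[i], panel$ref_allele[i],
                               panel$alt_allele[i], ".", "PASS", ".", "GT",
                               gt),
                             collapse = "\t"))
        }
        writeLines(lines, vcfPath)
        if (!is.null(mapPath))
            jsonlite::write_json(as.list(stats::setNames(pid,
                                                         processIds(cohort))),
                                 mapPath, auto_unbox = TRUE)
    }
    invisible(c(csvPath, vcfPath, mapPath))
}

#' Partition processes into the five MII outcome groups
#'
#' MII counts are binned into five groups: [0,2], (2,4], (4,7], (7,11] and
#' (11, Inf), labelled \code{"<=2", "(2,4]", "(4,7]", "(7,11]", ">11"}. The
#' bins are disjoint and jointly exhaustive over the nonnegative integers
#' (a count of exactly 2 falls in the first bin, the only closure under which
#' the five groups cover every process).
#'
#' @param x a [StimCohort-class] or a nonnegative integer vector of MII
#'   counts.
#' @return list with \code{assignment} (factor over the five labels, one per
#'   process), \code{sizes} (named integer vector) and \code{labels}.
#' @examples
#' binMiiCounts(c(0, 2, 3, 5, 9, 12))$sizes
#' @export
binMiiCounts <- function(x) {
    counts <- if (methods::is(x, "StimCohort")) miiCounts(x) else x
    if (anyNA(counts)) stop("every process needs an MII count")
    if (any(counts < 0)) stop("MII counts must be nonnegative")
    labels <- c("<=2", "(2,4]", "(4,7]", "(7,11]", ">11")
    assignment <- cut(counts, breaks = c(-Inf, 2, 4, 7, 11, Inf),
                      labels = labels, right = TRUE)
    list(assignment = assignment,
         sizes = stats::setNames(as.integer(table(assignment)), labels),
         labels = labels)
}
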