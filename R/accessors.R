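#' Accessors for DCISevo data classes
#'
#' `sampleId()` / `patientId()` return identifiers; `variantKeys()` the
#' canonical "chrom:pos:ref:alt" strings of a variant set; `variantTable()`
#' its underlying data.frame; `cnaBins()` the bin `GRanges` of a profile;
#' `marker()`, `categories()` and `proportions()` the components of an IHC
#' profile; `patients()`, `variantSets()`, `cnaProfiles()`, `ihcProfiles()`
#' and `covariateSchema()` the slots of a cohort.
#'
#' @param x an object of the corresponding class.
#' @return the slot value (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setGeneric("cnaBins", function(x) standardGeneric("cnaBins"))
#' @rdname accessors
#' @export
setGeneric("marker", function(x) standardGeneric("marker"))
#' @rdname accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname accessors
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))
#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname accessors
#' @export
setGeneric("variantSets", function(x) standardGeneric("variantSets"))
#' @rdname accessors
#' @export
setGeneric("cnaProfiles", function(x) standardGeneric("cnaProfiles"))
#' @rdname accessors
#' @export
setGeneric("ihcProfiles", function(x) standardGeneric("ihcProfiles"))
#' @rdname accessors
#' @export
setGeneric("covariateSchema", function(x) standardGeneric("covariateSchema"))

#' @rdname accessors
setMethod("sampleId", "SampleVariantSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "CopyNumberProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "IHCProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("patientId", "SampleVariantSet", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "CopyNumberProfile", function(x) x@patientId)
#' @rdname accessors
setMethod("variantKeys", "SampleVariantSet",
          function(x) variantKeyStrings(x@variants))
#' @rdname accessors
setMethod("variantTable", "SampleVariantSet", function(x) x@variants)
#' @rdname accessors
setMethod("cnaBins", "CopyNumberProfile", function(x) x@bins)
#' @rdname accessors
setMethod("marker", "IHCProfile", function(x) x@marker)
#' @rdname accessors
setMethod("categories", "IHCProfile", function(x) x@categories)
#' @rdname accessors
setMethod("proportions", "IHCProfile", function(x) x@proportions)
#' @rdname accessors
setMethod("patients", "DCISCohort", function(x) x@patients)
#' @rdname accessors
setMethod("variantSets", "DCISCohort", function(x) x@variants)
#' @rdname accessors
setMethod("cnaProfiles", "DCISCohort", function(x) x@cna)
#' @rdname accessors
setMethod("ihcProfiles", "DCISCohort", function(x) x@ihc)
#' @rdname accessors
setMethod("covariateSchema", "DCISCohort", function(x) x@schema)

setMethod("show", "SampleVariantSet", function(object) {
    cat("SampleVariantSet", object@sampleId,
        sprintf("(patient %s): %d variants\n",
                object@patientId, nrow(object@variants)))
})

setMethod("show", "CopyNumberProfile", function(object) {
    n <- length(object@bins)
    nna <- sum(is.na(mcols(object@bins)$log2))
    cat("CopyNumberProfile", object@sampleId,
        sprintf("(patient %s): %d bins (%d filtered)\n",
                object@patientId, n, nna))
})

setMethod("show", "IHCProfile", function(object) {
    cat("IHCProfile", object@marker, "in", object@sampleId, ":",
        paste(sprintf("%s=%.3f", object@categories, object@proportions),
              collapse = " "), "\n")
})

setMethod("show", "DCISCohort", function(object) {
    tab <- table(object@patients$cohort)
    cat(sprintf("DCISCohort: %d patients (%s)\n", nrow(object@patients),
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    cat(sprintf("  variant sets: %d | CNA profiles: %d | IHC profiles: %d\n",
                length(object@variants), length(object@cna),
                length(object@ihc)))
})
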