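#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## Canonical ordered category systems for IHC profiles. Order is meaningful:
## staining intensity increases left to right.
.IHC_LEVELS4 <- c("absence", "low", "medium", "high")
.IHC_LEVELS2 <- c("absent", "present")

#' Somatic variant identities of one tumor sample
#'
#' A `SampleVariantSet` holds the set of somatic SNV identities called in one
#' neoplastic sample. A variant identity is the exact tuple
#' (chrom, pos, ref, alt) with 1-based VCF-convention coordinates; two samples
#' share a variant iff all four fields match. The set may be empty.
#'
#' @slot sampleId single sample identifier.
#' @slot patientId single patient identifier.
#' @slot variants `data.frame` with columns `chrom` (character), `pos`
#'   (integer, >= 1), `ref`, `alt` (character, `ref != alt`); rows are unique.
#'
#' @seealso [snvBurden()], [snvDivergence()], [readVariants()]
#' @export
setClass("SampleVariantSet",
    representation(sampleId = "character", patientId = "character",
                   variants = "data.frame"))

setValidity("SampleVariantSet", function(object) {
    v <- object@variants
    msgs <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msgs <- c(msgs, "sampleId must be a single non-NA string")
    if (length(object@patientId) != 1L || is.na(object@patientId))
        msgs <- c(msgs, "patientId must be a single non-NA string")
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(v)))
        return("variants must have columns chrom, pos, ref, alt")
    if (nrow(v)) {
        if (any(is.na(v$pos)) || any(v$pos < 1L))
            msgs <- c(msgs, "variant pos must be >= 1")
        if (any(v$ref == v$alt))
            msgs <- c(msgs, "ref and alt alleles must differ")
        if (anyDuplicated(variantKeyStrings(v)))
            msgs <- c(msgs, "duplicate variant keys")
    }
    if (length(msgs)) msgs else TRUE
})

#' Bin-level copy-number profile of one sample
#'
#' Ordered, non-overlapping genomic bins (BED convention internally, stored as
#' a `GRanges`) with a purity/ploidy-corrected log2 read-depth ratio per bin.
#' `NA` log2 marks a bin filtered upstream (mappability/QC); such bins are
#' excluded from both numerator and denominator of every burden/divergence
#' computation. Alteration calls are derived lazily by [callAlteredBins()].
#'
#' @slot sampleId single sample identifier.
#' @slot patientId single patient identifier.
#' @slot bins `GRanges`, sorted, non-overlapping within chromosome, with a
#'   numeric metadata column `log2` (may contain `NA`).
#'
#' @seealso [cnaBurden()], [cnaDivergence()], [readCnaBins()]
#' @export
setClass("CopyNumberProfile",
    representation(sampleId = "character", patientId = "character",
                   bins = "GRanges"))

setValidity("CopyNumberProfile", function(object) {
    b <- object@bins
    msgs <- character()
    if (!"log2" %in% names(mcols(b)))
        return("bins must carry a 'log2' metadata column")
    if (!is.numeric(mcols(b)$log2))
        msgs <- c(msgs, "log2 must be numeric")
    if (length(b)) {
        sp <- split(b, as.character(seqnames(b)))
        for (chr in names(sp)) {
            g <- sp[[chr]]
            s <- start(g); e <- end(g)
            o <- order(s)
            if (any(s[o][-1] < e[o][-length(e)] + 1L) && length(g) > 1L)
                msgs <- c(msgs,
                    sprintf("overlapping bins on %s", chr))
        }
        if (is.unsorted(order(as.character(seqnames(b)), start(b))))
            msgs <- c(msgs, "bins must be sorted by (chrom, start)")
    }
    if (length(msgs)) msgs else TRUE
})

#' Ordinal immunohistochemistry staining profile
#'
#' Proportions of the slide area at each level of an ordered
#' staining-intensity scale for one marker in one sample. Two canonical scales
#' are used: 4-level (absence < low < medium < high) and 2-level
#' (absent < present). Proportions are non-negative and sum to 1 (tolerance
#' 1e-6).
#'
#' @slot sampleId single sample identifier.
#' @slot marker marker name (e.g. "ER", "GLUT1").
#' @slot categories ordered category labels, lowest intensity first.
#' @slot proportions numeric, same length as `categories`.
#'
#' @seealso [intensityScore()], [profileEmd()], [cdi()], [readIhc()]
#' @export
setClass("IHCProfile",
    representation(sampleId = "character", marker = "character",
                   categories = "character", proportions = "numeric"))

setValidity("IHCProfile", function(object) {
    p <- object@proportions
    msgs <- character()
    if (length(p) != length(object@categories))
        return("proportions and categories lengths differ")
    if (length(p) < 2L)
        msgs <- c(msgs, "need at least 2 ordered categories")
    if (any(is.na(p)) || any(p < 0))
        msgs <- c(msgs, "proportions must be non-negative and non-NA")
    else if (abs(sum(p) - 1) > 1e-6)
        msgs <- c(msgs, sprintf("proportions sum to %.8f, not 1", sum(p)))
    if (length(msgs)) msgs else TRUE
})

#' Multi-modal DCIS study cohort
#'
#' Container bundling the per-patient clinical/outcome table with the
#' molecular and phenotypic sample data. Every patient contributes exactly two
#' geographically distinct DCIS samples (and optionally one IDC sample);
#' patients missing a modality are excluded from that modality's analyses
#' only, never globally.
#'
#' @slot patients `data.frame` keyed by `patient_id` with columns `cohort`
#'   (one of nonrecurrent/recurrent/progressor or pure_dcis/synchronous_dcis),
#'   `outcome_time` (months, > 0), `outcome_event`
#'   (none/dcis_recurrence/progression), `sample_id_1`, `sample_id_2`,
#'   optional `sample_id_idc`, plus clinical covariate columns.
#' @slot variants named list of [SampleVariantSet-class], by sample id.
#' @slot cna named list of [CopyNumberProfile-class], by sample id.
#' @slot ihc list of [IHCProfile-class].
#' @slot schema named list declaring each clinical covariate as
#'   `"numeric"` or `"categorical"`; covariates are configuration, not code.
#'
#' @seealso [validateCohort()], [simulateCohort()], [genomicMetrics()]
#' @export
setClass("DCISCohort",
    representation(patients = "data.frame", variants = "list",
                   cna = "list", ihc = "list", schema = "list"))

setValidity("DCISCohort", function(object) {
    pt <- object@patients
    msgs <- character()
    need <- c("patient_id", "cohort", "outcome_time", "outcome_event",
              "sample_id_1", "sample_id_2")
    miss <- setdiff(need, names(pt))
    if (length(miss))
        return(paste("patients table missing columns:",
                     paste(miss, collapse = ", ")))
    if (anyDuplicated(pt$patient_id))
        msgs <- c(msgs, "duplicate patient_id")
    if (nrow(pt) && any(!is.na(pt$outcome_time) & pt$outcome_time <= 0))
        msgs <- c(msgs, "outcome_time must be > 0")
    bad <- .inconsistentOutcome(pt$cohort, pt$outcome_event)
    if (any(bad))
        msgs <- c(msgs, sprintf(
            "cohort/outcome_event inconsistent for: %s",
            paste(pt$patient_id[bad], collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

## cohort label -> admissible outcome_event values
.inconsistentOutcome <- function(cohort, event) {
    ok <- rep(TRUE, length(cohort))
    longit <- cohort %in% c("nonrecurrent", "recurrent", "progressor")
    ok[longit] <- (cohort[longit] == "nonrecurrent" & event[longit] == "none") |
        (cohort[longit] == "recurrent" & event[longit] == "dcis_recurrence") |
        (cohort[longit] == "progressor" & event[longit] == "progression")
    !ok
}
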