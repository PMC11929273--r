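#' Read per-sample somatic variant tables
#'
#' The TSV dialect expects header columns `sample_id`, `patient_id`, `chrom`,
#' `pos`, `ref`, `alt` (1-based VCF-convention coordinates) and may mix
#' samples in one file; duplicate rows collapse to one variant identity. The
#' VCF dialect maps one file to one sample (sample and patient ids supplied
#' by the caller) and requires the `vcfR` package.
#'
#' @param path input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param sampleId,patientId identifiers for the `"vcf"` dialect.
#' @return list of [SampleVariantSet-class], one per sample.
#' @export
readVariants <- function(path, dialect = c("tsv", "vcf"),
                         sampleId = NULL, patientId = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "vcf") {
        if (!requireNamespace("vcfR", quietly = TRUE))
            stop("the 'vcfR' package is required for the vcf dialect",
                 call. = FALSE)
        if (is.null(sampleId) || is.null(patientId))
            stop("sampleId and patientId are required for the vcf dialect",
                 call. = FALSE)
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
        df <- data.frame(chrom = fx$CHROM, pos = as.integer(fx$POS),
                         ref = fx$REF, alt = fx$ALT)
        return(list(SampleVariantSet(sampleId, patientId, df)))
    }
    tab <- .readTsv(path)
    .requireCols(tab, c("sample_id", "patient_id", "chrom", "pos", "ref",
                        "alt"), path)
    if (!nrow(tab)) return(list())
    pos <- .asNum(tab$pos, "pos", path)
    if (any(is.na(pos)))
        stop("missing pos in ", path, call. = FALSE)
    if (any(pos < 1))
        stop(sprintf("pos < 1 at data row %d of %s", which(pos < 1)[1], path),
             call. = FALSE)
    tab$pos <- as.integer(pos)
    ## one set per sample; sample -> patient mapping must be unique
    bySample <- split(tab, tab$sample_id)
    lapply(unname(bySample), function(s) {
        pid <- unique(s$patient_id)
        if (length(pid) != 1L)
            stop("sample ", s$sample_id[1], " maps to multiple patients",
                 call. = FALSE)
        SampleVariantSet(s$sample_id[1], pid,
                         s[, c("chrom", "pos", "ref", "alt")])
    })
}

#' Write variant sets to TSV
#'
#' @param sets list of [SampleVariantSet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeVariants <- function(sets, path) {
    rows <- lapply(sets, function(s) {
        v <- variantTable(s)
        if (!nrow(v)) return(NULL)
        cbind(data.frame(sample_id = sampleId(s), patient_id = patientId(s)),
              v)
    })
    empty <- data.frame(sample_id = character(), patient_id = character(),
                        chrom = character(), pos = integer(),
                        ref = character(), alt = character())
    .writeTsv(do.call(rbind, c(list(empty), rows)), path)
}

#' Read bin-level copy-number tables
#'
#' Expects a QDNAseq-style TSV with columns `sample_id`, `patient_id`,
#' `chrom`, `start`, `end` (0-based half-open, bp) and `log2` (corrected
#' log2 ratio; `NA` marks a bin filtered upstream). Bins are sorted by
#' (chrom, start) regardless of input row order.
#'
#' @param path input file.
#' @return list of [CopyNumberProfile-class], one per sample.
#' @export
readCnaBins <- function(path) {
    tab <- .readTsv(path)
    .requireCols(tab, c("sample_id", "patient_id", "chrom", "start", "end",
                        "log2"), path)
    if (!nrow(tab)) return(list())
    tab$start <- .asNum(tab$start, "start", path)
    tab$end <- .asNum(tab$end, "end", path)
    tab$log2 <- .asNum(tab$log2, "log2", path)
    if (any(tab$end <= tab$start))
        stop("bin end <= start in ", path, call. = FALSE)
    lapply(unname(split(tab, tab$sample_id)), function(s) {
        pid <- unique(s$patient_id)
        if (length(pid) != 1L)
            stop("sample ", s$sample_id[1], " maps to multiple patients",
                 call. = FALSE)
        CopyNumberProfile(s$sample_id[1], pid, s$chrom,
                          as.integer(s$start), as.integer(s$end), s$log2)
    })
}

#' Write copy-number profiles to TSV
#'
#' @param profiles list of [CopyNumberProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeCnaBins <- function(profiles, path) {
    rows <- lapply(profiles, function(p) {
        b <- cnaBins(p)
        data.frame(sample_id = sampleId(p), patient_id = patientId(p),
                   chrom = as.character(seqnames(b)),
                   start = start(b) - 1L, end = end(b),
                   log2 = mcols(b)$log2)
    })
    .writeTsv(do.call(rbind, rows), path)
}

#' Read IHC intensity-profile tables
#'
#' Expects a TSV with columns `sample_id`, `marker` and one column per
#' ordered category: either the 4-level system (`absence`, `low`, `medium`,
#' `high`) or the 2-level system (`absent`, `present`); a row uses exactly
#' one system (the other system's cells left `NA`). Rows may be percentages
#' or proportions: a row summing to 100 within 1% is rescaled to proportions,
#' a row summing to 1 within 1% is taken as is, anything else is an error —
#' never silently rescaled.
#'
#' @param path input file.
#' @return list of [IHCProfile-class].
#' @export
readIhc <- function(path) {
    tab <- .readTsv(path)
    .requireCols(tab, c("sample_id", "marker"), path)
    has4 <- all(.IHC_LEVELS4 %in% names(tab))
    has2 <- all(.IHC_LEVELS2 %in% names(tab))
    if (!has4 && !has2)
        stop("unknown category set in ", path, ": expected columns ",
             paste(.IHC_LEVELS4, collapse = "/"), " or ",
             paste(.IHC_LEVELS2, collapse = "/"), call. = FALSE)
    for (cc in intersect(c(.IHC_LEVELS4, .IHC_LEVELS2), names(tab)))
        tab[[cc]] <- .asNum(tab[[cc]], cc, path)
    lapply(seq_len(nrow(tab)), function(i) {
        v4 <- if (has4) unlist(tab[i, .IHC_LEVELS4]) else rep(NA_real_, 4)
        v2 <- if (has2) unlist(tab[i, .IHC_LEVELS2]) else rep(NA_real_, 2)
        if (!any(is.na(v4))) {
            vals <- v4; cats <- .IHC_LEVELS4
        } else if (!any(is.na(v2))) {
            vals <- v2; cats <- .IHC_LEVELS2
        } else {
            stop(sprintf("row %d of %s fills no complete category system",
                         i, path), call. = FALSE)
        }
        s <- sum(vals)
        if (abs(s - 100) <= 1) vals <- vals / 100
        else if (abs(s - 1) > 0.01)
            stop(sprintf(
                "row %d of %s sums to %.4g (neither ~1 nor ~100)", i, path,
                s), call. = FALSE)
        IHCProfile(tab$sample_id[i], tab$marker[i], vals, cats)
    })
}

#' Write IHC profiles to TSV (as proportions)
#'
#' @param profiles list of [IHCProfile-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeIhc <- function(profiles, path) {
    rows <- lapply(profiles, function(p) {
        out <- data.frame(sample_id = sampleId(p), marker = marker(p))
        for (cc in c(.IHC_LEVELS4, .IHC_LEVELS2)) out[[cc]] <- NA_real_
        out[categories(p)] <- as.list(proportions(p))
        out
    })
    .writeTsv(do.call(rbind, rows), path)
}

#' Read the per-patient clinical/outcome table
#'
#' Expects a TSV keyed by `patient_id` with columns `cohort`, `outcome_time`
#' (months), `outcome_event`, `sample_id_1`, `sample_id_2`, optional
#' `sample_id_idc`, plus one column per clinical covariate declared in
#' `schema`. Missing values are preserved (imputation is a separate,
#' explicit step; see [meanImpute()]); a missing `er_status` is recorded as
#' `"unknown"`.
#'
#' @param path input file.
#' @param schema named list mapping covariate names to `"numeric"` or
#'   `"categorical"`.
#' @return `data.frame` of patient records with the schema attached as the
#'   `"schema"` attribute.
#' @export
readClinical <- function(path, schema = defaultClinicalSchema()) {
    tab <- .readTsv(path)
    .requireCols(tab, c("patient_id", "cohort", "outcome_time",
                        "outcome_event", "sample_id_1", "sample_id_2"), path)
    if (anyDuplicated(tab$patient_id))
        stop("duplicate patient_id in ", path, call. = FALSE)
    tab$outcome_time <- .asNum(tab$outcome_time, "outcome_time", path)
    bad <- .inconsistentOutcome(tab$cohort, tab$outcome_event)
    if (any(bad))
        stop("cohort/outcome_event inconsistent for patient ",
             tab$patient_id[which(bad)[1]], " in ", path, call. = FALSE)
    for (cov in names(schema)) {
        if (!cov %in% names(tab)) next
        if (schema[[cov]] == "numeric")
            tab[[cov]] <- .asNum(tab[[cov]], cov, path)
        else
            tab[[cov]][tab[[cov]] %in% c("", "NA")] <- NA_character_
    }
    if ("er_status" %in% names(tab))
        tab$er_status[is.na(tab$er_status)] <- "unknown"
    attr(tab, "schema") <- schema
    tab
}

#' Write a per-patient clinical table to TSV
#'
#' @param patients clinical `data.frame`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClinical <- function(patients, path) .writeTsv(patients, path)

#' Default clinical covariate schema
#'
#' The covariate list is configuration, not code: studies declare their own
#' covariates and types. This default names the three covariates the package
#' treats specially (`treatment`, `er_status`, `surgical_margin_mm`) plus the
#' additional covariates emitted by the synthetic generator.
#'
#' @return named list mapping covariate names to `"numeric"`/`"categorical"`.
#' @export
defaultClinicalSchema <- function() {
    c(list(treatment = "categorical", er_status = "categorical",
           surgical_margin_mm = "numeric"),
      as.list(stats::setNames(
          rep("numeric", length(.NUMERIC_EXTRA_COVARIATES)),
          .NUMERIC_EXTRA_COVARIATES)),
      as.list(stats::setNames(
          rep("categorical", length(.CATEGORICAL_EXTRA_COVARIATES)),
          .CATEGORICAL_EXTRA_COVARIATES)))
}

## Extra clinical covariates generated by the simulator (15, making 18 with
## treatment, er_status and surgical_margin_mm).
.NUMERIC_EXTRA_COVARIATES <- c(
    "age", "bmi", "size_mm", "year_of_diagnosis", "parity",
    "screening_interval_months", "ki67_clinical", "lesion_count",
    "density_score", "distance_to_nipple_mm")
.CATEGORICAL_EXTRA_COVARIATES <- c(
    "dcis_grade", "necrosis", "microcalcifications", "menopausal_status",
    "family_history")

#' Cross-reference a cohort's modalities
#'
#' Report-only validation: checks every patient's two DCIS sample ids
#' against the molecular tables and flags patients with missing modalities.
#' Analyses proceed per-modality on the available patients; nothing is
#' dropped globally.
#'
#' @param cohort a [DCISCohort-class].
#' @return `data.frame` with one row per patient and logical flags
#'   `snv_available`, `cna_available`, `ihc_available`, plus a `notes`
#'   column describing problems (e.g. variants present for only one sample).
#' @export
validateCohort <- function(cohort) {
    pt <- patients(cohort)
    vs <- names(variantSets(cohort))
    cn <- names(cnaProfiles(cohort))
    ihcS <- vapply(ihcProfiles(cohort), sampleId, character(1))
    out <- data.frame(patient_id = pt$patient_id,
                      snv_available = FALSE, cna_available = FALSE,
                      ihc_available = FALSE, notes = "")
    for (i in seq_len(nrow(pt))) {
        ids <- c(pt$sample_id_1[i], pt$sample_id_2[i])
        notes <- character()
        if (anyDuplicated(ids) || any(is.na(ids)) || any(ids == ""))
            notes <- c(notes, "structural error: needs exactly 2 distinct DCIS samples")
        nv <- sum(ids %in% vs)
        out$snv_available[i] <- nv == 2L
        if (nv == 1L) notes <- c(notes, "SNV metrics unavailable (one sample)")
        if (nv == 0L) notes <- c(notes, "SNV metrics unavailable")
        nc <- sum(ids %in% cn)
        out$cna_available[i] <- nc == 2L
        if (nc < 2L) notes <- c(notes, "CNA metrics unavailable")
        out$ihc_available[i] <- any(ids %in% ihcS)
        if (!out$ihc_available[i]) notes <- c(notes, "IHC metrics unavailable")
        out$notes[i] <- paste(notes, collapse = "; ")
    }
    out
}
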