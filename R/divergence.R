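#' Paired-sample SNV burden
#'
#' The SNV burden of a tumor is the number of distinct somatic mutations in
#' the union of the two geographically distant samples' call sets.
#'
#' @param a,b [SampleVariantSet-class] objects from the same patient.
#' @return integer count of union mutations.
#' @examples
#' a <- SampleVariantSet("S1", "P1", data.frame(chrom = "1", pos = 1:6,
#'                                              ref = "A", alt = "T"))
#' b <- SampleVariantSet("S2", "P1", data.frame(chrom = "1", pos = c(1:4, 7:8),
#'                                              ref = "A", alt = "T"))
#' snvBurden(a, b)  # 8
#' @export
snvBurden <- function(a, b) {
    .assertSamePatient(a, b)
    length(union(variantKeys(a), variantKeys(b)))
}

#' Paired-sample SNV divergence
#'
#' Percentage of mutations in the union of the two samples' call sets that
#' are private to one sample, i.e. `100 * (|A u B| - |A n B|) / |A u B|`. A
#' minimum union size (default 5 mutations) is required; below it the
#' divergence cannot be estimated reliably and `NA` is returned.
#'
#' @inheritParams snvBurden
#' @param minUnion minimum union size required to compute divergence.
#' @return percent in `[0, 100]`, or `NA` when the union has fewer than
#'   `minUnion` mutations.
#' @export
snvDivergence <- function(a, b, minUnion = 5L) {
    .assertSamePatient(a, b)
    ka <- variantKeys(a); kb <- variantKeys(b)
    u <- length(union(ka, kb))
    if (u < minUnion) return(NA_real_)
    i <- length(intersect(ka, kb))
    100 * (u - i) / u
}

#' Call altered copy-number bins
#'
#' A bin is altered iff its corrected log2 ratio is present and strictly
#' exceeds the threshold in absolute value; bins at exactly the threshold are
#' normal. Direction is gain for positive log2, loss for negative.
#'
#' @param p a [CopyNumberProfile-class].
#' @param threshold positive log2-ratio cutoff (default 0.3).
#' @return `data.frame` with columns `bin` (index into the profile's bins)
#'   and `direction` ("gain"/"loss"), one row per altered bin.
#' @export
callAlteredBins <- function(p, threshold = 0.3) {
    stopifnot(threshold > 0)
    l2 <- mcols(cnaBins(p))$log2
    idx <- which(!is.na(l2) & abs(l2) > threshold)
    data.frame(bin = idx,
               direction = ifelse(l2[idx] > 0, "gain", "loss"))
}

#' Copy-number alteration burden of one sample
#'
#' Fraction of the considered genome that is altered: total width (bp) of
#' altered bins over total width of bins with a non-missing log2 ratio.
#' Bins filtered upstream (`NA` log2) contribute to neither numerator nor
#' denominator.
#'
#' @inheritParams callAlteredBins
#' @return fraction in `[0, 1]`.
#' @export
cnaBurden <- function(p, threshold = 0.3) {
    b <- cnaBins(p)
    usable <- !is.na(mcols(b)$log2)
    if (!any(usable)) stop("no considered genome: all bins missing",
                           call. = FALSE)
    alt <- callAlteredBins(p, threshold)
    sum(width(b)[alt$bin]) / sum(width(b)[usable])
}

#' Paired-sample copy-number divergence
#'
#' With `A` and `B` the sets of altered genomic bins of the two samples, the
#' divergence is the bp-weighted symmetric difference over the union:
#' `100 * bp(A delta B) / bp(A u B)`. Both profiles must share one bin grid;
#' bins missing in either sample are dropped from both. By default direction
#' (gain vs loss) is ignored when deciding whether an alteration is shared;
#' with `directionAware = TRUE` a bin gained in one sample and lost in the
#' other is discordant: it stays in the union but leaves the shared set, so
#' it contributes to the numerator.
#'
#' @param pa,pb [CopyNumberProfile-class] objects on the same bin grid.
#' @param threshold log2-ratio cutoff, see [callAlteredBins()].
#' @param directionAware require matching direction for a shared alteration.
#' @return percent in `[0, 100]`, or `NA` when neither sample has any
#'   altered bin (empty union).
#' @export
cnaDivergence <- function(pa, pb, threshold = 0.3, directionAware = FALSE) {
    ba <- cnaBins(pa); bb <- cnaBins(pb)
    if (length(ba) != length(bb) ||
        !all(as.character(seqnames(ba)) == as.character(seqnames(bb))) ||
        !all(start(ba) == start(bb)) || !all(end(ba) == end(bb)))
        stop("mismatched bin grids", call. = FALSE)
    keep <- !is.na(mcols(ba)$log2) & !is.na(mcols(bb)$log2)
    la <- mcols(ba)$log2; lb <- mcols(bb)$log2
    altA <- keep & abs(la) > threshold
    altB <- keep & abs(lb) > threshold
    un <- altA | altB
    if (!any(un)) return(NA_real_)
    shared <- altA & altB
    if (directionAware)
        shared <- shared & (sign(la) == sign(lb))
    w <- width(ba)
    100 * (sum(w[un]) - sum(w[shared])) / sum(w[un])
}

#' DCIS-to-IDC SNV divergence
#'
#' For patients with a synchronous or subsequent invasive sample, the
#' DCIS-IDC divergence is the mean of the two pairwise divergences between
#' each DCIS sample and the IDC sample. If exactly one pairwise comparison is
#' computable (the other union being below `minUnion`), that single value is
#' used; if both are missing the result is missing.
#'
#' @param dcis1,dcis2 the two DCIS [SampleVariantSet-class]s of one patient.
#' @param idc the patient's IDC [SampleVariantSet-class].
#' @param minUnion minimum union size, see [snvDivergence()].
#' @return list with `divergence` (percent or `NA`) and `nComparisons`
#'   (0, 1 or 2 computable pairwise comparisons).
#' @export
dcisIdcDivergence <- function(dcis1, dcis2, idc, minUnion = 5L) {
    .assertSamePatient(dcis1, dcis2)
    .assertSamePatient(dcis1, idc)
    d1 <- snvDivergence(dcis1, idc, minUnion)
    d2 <- snvDivergence(dcis2, idc, minUnion)
    vals <- c(d1, d2)[!is.na(c(d1, d2))]
    list(divergence = if (length(vals)) mean(vals) else NA_real_,
         nComparisons = length(vals))
}

#' Per-patient genetic burden and divergence table
#'
#' Runs the SNV and CNA metrics over every patient of a cohort. Patients
#' missing a modality get `NA` in that modality's columns only.
#'
#' @param cohort a [DCISCohort-class].
#' @param config an [analysisConfig()] list (thresholds, minimum union size).
#' @return `data.frame` with one row per patient: `patient_id`, `snv_burden`,
#'   `snv_divergence`, `n_union_snvs`, `cna_burden_s1`, `cna_burden_s2`,
#'   `cna_divergence`, `altered_union_bins`.
#' @export
genomicMetrics <- function(cohort, config = analysisConfig()) {
    pt <- patients(cohort)
    vs <- variantSets(cohort)
    cn <- cnaProfiles(cohort)
    thr <- config$cna_log2_threshold
    res <- lapply(seq_len(nrow(pt)), function(i) {
        s1 <- pt$sample_id_1[i]; s2 <- pt$sample_id_2[i]
        out <- data.frame(patient_id = pt$patient_id[i],
                          snv_burden = NA_integer_,
                          snv_divergence = NA_real_,
                          n_union_snvs = NA_integer_,
                          cna_burden_s1 = NA_real_,
                          cna_burden_s2 = NA_real_,
                          cna_divergence = NA_real_,
                          altered_union_bins = NA_integer_)
        if (!is.null(vs[[s1]]) && !is.null(vs[[s2]])) {
            out$snv_burden <- snvBurden(vs[[s1]], vs[[s2]])
            out$n_union_snvs <- out$snv_burden
            out$snv_divergence <- snvDivergence(vs[[s1]], vs[[s2]],
                                                config$min_union_snvs)
        }
        if (!is.null(cn[[s1]]) && !is.null(cn[[s2]])) {
            out$cna_burden_s1 <- cnaBurden(cn[[s1]], thr)
            out$cna_burden_s2 <- cnaBurden(cn[[s2]], thr)
            out$cna_divergence <- cnaDivergence(
                cn[[s1]], cn[[s2]], thr,
                directionAware = config$direction_aware_cna_sharing)
            a1 <- callAlteredBins(cn[[s1]], thr)$bin
            a2 <- callAlteredBins(cn[[s2]], thr)$bin
            out$altered_union_bins <- length(union(a1, a2))
        }
        out
    })
    do.call(rbind, res)
}
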