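#' Construct a SampleVariantSet
#'
#' Duplicate variant rows collapse to a single identity; rows are stored
#' sorted by (chrom, pos, ref, alt) so the object is independent of input
#' row order.
#'
#' @param sampleId,patientId identifiers.
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (may have zero rows).
#' @return A [SampleVariantSet-class].
#' @examples
#' vs <- SampleVariantSet("S1", "P1",
#'     data.frame(chrom = "chr1", pos = c(10L, 10L, 42L),
#'                ref = c("A", "A", "C"), alt = c("T", "T", "G")))
#' length(variantKeys(vs))  # 2: duplicates collapse
#' @export
SampleVariantSet <- function(sampleId, patientId,
                             variants = data.frame(chrom = character(),
                                                   pos = integer(),
                                                   ref = character(),
                                                   alt = character())) {
    v <- as.data.frame(variants)[, c("chrom", "pos", "ref", "alt")]
    v$chrom <- as.character(v$chrom)
    v$pos <- as.integer(v$pos)
    v$ref <- as.character(v$ref)
    v$alt <- as.character(v$alt)
    v <- v[!duplicated(variantKeyStrings(v)), , drop = FALSE]
    v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
    rownames(v) <- NULL
    new("SampleVariantSet", sampleId = as.character(sampleId),
        patientId = as.character(patientId), variants = v)
}

#' Construct a CopyNumberProfile
#'
#' Bins are sorted by (chrom, start); `NA` log2 marks bins filtered upstream.
#'
#' @param sampleId,patientId identifiers.
#' @param chrom,start,end bin coordinates, 0-based half-open (BED convention).
#' @param log2 corrected log2 ratio per bin, `NA` allowed.
#' @return A [CopyNumberProfile-class].
#' @export
CopyNumberProfile <- function(sampleId, patientId, chrom, start, end, log2) {
    if (any(end <= start))
        stop("bin end must exceed start", call. = FALSE)
    o <- order(chrom, start)
    ## BED 0-based half-open -> IRanges 1-based closed
    g <- GRanges(chrom[o], IRanges(start[o] + 1L, end[o]))
    mcols(g)$log2 <- as.numeric(log2)[o]
    new("CopyNumberProfile", sampleId = as.character(sampleId),
        patientId = as.character(patientId), bins = g)
}

#' Construct an IHCProfile
#'
#' @param sampleId sample identifier.
#' @param marker marker name.
#' @param proportions named or unnamed numeric vector of per-category
#'   proportions (lowest intensity first); must sum to 1 within 1e-6.
#' @param categories ordered category labels; defaults to the canonical
#'   4-level (absence/low/medium/high) or 2-level (absent/present) system
#'   matching `length(proportions)`.
#' @return An [IHCProfile-class].
#' @examples
#' IHCProfile("S1", "GLUT1", c(0.25, 0.25, 0.25, 0.25))
#' @export
IHCProfile <- function(sampleId, marker, proportions, categories = NULL) {
    if (is.null(categories)) {
        categories <- switch(as.character(length(proportions)),
                             "4" = .IHC_LEVELS4, "2" = .IHC_LEVELS2,
                             stop("supply category labels for a ",
                                  length(proportions), "-level profile",
                                  call. = FALSE))
    }
    new("IHCProfile", sampleId = as.character(sampleId),
        marker = as.character(marker),
        categories = as.character(categories),
        proportions = unname(as.numeric(proportions)))
}

#' Construct a DCISCohort
#'
#' @param patients per-patient clinical/outcome `data.frame`
#'   (see [DCISCohort-class]).
#' @param variants list of [SampleVariantSet-class].
#' @param cna list of [CopyNumberProfile-class].
#' @param ihc list of [IHCProfile-class].
#' @param schema named list mapping clinical covariate names to
#'   `"numeric"` or `"categorical"`.
#' @return A [DCISCohort-class].
#' @export
DCISCohort <- function(patients, variants = list(), cna = list(),
                       ihc = list(), schema = list()) {
    if (length(variants))
        names(variants) <- vapply(variants, sampleId, character(1))
    if (length(cna))
        names(cna) <- vapply(cna, sampleId, character(1))
    new("DCISCohort", patients = as.data.frame(patients),
        variants = variants, cna = cna, ihc = ihc, schema = schema)
}
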