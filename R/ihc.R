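#' Intensity score of an IHC profile
#'
#' Weighted sum of the staining-proportion profile normalized by the maximum
#' possible staining. For the 4-level scale the default weights encode
#' relative intensities 0:1:2:3 (medium about twice as intense as low, high
#' about three times), giving
#' `(0*p_abs + 1*p_low + 2*p_med + 3*p_high) / 3`; for a 2-level marker the
#' score reduces to the presence fraction.
#'
#' @param p an [IHCProfile-class].
#' @param weights optional per-category intensity weights (lowest first);
#'   default `0:(K-1)`. The score is the weighted mean divided by the
#'   maximum weight.
#' @return score in `[0, 1]`.
#' @export
intensityScore <- function(p, weights = NULL) {
    k <- length(categories(p))
    w <- weights %||% (seq_len(k) - 1)
    stopifnot(length(w) == k, max(w) > 0)
    sum(proportions(p) * w) / max(w)
}

#' Mean intensity score across a patient's samples
#'
#' Arithmetic mean of the per-sample intensity scores of one marker; with a
#' single available sample the mean is that sample's score.
#'
#' @param profiles list of 1-2 [IHCProfile-class]s of one marker and patient.
#' @param weights see [intensityScore()].
#' @return mean score in `[0, 1]`, or `NA` for an empty list.
#' @export
meanIntensityScore <- function(profiles, weights = NULL) {
    if (!length(profiles)) return(NA_real_)
    .assertOneMarker(profiles)
    mean(vapply(profiles, intensityScore, numeric(1), weights = weights))
}

#' Earth Mover's Distance between two ordinal profiles
#'
#' Minimum total movement of proportion mass between ordered categories (unit
#' spacing) needed to turn one profile into the other. For one-dimensional
#' ordered histograms this optimum equals the sum of absolute CDF differences
#' over the K-1 interior cut points. With `normalize = TRUE` the distance is
#' divided by K-1 so 4-level and 2-level markers share a `[0, 1]` scale; for
#' a 2-level profile it is then `|p_present(a) - p_present(b)|`.
#'
#' @param a,b [IHCProfile-class]s of the same marker and category system.
#' @param normalize divide by K-1. Default `TRUE`.
#' @return non-negative distance; in `[0, 1]` when normalized.
#' @export
profileEmd <- function(a, b, normalize = TRUE) {
    if (!identical(categories(a), categories(b)) ||
        !identical(marker(a), marker(b)))
        stop("profiles use different markers or category systems",
             call. = FALSE)
    .emdVec(proportions(a), proportions(b), normalize)
}

## EMD on raw proportion vectors (shared by cdi, which compares against
## reference profiles that are not sample measurements).
.emdVec <- function(pa, pb, normalize = FALSE) {
    k <- length(pa)
    d <- sum(abs(cumsum(pa) - cumsum(pb))[seq_len(k - 1L)])
    if (normalize) d / (k - 1L) else d
}

#' Cumulative Density Index: within-sample staining uniformity
#'
#' Measures how close the observed profile is to the discrete uniform
#' distribution, from 0 (all mass in one extreme category) to 1 (uniform
#' profile). Operationalized as
#' `1 - EMD(p, uniform) / EMD(extreme, uniform)` with unnormalized EMD,
#' where `extreme` is a point mass at the first category (by symmetry the
#' denominator is identical for the last category).
#'
#' @param p an [IHCProfile-class].
#' @return index in `[0, 1]`.
#' @export
cdi <- function(p) {
    pr <- proportions(p)
    k <- length(pr)
    unif <- rep(1 / k, k)
    extreme <- c(1, rep(0, k - 1L))
    1 - .emdVec(pr, unif) / .emdVec(extreme, unif)
}

#' Per-patient marker summary at the three scales of comparison
#'
#' Aggregates one marker's 1-2 sample profiles of a patient into the mean
#' intensity score (typical signal), the between-sample Earth Mover's
#' Distance (divergence between distant locations; missing with a single
#' sample) and the mean within-sample Cumulative Density Index (uniformity at
#' short distances).
#'
#' @param profiles list of 1-2 [IHCProfile-class]s of one marker and patient.
#' @param weights see [intensityScore()].
#' @param normalize see [profileEmd()].
#' @return `data.frame` row with `mis`, `emd_between`, `cdi_within`.
#' @export
patientMarkerSummary <- function(profiles, weights = NULL, normalize = TRUE) {
    stopifnot(length(profiles) >= 1L, length(profiles) <= 2L)
    .assertOneMarker(profiles)
    data.frame(
        mis = meanIntensityScore(profiles, weights),
        emd_between = if (length(profiles) == 2L)
            profileEmd(profiles[[1]], profiles[[2]], normalize)
            else NA_real_,
        cdi_within = mean(vapply(profiles, cdi, numeric(1))))
}

.assertOneMarker <- function(profiles) {
    mk <- unique(vapply(profiles, marker, character(1)))
    if (length(mk) > 1L)
        stop("profiles mix markers: ", paste(mk, collapse = ", "),
             call. = FALSE)
    invisible(mk)
}

#' Per-patient, per-marker IHC metric table for a cohort
#'
#' @param cohort a [DCISCohort-class].
#' @param config an [analysisConfig()] list (EMD normalization flag).
#' @return `data.frame` with columns `patient_id`, `marker`, `mis`,
#'   `emd_between`, `cdi_within`; one row per patient-marker with at least
#'   one profiled DCIS sample.
#' @export
ihcMetrics <- function(cohort, config = analysisConfig()) {
    pt <- patients(cohort)
    prof <- ihcProfiles(cohort)
    if (!length(prof)) {
        return(data.frame(patient_id = character(), marker = character(),
                          mis = numeric(), emd_between = numeric(),
                          cdi_within = numeric()))
    }
    sids <- vapply(prof, sampleId, character(1))
    mks <- vapply(prof, marker, character(1))
    rows <- list()
    for (i in seq_len(nrow(pt))) {
        own <- sids %in% c(pt$sample_id_1[i], pt$sample_id_2[i])
        for (mk in unique(mks[own])) {
            sel <- prof[own & mks == mk]
            rows[[length(rows) + 1L]] <- cbind(
                data.frame(patient_id = pt$patient_id[i], marker = mk),
                patientMarkerSummary(sel, normalize = config$emd_normalize))
        }
    }
    if (!length(rows)) {
        return(data.frame(patient_id = character(), marker = character(),
                          mis = numeric(), emd_between = numeric(),
                          cdi_within = numeric()))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
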