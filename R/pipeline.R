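#' Per-patient outcome-model measurement table
#'
#' Assembles the eight genetic and phenotypic measurements used by the
#' outcome models: SNV burden and divergence, per-patient CNA burden (mean
#' of the two samples) and divergence, ER and GLUT1 mean intensity scores,
#' ER within-sample uniformity (CDI) and GLUT1 between-sample divergence
#' (EMD). Columns are `NA` where a modality is unavailable; measurement
#' columns are never imputed downstream.
#'
#' @param cohort a [DCISCohort-class].
#' @param config an [analysisConfig()].
#' @return `data.frame` keyed by `patient_id` with the eight measurement
#'   columns.
#' @export
outcomeMetricsTable <- function(cohort, config = analysisConfig()) {
    gm <- genomicMetrics(cohort, config)
    im <- ihcMetrics(cohort, config)
    out <- data.frame(patient_id = gm$patient_id,
                      snv_burden = gm$snv_burden,
                      snv_divergence = gm$snv_divergence,
                      cna_burden = rowMeans(
                          gm[, c("cna_burden_s1", "cna_burden_s2")]),
                      cna_divergence = gm$cna_divergence,
                      er_mis = NA_real_, glut1_mis = NA_real_,
                      er_cdi_within = NA_real_,
                      glut1_emd_between = NA_real_)
    pick <- function(mk, col) {
        sub <- im[im$marker == mk, c("patient_id", col)]
        sub[[col]][match(out$patient_id, sub$patient_id)]
    }
    if (nrow(im)) {
        out$er_mis <- pick("ER", "mis")
        out$glut1_mis <- pick("GLUT1", "mis")
        out$er_cdi_within <- pick("ER", "cdi_within")
        out$glut1_emd_between <- pick("GLUT1", "emd_between")
    }
    out
}

#' Run the full analysis over a cohort
#'
#' Computes the per-patient metric tables, the reverse Kaplan-Meier median
#' follow-up, and the two primary endpoint models (non-invasive recurrence
#' and progression), each with stability selection, final Cox fit and
#' Youden-threshold risk stratification.
#'
#' @param cohort a [DCISCohort-class].
#' @param config an [analysisConfig()].
#' @param modes endpoint modes to model. Default the two primary endpoints.
#' @return list with `genomic`, `ihc`, `metrics`, `followup`, and `models`
#'   (one [runOutcomeModel()] result per mode).
#' @export
runAll <- function(cohort, config = analysisConfig(),
                   modes = c("recurrence", "progression")) {
    pt <- patients(cohort)
    metrics <- outcomeMetricsTable(cohort, config)
    anyEvent <- as.integer(pt$outcome_event != "none")
    models <- lapply(modes, function(m)
        runOutcomeModel(pt, metrics, m, config,
                        schema = covariateSchema(cohort)))
    names(models) <- modes
    list(genomic = genomicMetrics(cohort, config),
         ihc = ihcMetrics(cohort, config),
         metrics = metrics,
         followup = reverseKmMedianFollowup(pt$outcome_time, anyEvent),
         models = models)
}
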