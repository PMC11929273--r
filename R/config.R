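#' Analysis configuration
#'
#' Collects the constants of the pipeline in one serializable object that is
#' embedded in every run manifest, so a base seed plus the resolved
#' configuration fully determines each stochastic result.
#'
#' @param cna_log2_threshold absolute corrected log2-ratio cutoff above which
#'   a bin is called altered (strict inequality). Default 0.3.
#' @param min_union_snvs minimum number of mutations in the union of the two
#'   samples required to compute SNV divergence. Default 5.
#' @param lasso_reps number of independent repetitions of the
#'   cross-validated Cox-LASSO selection. Default 100.
#' @param cv_folds folds of the cross-validation. Default 10.
#' @param selection_freq_threshold minimum selection frequency across
#'   repetitions for a covariate to enter the final model. Default 0.9.
#' @param lasso_nlambda,lasso_lambda_min_ratio resolution and depth of the
#'   LASSO regularization path (log-spaced from the smallest all-zero
#'   lambda). Defaults 100 points over 4 decades.
#' @param base_seed integer seed from which every per-repetition seed is
#'   derived.
#' @param endpoint_mode one of `"recurrence"`, `"progression"`,
#'   `"any_recurrence"`, `"progression_censor_recurrents"`.
#' @param emd_normalize divide the Earth Mover's Distance by K-1 so 4-level
#'   and 2-level markers share a \[0,1\] scale. Default `TRUE`.
#' @param direction_aware_cna_sharing require matching gain/loss direction
#'   for a copy-number alteration to count as shared. Default `FALSE`.
#' @return a classed list (`"AnalysisConfig"`).
#' @export
analysisConfig <- function(cna_log2_threshold = 0.3,
                           min_union_snvs = 5L,
                           lasso_reps = 100L,
                           cv_folds = 10L,
                           selection_freq_threshold = 0.9,
                           lasso_nlambda = 100L,
                           lasso_lambda_min_ratio = 1e-4,
                           base_seed = 1L,
                           endpoint_mode = c("recurrence", "progression",
                                             "any_recurrence",
                                             "progression_censor_recurrents"),
                           emd_normalize = TRUE,
                           direction_aware_cna_sharing = FALSE) {
    stopifnot(cna_log2_threshold > 0,
              min_union_snvs >= 1, lasso_reps >= 1, cv_folds >= 2,
              selection_freq_threshold > 0, selection_freq_threshold <= 1)
    structure(list(
        cna_log2_threshold = cna_log2_threshold,
        min_union_snvs = as.integer(min_union_snvs),
        lasso_reps = as.integer(lasso_reps),
        cv_folds = as.integer(cv_folds),
        selection_freq_threshold = selection_freq_threshold,
        lasso_nlambda = as.integer(lasso_nlambda),
        lasso_lambda_min_ratio = lasso_lambda_min_ratio,
        base_seed = as.integer(base_seed),
        endpoint_mode = match.arg(endpoint_mode),
        emd_normalize = emd_normalize,
        direction_aware_cna_sharing = direction_aware_cna_sharing),
        class = "AnalysisConfig")
}

#' Serialize a run manifest
#'
#' Writes the resolved configuration (plus free-form extras such as seeds and
#' input paths) as JSON next to the run's result tables.
#'
#' @param config an [analysisConfig()] object.
#' @param path output JSON path.
#' @param extra named list of additional fields to embed.
#' @return the path, invisibly.
#' @export
writeRunManifest <- function(config, path, extra = list()) {
    stopifnot(inherits(config, "AnalysisConfig"))
    jsonlite::write_json(c(unclass(config), extra), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}
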