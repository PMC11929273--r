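#' @importFrom survival Surv coxph survfit survdiff cox.zph strata
NULL

#' Construct a survival endpoint table
#'
#' Turns cohort labels and outcome times into an endpoint-specific
#' (time, event) table. Modes:
#' \describe{
#'   \item{recurrence}{non-invasive recurrence: recurrents are events at
#'     their recurrence time, nonrecurrents are censored at follow-up,
#'     progressors are discarded.}
#'   \item{progression}{progressors are events, nonrecurrents censored,
#'     recurrents discarded.}
#'   \item{any_recurrence}{recurrents and progressors are both events,
#'     nonrecurrents censored.}
#'   \item{progression_censor_recurrents}{as progression, but recurrents are
#'     right-censored at their recurrence time instead of discarded.}
#' }
#' Discarded patients are absent from the table, never censored.
#'
#' @param patients per-patient `data.frame` with `patient_id`, `cohort`,
#'   `outcome_time`, `outcome_event`.
#' @param mode endpoint mode (see above).
#' @return `data.frame` with `patient_id`, `time`, `event` (0/1); attributes
#'   `mode` and `excluded` (patient ids discarded by the mode).
#' @export
prepareEndpoint <- function(patients,
                            mode = c("recurrence", "progression",
                                     "any_recurrence",
                                     "progression_censor_recurrents")) {
    mode <- match.arg(mode)
    stopifnot(all(!is.na(patients$outcome_time)),
              all(patients$outcome_time > 0))
    ev <- patients$outcome_event
    keep <- switch(mode,
        recurrence = ev != "progression",
        progression = ev != "dcis_recurrence",
        any_recurrence = rep(TRUE, nrow(patients)),
        progression_censor_recurrents = rep(TRUE, nrow(patients)))
    isEvent <- switch(mode,
        recurrence = ev == "dcis_recurrence",
        progression = ev == "progression",
        any_recurrence = ev %in% c("dcis_recurrence", "progression"),
        progression_censor_recurrents = ev == "progression")
    out <- data.frame(patient_id = patients$patient_id[keep],
                      time = patients$outcome_time[keep],
                      event = as.integer(isEvent[keep]))
    attr(out, "mode") <- mode
    attr(out, "excluded") <- patients$patient_id[!keep]
    out
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier median of the censoring distribution: the event indicator is
#' flipped so censored patients become "events" and vice versa.
#'
#' @param time follow-up/event times (months).
#' @param event 0/1 event indicator (1 = clinical event, 0 = censored).
#' @return list with `median` (months; `NA` when unreached), `reached`
#'   (logical) and `lower_bound` (last follow-up time, reported when the
#'   median is unreached).
#' @export
reverseKmMedianFollowup <- function(time, event) {
    fit <- survfit(Surv(time, 1 - event) ~ 1)
    med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
    list(median = med, reached = !is.na(med), lower_bound = max(time))
}

#' Mean-impute clinical covariate columns
#'
#' Replaces missing entries of the named columns by the column mean of the
#' observed values. Categorical covariates must be dummy-coded first (see
#' [buildDesign()]); their dummies are then imputed by the observed level
#' proportions. Intended for clinical covariates only — genetic/phenotypic
#' measurement columns must never be imputed, and passing one in `forbid`
#' raises an error.
#'
#' @param x numeric `data.frame` or matrix.
#' @param columns columns to impute (default: all).
#' @param forbid column names that must not be imputed (guard for
#'   measurement columns).
#' @return `x` with the named columns imputed.
#' @export
meanImpute <- function(x, columns = colnames(x), forbid = character()) {
    bad <- intersect(columns, forbid)
    if (length(bad))
        stop("refusing to impute measurement column(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    for (cc in columns) {
        v <- x[, cc]
        if (all(is.na(v)))
            stop("all-missing column: ", cc, call. = FALSE)
        x[is.na(v), cc] <- mean(v, na.rm = TRUE)
    }
    x
}

#' Dummy-code a covariate table into a numeric design matrix
#'
#' Numeric covariates pass through; categorical covariates are expanded into
#' one 0/1 dummy per non-reference level, the reference being the
#' alphabetically first observed level (so `treatment` is coded against
#' `lumpectomy_only` and `er_status` against `neg`). An `er_status` of
#' `"unknown"` is treated as missing. `NA` in the source propagates to the
#' dummies, to be handled explicitly by [meanImpute()] or complete-case
#' subsetting.
#'
#' @param patients per-patient `data.frame`.
#' @param schema named list mapping covariate names to `"numeric"` or
#'   `"categorical"`; covariates absent from `patients` are skipped.
#' @return numeric matrix (rownames = `patient_id`) with attribute `source`,
#'   a named character vector mapping design columns to source covariates.
#' @export
buildDesign <- function(patients, schema = defaultClinicalSchema()) {
    cols <- list(); src <- character()
    for (cov in names(schema)) {
        if (!cov %in% names(patients)) next
        v <- patients[[cov]]
        if (schema[[cov]] == "numeric") {
            cols[[cov]] <- as.numeric(v)
            src[cov] <- cov
        } else {
            v <- as.character(v)
            if (cov == "er_status") v[v == "unknown"] <- NA_character_
            lv <- sort(unique(v[!is.na(v)]))
            for (l in lv[-1]) {
                nm <- paste(cov, l, sep = "_")
                cols[[nm]] <- ifelse(is.na(v), NA_real_,
                                     as.numeric(v == l))
                src[nm] <- cov
            }
        }
    }
    X <- do.call(cbind, cols)
    rownames(X) <- patients$patient_id
    attr(X, "source") <- src
    X
}

#' Standardize covariate columns to z-scores
#'
#' Per-column centering and scaling (sample SD, n-1), storing the means and
#' SDs so hazard ratios per standard deviation can be rescaled to natural
#' units ([hrRescale()]). Zero-SD columns are dropped with a warning.
#'
#' @param x numeric matrix.
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
standardizeCovariates <- function(x) {
    mu <- colMeans(x, na.rm = TRUE)
    sd <- apply(x, 2, stats::sd, na.rm = TRUE)
    drop <- which(is.na(sd) | sd == 0)
    if (length(drop)) {
        warning("dropping zero-variance column(s): ",
                paste(colnames(x)[drop], collapse = ", "), call. = FALSE)
        x <- x[, -drop, drop = FALSE]
        mu <- mu[-drop]; sd <- sd[-drop]
    }
    z <- sweep(sweep(x, 2, mu), 2, sd, "/")
    attr(z, "center") <- mu
    attr(z, "scale") <- sd
    z
}

#' Proportional-hazards regression with PH diagnostics
#'
#' Cox partial-likelihood fit (Efron tie handling) with per-coefficient Wald
#' tests and a Schoenfeld-residual proportional-hazards check reported
#' alongside each covariate (flagged, not enforced).
#'
#' @param time,event survival times and 0/1 event indicators.
#' @param X numeric covariate matrix (typically standardized, so hazard
#'   ratios are per 1 SD).
#' @return list with `table` (`term`, `beta`, `hr`, `ci_lo`, `ci_hi`,
#'   `wald_p`, `ph_p`), `n`, `events`, `loglik`, `fit`, and any
#'   standardization metadata carried by `X` (`center`, `scale`).
#' @export
coxFit <- function(time, event, X) {
    if (sum(event) < 1L) stop("no events", call. = FALSE)
    X <- as.matrix(X)
    dat <- data.frame(X, check.names = FALSE)
    dat$.time <- time; dat$.event <- event
    ## one formula term per covariate so PH diagnostics are per-covariate
    fml <- stats::as.formula(paste(
        "Surv(.time, .event) ~",
        paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
    fit <- coxph(fml, data = dat, ties = "efron")
    if (!fit$iter || any(is.na(stats::coef(fit))))
        stop("Cox fit did not converge or is rank-deficient", call. = FALSE)
    cf <- summary(fit)$coefficients
    ci <- summary(fit)$conf.int
    phP <- rep(NA_real_, nrow(cf))
    zp <- tryCatch(cox.zph(fit), error = function(e) NULL)
    if (!is.null(zp)) {
        tab <- zp$table
        phP <- tab[seq_len(nrow(cf)), "p"]
    }
    list(table = data.frame(
             term = colnames(X),
             beta = cf[, "coef"], hr = cf[, "exp(coef)"],
             ci_lo = ci[, "lower .95"], ci_hi = ci[, "upper .95"],
             wald_p = cf[, "Pr(>|z|)"], ph_p = phP, row.names = NULL),
         n = fit$n, events = sum(event),
         loglik = fit$loglik[2], fit = fit,
         center = attr(X, "center"), scale = attr(X, "scale"))
}

#' Rescale a per-SD hazard ratio to a natural unit
#'
#' With standardized covariates the fitted hazard ratios are per 1 SD; this
#' converts to a stated raw-scale unit (e.g. per 10 SNVs, per mm):
#' `HR_unit = exp(beta_sd * unit / sd_raw)`.
#'
#' @param result a [coxFit()] result carrying standardization metadata.
#' @param covariate term name.
#' @param unit change on the raw scale.
#' @return hazard ratio per `unit`.
#' @export
hrRescale <- function(result, covariate, unit) {
    tab <- result$table
    if (!covariate %in% tab$term)
        stop("covariate not in model: ", covariate, call. = FALSE)
    if (is.null(result$scale) || !covariate %in% names(result$scale))
        stop("no standardization metadata for ", covariate, call. = FALSE)
    beta <- tab$beta[tab$term == covariate]
    exp(beta * unit / result$scale[[covariate]])
}

#' Repeated cross-validated Cox-LASSO stability selection
#'
#' One repetition draws a fold assignment (seeded by `baseSeed + r`), fits
#' the Cox-LASSO path, picks the regularization strength minimizing the
#' cross-validated partial-likelihood deviance, and records the covariates
#' with nonzero coefficients there. After `reps` repetitions the selected
#' set is the covariates chosen in at least `freqThreshold` of them. The
#' lambda path is log-spaced from the smallest all-zero lambda down
#' `-log10(lambdaMinRatio)` decades.
#'
#' @param time,event survival data; at least `folds` events required.
#' @param X standardized covariate matrix (2+ columns, complete).
#' @param reps repetitions. Default 100.
#' @param folds CV folds. Default 10.
#' @param freqThreshold selection-frequency cutoff. Default 0.9.
#' @param baseSeed integer; repetition r uses seed `baseSeed + r`.
#' @param nlambda,lambdaMinRatio lambda-grid resolution and depth.
#' @return list with `frequency` (named, per covariate), `selected`,
#'   `lambdas` (per-rep chosen lambda), `perRep` (list of per-rep nonzero
#'   sets), `reps`, `freqThreshold`, `baseSeed`.
#' @export
coxLassoStability <- function(time, event, X, reps = 100L, folds = 10L,
                              freqThreshold = 0.9, baseSeed = 1L,
                              nlambda = 100L, lambdaMinRatio = 1e-4) {
    X <- as.matrix(X)
    if (ncol(X) < 2L) stop("need at least 2 covariates", call. = FALSE)
    if (sum(event) < folds)
        stop("fewer events (", sum(event), ") than folds (", folds, ")",
             call. = FALSE)
    n <- nrow(X)
    y <- Surv(time, event)
    perRep <- vector("list", reps)
    lambdas <- numeric(reps)
    for (r in seq_len(reps)) {
        set.seed(baseSeed + r)
        foldid <- sample(rep(seq_len(folds), length.out = n))
        cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                                nlambda = nlambda,
                                lambda.min.ratio = lambdaMinRatio)
        cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
        perRep[[r]] <- rownames(cf)[cf[, 1] != 0]
        lambdas[r] <- cv$lambda.min
    }
    freq <- vapply(colnames(X), function(cc)
        mean(vapply(perRep, function(s) cc %in% s, logical(1))), numeric(1))
    list(frequency = freq,
         selected = names(freq)[freq >= freqThreshold],
         lambdas = lambdas, perRep = perRep, reps = reps,
         freqThreshold = freqThreshold, baseSeed = as.integer(baseSeed))
}

#' Per-patient relative risk
#'
#' Risk relative to a reference patient with every covariate at its mean:
#' `r_i = exp(sum_j beta_j x_ij)` on standardized covariates (mean 0), so
#' the reference risk is exactly 1. Patients missing a needed covariate get
#' `NA` with a warning.
#'
#' @param result a [coxFit()] result.
#' @param X standardized covariate matrix containing the model's terms.
#' @return named numeric vector of relative risks.
#' @export
relativeRisk <- function(result, X) {
    beta <- stats::setNames(result$table$beta, result$table$term)
    X <- as.matrix(X)[, names(beta), drop = FALSE]
    r <- exp(drop(X %*% beta))
    if (any(is.na(r)))
        warning(sum(is.na(r)), " patient(s) missing covariate values; ",
                "excluded from stratification", call. = FALSE)
    r
}

#' Youden-optimal risk threshold
#'
#' Scans the midpoints between consecutive sorted unique risks, plus one
#' boundary candidate half an average gap outside each end of the risk range
#' (so the degenerate all-high/all-low classifications, with J = 0, are
#' admissible for anti-informative scores); at each candidate t the
#' classification "risk > t predicts event" yields
#' `J(t) = sensitivity + specificity - 1`. Returns the smallest t maximizing
#' J (ties broken toward the smallest threshold).
#'
#' @param risks numeric risk scores.
#' @param events 0/1 outcome indicators.
#' @return list with `threshold` and `J`.
#' @export
youdenThreshold <- function(risks, events) {
    keep <- !is.na(risks)
    risks <- risks[keep]; events <- events[keep]
    if (sum(events) < 1L || sum(1 - events) < 1L)
        stop("need at least one event and one non-event", call. = FALSE)
    u <- sort(unique(risks))
    if (length(u) < 2L) stop("no separating threshold: all risks equal",
                             call. = FALSE)
    gap <- mean(diff(u)) / 2
    cand <- c(u[1] - gap, (u[-1] + u[-length(u)]) / 2, u[length(u)] + gap)
    J <- vapply(cand, function(t) {
        hi <- risks > t
        mean(hi[events == 1]) + mean(!hi[events == 0]) - 1
    }, numeric(1))
    best <- which(J >= max(J) - 1e-12)[1]
    list(threshold = cand[best], J = J[best])
}

#' Kaplan-Meier curves and log-rank comparison of risk groups
#'
#' Product-limit estimate per group, per-group median time-to-event (first
#' time the KM curve drops to 0.5 or below; `NA` when unreached), the
#' log-rank chi-square test, and at-risk counts on a requested time grid.
#'
#' @param time,event survival data.
#' @param groups group labels (2+ non-empty groups).
#' @param timeGrid times (months) for the at-risk table. Default
#'   `seq(0, max(time), length.out = 7)` rounded.
#' @return list with `chisq`, `df`, `p`, `medians` (named), `curves`
#'   (`data.frame`: `group`, `time`, `surv`, `n_risk`, `n_event`) and
#'   `atRisk` (`data.frame`: `group`, `time`, `n_risk`).
#' @export
kmLogrank <- function(time, event, groups, timeGrid = NULL) {
    groups <- as.character(groups)
    if (length(unique(groups)) < 2L)
        stop("need at least 2 groups", call. = FALSE)
    df <- data.frame(time = time, event = event, group = groups)
    sd <- survdiff(Surv(time, event) ~ group, data = df)
    k <- length(sd$n)
    chisq <- sd$chisq
    p <- stats::pchisq(chisq, k - 1, lower.tail = FALSE)
    fit <- survfit(Surv(time, event) ~ group, data = df)
    sm <- summary(fit)
    stratum <- sub("^group=", "", as.character(sm$strata))
    curves <- data.frame(group = stratum, time = sm$time, surv = sm$surv,
                         n_risk = sm$n.risk, n_event = sm$n.event)
    tabs <- summary(fit)$table
    medians <- if (is.matrix(tabs))
        stats::setNames(tabs[, "median"], sub("^group=", "", rownames(tabs)))
    else stats::setNames(tabs[["median"]], unique(stratum))
    timeGrid <- timeGrid %||% round(seq(0, max(time), length.out = 7))
    smg <- summary(fit, times = timeGrid, extend = TRUE)
    atRisk <- data.frame(group = sub("^group=", "",
                                     as.character(smg$strata)),
                         time = smg$time, n_risk = smg$n.risk)
    list(chisq = chisq, df = k - 1L, p = p, medians = medians,
         curves = curves, atRisk = atRisk)
}

#' Endpoint-specific outcome model: selection, fit, stratification
#'
#' The full modeling pipeline for one endpoint mode: endpoint construction,
#' clinical mean imputation (measurement columns are never imputed),
#' standardization, repeated CV Cox-LASSO stability selection, a final Cox
#' fit on the selected variables using all endpoint patients with available
#' (imputed) data for them, relative-risk computation, Youden-threshold
#' stratification and Kaplan-Meier/log-rank comparison. A complete-case
#' sensitivity refit of the final model (no imputation) is reported
#' alongside.
#'
#' @param patients per-patient clinical table (see [prepareEndpoint()],
#'   [buildDesign()]).
#' @param metrics per-patient measurement `data.frame` (keyed by
#'   `patient_id`; e.g. the merged [genomicMetrics()] and wide
#'   [ihcMetrics()] columns). These columns are complete-case, never
#'   imputed.
#' @param mode endpoint mode, see [prepareEndpoint()].
#' @param config an [analysisConfig()].
#' @param schema clinical covariate schema, see [buildDesign()].
#' @return list with elements `mode`, `endpoint`, `nSelection`, `stability`,
#'   `selected`, `cox`, `coxCompleteCase`, `risks`, `youden`,
#'   `stratification` (NULL when the selected set is empty, with
#'   `note` explaining why), `config`.
#' @export
runOutcomeModel <- function(patients, metrics, mode, config = analysisConfig(),
                            schema = defaultClinicalSchema()) {
    ep <- prepareEndpoint(patients, mode)
    rowsP <- match(ep$patient_id, patients$patient_id)
    rowsM <- match(ep$patient_id, metrics$patient_id)
    metricCols <- setdiff(names(metrics), "patient_id")
    M <- as.matrix(metrics[rowsM, metricCols, drop = FALSE])
    rownames(M) <- ep$patient_id
    C <- buildDesign(patients[rowsP, , drop = FALSE], schema)
    clinCols <- colnames(C)
    Cimp <- meanImpute(C, clinCols, forbid = metricCols)
    Xall <- cbind(M, Cimp)

    ## selection set: complete on (never-imputed) measurement columns
    selRows <- stats::complete.cases(M)
    Xsel <- standardizeCovariates(Xall[selRows, , drop = FALSE])
    stab <- coxLassoStability(ep$time[selRows], ep$event[selRows], Xsel,
                              reps = config$lasso_reps,
                              folds = config$cv_folds,
                              freqThreshold = config$selection_freq_threshold,
                              baseSeed = config$base_seed,
                              nlambda = config$lasso_nlambda,
                              lambdaMinRatio = config$lasso_lambda_min_ratio)
    out <- list(mode = attr(ep, "mode"), endpoint = ep,
                nSelection = sum(selRows), stability = stab,
                selected = stab$selected, config = config)
    if (!length(stab$selected)) {
        out$note <- "empty selected set; stratification skipped"
        return(out)
    }

    ## final model: all endpoint patients with available (imputed) data for
    ## the selected variables
    finRows <- stats::complete.cases(Xall[, stab$selected, drop = FALSE])
    Xfin <- standardizeCovariates(
        Xall[finRows, stab$selected, drop = FALSE])
    cox <- coxFit(ep$time[finRows], ep$event[finRows], Xfin)
    risks <- relativeRisk(cox, Xfin)
    yj <- youdenThreshold(risks, ep$event[finRows])
    grp <- ifelse(risks > yj$threshold, "high", "low")
    strat <- if (length(unique(grp)) == 2L)
        kmLogrank(ep$time[finRows], ep$event[finRows], grp) else NULL
    out$cox <- cox
    out$risks <- risks
    out$youden <- yj
    out$stratification <- strat

    ## sensitivity: complete observed data for the selected variables
    Xcc0 <- cbind(M, C)[, stab$selected, drop = FALSE]
    ccRows <- stats::complete.cases(Xcc0)
    out$coxCompleteCase <- if (sum(ep$event[ccRows]) >= 1L)
        tryCatch(coxFit(ep$time[ccRows], ep$event[ccRows],
                        standardizeCovariates(
                            Xcc0[ccRows, , drop = FALSE])),
                 error = function(e) list(error = conditionMessage(e)))
        else list(error = "no events in complete-case subset")
    out
}
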