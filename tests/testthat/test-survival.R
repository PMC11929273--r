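test_that("prepareEndpoint implements the four endpoint modes exactly", {
    pts <- data.frame(patient_id = c("N", "R", "P"),
                      cohort = c("nonrecurrent", "recurrent", "progressor"),
                      outcome_time = c(80, 30, 50),
                      outcome_event = c("none", "dcis_recurrence",
                                        "progression"))
    prog <- prepareEndpoint(pts, "progression")
    expect_identical(prog$patient_id, c("N", "P"))
    expect_equal(prog$time, c(80, 50))
    expect_equal(prog$event, c(0L, 1L))
    expect_identical(attr(prog, "excluded"), "R")

    rec <- prepareEndpoint(pts, "recurrence")
    expect_identical(rec$patient_id, c("N", "R"))
    expect_equal(rec$event, c(0L, 1L))

    pcr <- prepareEndpoint(pts, "progression_censor_recurrents")
    expect_equal(pcr$time, c(80, 30, 50))
    expect_equal(pcr$event, c(0L, 0L, 1L))

    anyr <- prepareEndpoint(pts, "any_recurrence")
    expect_equal(anyr$event, c(0L, 1L, 1L))
    expect_error(prepareEndpoint(pts, "bogus"))
})

test_that("recurrence and progression modes partition the cohort without overlap", {
    pts <- handCohortPatients()
    rec <- prepareEndpoint(pts, "recurrence")
    prog <- prepareEndpoint(pts, "progression")
    expect_setequal(c(rec$patient_id, attr(rec, "excluded")), pts$patient_id)
    expect_setequal(c(prog$patient_id, attr(prog, "excluded")), pts$patient_id)
    # a patient excluded from one mode is an event in the other
    expect_setequal(attr(rec, "excluded"),
                    prog$patient_id[prog$event == 1])
    expect_setequal(attr(prog, "excluded"),
                    rec$patient_id[rec$event == 1])
})

test_that("reverseKmMedianFollowup estimates the censoring median", {
    expect_equal(reverseKmMedianFollowup(rep(60, 10), rep(0, 10))$median, 60)
    res <- reverseKmMedianFollowup(rexp(20) + 1, rep(1, 20))
    expect_false(res$reached)
    expect_true(is.na(res$median))
    set.seed(14)
    n <- 400
    cens <- runif(n, 60, 174)              # median 117
    evt <- rexp(n, 1 / 500)
    time <- pmin(cens, evt)
    ev <- as.integer(evt <= cens)
    est <- reverseKmMedianFollowup(time, ev)
    expect_equal(est$median, 117, tolerance = 0.05)
})

test_that("meanImpute fills clinical columns only and guards measurements", {
    x <- cbind(a = c(1, NA, 3), b = c(0, 1, NA))
    out <- meanImpute(x, c("a", "b"))
    expect_equal(out[, "a"], c(1, 2, 3))
    expect_equal(out[, "b"], c(0, 1, 0.5))
    expect_equal(meanImpute(x, character()), x)
    expect_error(meanImpute(x, c("a"), forbid = "a"),
                 "refusing to impute")
    expect_error(meanImpute(cbind(z = c(NA_real_, NA_real_)), "z"),
                 "all-missing")
})

test_that("standardizeCovariates makes z-scores and drops constants", {
    x <- cbind(a = c(0, 10), b = c(1, 1))
    expect_warning(z <- standardizeCovariates(x), "zero-variance")
    expect_equal(unname(z[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
    expect_identical(colnames(z), "a")
    expect_equal(attr(z, "center")[["a"]], 5)
    expect_equal(attr(z, "scale")[["a"]], sd(c(0, 10)))
    # already-standardized columns are unchanged
    y <- matrix(scale(rnorm(20)), ncol = 1, dimnames = list(NULL, "v"))
    expect_equal(unname(standardizeCovariates(y)[, 1]), unname(y[, 1]),
                 tolerance = 1e-12)
})

test_that("buildDesign dummy-codes against the alphabetically first level", {
    pts <- data.frame(patient_id = c("P1", "P2", "P3"),
                      treatment = c("lumpectomy_only", "mastectomy",
                                    "lumpectomy_radiation"),
                      er_status = c("pos", "neg", "unknown"),
                      surgical_margin_mm = c(1, NA, 3))
    X <- buildDesign(pts, list(treatment = "categorical",
                               er_status = "categorical",
                               surgical_margin_mm = "numeric"))
    expect_setequal(colnames(X),
                    c("treatment_lumpectomy_radiation",
                      "treatment_mastectomy", "er_status_pos",
                      "surgical_margin_mm"))
    expect_equal(unname(X["P2", "treatment_mastectomy"]), 1)
    expect_equal(unname(X["P1", "treatment_mastectomy"]), 0)
    # unknown ER becomes missing, not a level
    expect_true(is.na(X["P3", "er_status_pos"]))
    expect_true(is.na(X["P2", "surgical_margin_mm"]))
})

test_that("coxFit's score test at beta = 0 equals the log-rank statistic", {
    set.seed(15)
    n <- 60
    grp <- rep(c(0, 1), each = n / 2)
    time <- rexp(n, 0.02 * exp(0.8 * grp)) + runif(n, 0, 1e-4)  # no ties
    ev <- rep(1L, n)
    fit <- coxFit(time, ev, cbind(g = grp))
    sd <- survival::survdiff(survival::Surv(time, ev) ~ grp)
    expect_equal(fit$fit$score, sd$chisq, tolerance = 1e-6)
    # duplicating every row leaves the estimate (nearly) unchanged; the
    # duplication introduces ties, so Efron's correction perturbs it slightly
    fit2 <- coxFit(c(time, time), c(ev, ev), cbind(g = c(grp, grp)))
    expect_equal(fit$table$beta, fit2$table$beta, tolerance = 0.02)
    expect_error(coxFit(time, rep(0L, n), cbind(g = grp)), "no events")
    expect_true(all(c("hr", "ci_lo", "ci_hi", "wald_p", "ph_p") %in%
                    names(fit$table)))
    expect_equal(fit$table$hr, exp(fit$table$beta))
})

test_that("hrRescale converts per-SD hazard ratios to natural units", {
    res <- list(table = data.frame(term = "x", beta = 0.5),
                scale = c(x = 20))
    expect_equal(hrRescale(res, "x", 10), exp(0.25))
    expect_equal(hrRescale(res, "x", 20), exp(0.5))
    expect_equal(hrRescale(res, "x", 0), 1)
    expect_error(hrRescale(res, "y", 1), "not in model")
})

test_that("coxLassoStability is reproducible and honors the degenerate single-rep case", {
    set.seed(16)
    n <- 120
    X <- matrix(rnorm(n * 4), n,
                dimnames = list(NULL, paste0("x", 1:4)))
    time <- rexp(n, 0.05 * exp(0.9 * X[, 1]))
    ev <- rep(1L, n)
    s1 <- coxLassoStability(time, ev, X, reps = 5, folds = 5, baseSeed = 7,
                            nlambda = 40, lambdaMinRatio = 1e-2)
    s2 <- coxLassoStability(time, ev, X, reps = 5, folds = 5, baseSeed = 7,
                            nlambda = 40, lambdaMinRatio = 1e-2)
    expect_identical(s1$frequency, s2$frequency)
    expect_identical(s1$lambdas, s2$lambdas)
    # the strong signal is always kept
    expect_equal(unname(s1$frequency["x1"]), 1)
    # reps = 1: selected set is that run's nonzero set
    s3 <- coxLassoStability(time, ev, X, reps = 1, folds = 5, baseSeed = 3,
                            freqThreshold = 0.9)
    expect_identical(s3$selected, s3$perRep[[1]])
    expect_error(coxLassoStability(time, rep(c(1L, 0L), c(4, n - 4)), X,
                                   folds = 10),
                 "fewer events")
})

test_that("relativeRisk is 1 at the covariate means and exponential in beta.x", {
    set.seed(17)
    X <- standardizeCovariates(cbind(a = rnorm(30), b = rnorm(30)))
    res <- list(table = data.frame(term = c("a", "b"),
                                   beta = c(log(2), 0)))
    r <- relativeRisk(res, X)
    ref <- relativeRisk(res, rbind(X, mean = c(0, 0)))
    expect_equal(unname(ref["mean"]), 1)
    expect_equal(unname(r), exp(log(2) * X[, "a"]))
})

test_that("youdenThreshold matches the exhaustive scan and its tie rules", {
    res <- youdenThreshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
    expect_equal(res$threshold, 0.5)
    expect_equal(res$J, 1)
    # anti-informative scores: the boundary classification (J = 0) wins
    anti <- youdenThreshold(c(0.1, 0.9), c(1, 0))
    expect_equal(anti$J, 0)
    expect_lt(anti$threshold, 0.1)
    set.seed(18)
    for (i in 1:50) {
        r <- round(runif(40), 2)
        e <- rbinom(40, 1, 0.4)
        if (sum(e) == 0 || sum(e) == 40 || length(unique(r)) < 2) next
        expect_equal(youdenThreshold(r, e)$J, bruteYouden(r, e))
    }
    expect_error(youdenThreshold(rep(0.5, 4), c(0, 1, 0, 1)),
                 "no separating threshold")
    expect_error(youdenThreshold(1:4, rep(1, 4)), "at least one event")
})

test_that("kmLogrank reproduces a hand-computed 6-patient log-rank table", {
    time <- 1:6
    ev <- rep(1L, 6)
    grp <- rep(c("A", "B"), each = 3)
    res <- kmLogrank(time, ev, grp)
    # O_A = 3, E_A = 3/6 + 2/5 + 1/4, V = 0.25 + 0.24 + 0.1875
    expect_equal(res$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)
    expect_identical(res$df, 1L)
    expect_equal(res$medians[["A"]], 2)
    expect_equal(res$medians[["B"]], 5)
    # identical groups: statistic 0, p 1
    same <- kmLogrank(c(1:4, 1:4), rep(c(1, 0), 4),
                      rep(c("A", "B"), each = 4))
    expect_equal(same$chisq, 0)
    expect_equal(same$p, 1)
    expect_error(kmLogrank(1:4, rep(1, 4), rep("A", 4)), "at least 2 groups")
    # at-risk table covers all groups on the grid
    expect_true(all(table(res$atRisk$group) == length(unique(res$atRisk$time))))
})

test_that("Cox Wald CIs achieve nominal coverage under a known hazard model", {
    set.seed(19)
    betaTrue <- 0.3
    hits <- vapply(1:150, function(i) {
        n <- 150
        x <- rnorm(n)
        time <- rexp(n, 0.02 * exp(betaTrue * x))
        cens <- runif(n, 20, 120)
        ev <- as.integer(time <= cens)
        fit <- coxFit(pmin(time, cens), ev, cbind(x = x))
        se <- sqrt(fit$fit$var[1, 1])
        abs(fit$table$beta - betaTrue) <= 1.96 * se
    }, logical(1))
    expect_gt(mean(hits), 0.90)
    expect_lt(mean(hits), 0.99)
})

test_that("runOutcomeModel: imputation and no-imputation agree on complete data", {
    cfg <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 40L, recurrent = 25L, progressor = 20L),
        nBins = 80L, missingness = c())
    sim <- simulateCohort(cfg, seed = 99L)
    metrics <- outcomeMetricsTable(sim$cohort)
    ac <- analysisConfig(lasso_reps = 10L, cv_folds = 5L,
                         selection_freq_threshold = 0.8, base_seed = 5L,
                         lasso_nlambda = 40L, lasso_lambda_min_ratio = 1e-2)
    res <- runOutcomeModel(patients(sim$cohort), metrics, "recurrence", ac,
                           schema = covariateSchema(sim$cohort))
    expect_identical(res$mode, "recurrence")
    expect_true(all(res$stability$frequency >= 0 &
                    res$stability$frequency <= 1))
    if (length(res$selected)) {
        expect_equal(res$cox$table$beta, res$coxCompleteCase$table$beta,
                     tolerance = 1e-8)
        expect_equal(res$cox$n, res$coxCompleteCase$n)
        expect_true(!is.null(res$youden))
        rr <- res$risks
        expect_true(all(rr > 0))
    } else {
        expect_match(res$note, "empty selected set")
    }
})
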