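#' Mann-Whitney U test between two cohorts
#'
#' Two-sided rank-sum comparison with tie correction. An exact p-value is
#' used for small samples without ties; above the size switch (combined n,
#' default 30) or with ties, the normal approximation with continuity
#' correction is used.
#'
#' @param a,b numeric value vectors of the two groups.
#' @param exactMax combined sample size up to which the exact distribution
#'   is used. Default 30.
#' @return list with `statistic` (U for the first group) and `p`.
#' @export
mannWhitney <- function(a, b, exactMax = 30L) {
    if (!length(a) || !length(b))
        stop("both groups must be non-empty", call. = FALSE)
    exact <- (length(a) + length(b)) <= exactMax
    wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Holm-Sidak step-down adjustment
#'
#' Orders raw p-values ascending and sets
#' `adj_i = max_(j <= i) (1 - (1 - p_j)^(m - j + 1))`, capped at 1; with a
#' single comparison the adjusted p equals the raw p.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @export
holmSidak <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
    adj <- pmin(cummax(adj), 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H, followed (for 3+ groups) by Dunn's
#' pairwise z statistics on the pooled ranks with the standard tie-corrected
#' variance, adjusted with the Holm-Sidak step-down procedure.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `statistic`, `df`, `p`, and (3+ groups) `pairwise`
#'   `data.frame`: `group_i`, `group_j`, `statistic` (Dunn z), `raw_p`,
#'   `adjusted_p`, `method`.
#' @export
kruskalWallisDunn <- function(values, groups) {
    groups <- as.character(groups)
    lv <- unique(groups)
    if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
    kw <- stats::kruskal.test(values, factor(groups))
    out <- list(statistic = unname(kw$statistic),
                df = unname(kw$parameter), p = kw$p.value)
    if (length(lv) > 2L) {
        n <- length(values)
        r <- rank(values)
        rbar <- tapply(r, groups, mean)
        ns <- tapply(r, groups, length)
        ties <- table(values)
        tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
        cmb <- utils::combn(lv, 2)
        z <- apply(cmb, 2, function(gg) {
            se <- sqrt((n * (n + 1) / 12 - tieCorr) *
                       (1 / ns[[gg[1]]] + 1 / ns[[gg[2]]]))
            (rbar[[gg[1]]] - rbar[[gg[2]]]) / se
        })
        rawP <- 2 * stats::pnorm(-abs(z))
        out$pairwise <- data.frame(
            group_i = cmb[1, ], group_j = cmb[2, ], statistic = z,
            raw_p = rawP, adjusted_p = holmSidak(rawP),
            method = "dunn_holm_sidak")
    }
    out
}

#' Paired-samples sign test
#'
#' Exact two-sided binomial test on the signs of the paired differences;
#' ties are discarded.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return two-sided p-value.
#' @export
pairedSignTest <- function(x, y) {
    stopifnot(length(x) == length(y))
    d <- x - y
    d <- d[d != 0]
    if (!length(d)) stop("no informative pairs (all ties)", call. = FALSE)
    stats::binom.test(sum(d > 0), length(d))$p.value
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `statistic` (F), `df`, `p`, and `pairwise` `data.frame`
#'   with Tukey-adjusted p-values from the studentized range distribution.
#'   When every value is identical the omnibus is reported as a no-variance
#'   case (`p = NA`).
#' @export
anovaTukey <- function(values, groups) {
    groups <- factor(as.character(groups))
    if (any(table(groups) == 0L) || nlevels(groups) < 2L)
        stop("need at least 2 non-empty groups", call. = FALSE)
    if (stats::var(values) == 0) {
        return(list(statistic = NA_real_, df = c(nlevels(groups) - 1L,
                    length(values) - nlevels(groups)), p = NA_real_,
                    pairwise = NULL, note = "no variance in values"))
    }
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    list(statistic = an[["F value"]][1],
         df = an[["Df"]],
         p = an[["Pr(>F)"]][1],
         pairwise = data.frame(
             group_i = vapply(nm, `[`, character(1), 1),
             group_j = vapply(nm, `[`, character(1), 2),
             statistic = tk[, "diff"],
             raw_p = NA_real_, adjusted_p = tk[, "p adj"],
             method = "tukey_hsd", row.names = NULL))
}

#' Mixed-effects ANOVA on square-root-transformed per-sample values
#'
#' For variables measured once per sample (two samples per patient, e.g. CNA
#' burden) the per-patient dependence is absorbed by a random intercept:
#' `sqrt(value) ~ cohort + (1 | patient)`. The omnibus fixed-effect test uses
#' the Satterthwaite F; pairwise contrasts of the estimated marginal means
#' are Tukey-adjusted.
#'
#' @param values per-sample numeric values in `[0, 1]`.
#' @param patientIds patient of each sample.
#' @param groups cohort label of each sample.
#' @return list with `statistic` (F), `df` (numerator, denominator), `p`,
#'   `pairwise` (`group_i`, `group_j`, `statistic`, `adjusted_p`), `fit`.
#' @export
mixedAnovaSqrt <- function(values, patientIds, groups) {
    if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
    df <- data.frame(y = sqrt(values),
                     patient = as.character(patientIds),
                     cohort = factor(as.character(groups)))
    fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ cohort + (1 | patient), data = df)))
    an <- suppressMessages(stats::anova(fit))
    emm <- emmeans::emmeans(fit, "cohort", lmer.df = "satterthwaite")
    pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "tukey"))
    nm <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
    list(statistic = an[["F value"]][1],
         df = c(an[["NumDF"]][1], an[["DenDF"]][1]),
         p = an[["Pr(>F)"]][1],
         pairwise = data.frame(
             group_i = vapply(nm, `[`, character(1), 1),
             group_j = vapply(nm, `[`, character(1), 2),
             statistic = pr$t.ratio, adjusted_p = pr$p.value,
             method = "tukey_emmeans"),
         fit = fit)
}

#' Random-forest Gini importance ranking
#'
#' Fits a classification random forest under the Gini impurity criterion on
#' the complete-case rows and returns the features sorted by mean decrease
#' in Gini impurity. Deterministic given the seed.
#'
#' @param features `data.frame` or matrix of predictors (missingness
#'   allowed; complete cases used).
#' @param labels binary class labels.
#' @param nTrees number of trees. Default 500.
#' @param seed RNG seed.
#' @return `data.frame` with `feature` and `importance`, sorted descending.
#' @export
rfGiniRanking <- function(features, labels, nTrees = 500L, seed = 1L) {
    features <- as.data.frame(features)
    y <- factor(labels)
    if (nlevels(droplevels(y)) < 2L)
        stop("labels contain a single class", call. = FALSE)
    cc <- stats::complete.cases(features)
    set.seed(seed)
    rf <- randomForest::randomForest(features[cc, , drop = FALSE],
                                     droplevels(y[cc]), ntree = nTrees)
    imp <- randomForest::importance(rf, type = 2)[, 1]
    data.frame(feature = names(sort(imp, decreasing = TRUE)),
               importance = unname(sort(imp, decreasing = TRUE)))
}

#' Logistic discrimination model
#'
#' Maximum-likelihood logistic fit of a binary cohort label on a chosen
#' feature subset (complete cases). Perfect separation and rank deficiency
#' are flagged rather than silently accepted.
#'
#' @param features `data.frame` of predictors.
#' @param labels binary labels (coerced to 0/1 by `factor` order).
#' @return list with `coefficients` (`term`, `estimate`, `wald_p`), `aic`,
#'   `n`, `separationFlagged`, `rankDeficient`, and the `fit` object.
#' @export
logisticDiscriminator <- function(features, labels) {
    features <- as.data.frame(features)
    cc <- if (ncol(features)) stats::complete.cases(features) & !is.na(labels)
          else !is.na(labels)
    dat <- features[cc, , drop = FALSE]
    dat$.y <- as.integer(factor(labels[cc])) - 1L
    fml <- if (ncol(features)) .y ~ . else .y ~ 1
    sep <- FALSE
    withCallingHandlers(
        fit <- stats::glm(fml, data = dat, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
                sep <<- TRUE
            invokeRestart("muffleWarning")
        })
    if (sep) warning("possible perfect separation; coefficients unreliable",
                     call. = FALSE)
    cf <- summary(fit)$coefficients
    rankDef <- any(is.na(stats::coef(fit)))
    if (rankDef) warning("rank-deficient design: aliased coefficients dropped",
                         call. = FALSE)
    list(coefficients = data.frame(term = rownames(cf),
                                   estimate = cf[, "Estimate"],
                                   wald_p = cf[, "Pr(>|z|)"],
                                   row.names = NULL),
         aic = stats::AIC(fit), n = sum(cc),
         separationFlagged = sep, rankDeficient = rankDef, fit = fit)
}

#' Compare logistic models by AIC on the common complete-case subset
#'
#' Because the candidate models use features with different missingness, a
#' fair AIC comparison refits every model on the intersection of
#' complete-case rows across all models' features (the smallest common
#' dataset).
#'
#' @param modelFeatures named list; each element a character vector of
#'   feature column names defining one model.
#' @param features `data.frame` holding all feature columns.
#' @param labels binary labels.
#' @return `data.frame` with `model`, `aic`, `delta_aic`, `n`, ordered by
#'   AIC.
#' @export
aicCompare <- function(modelFeatures, features, labels) {
    stopifnot(length(modelFeatures) >= 2L)
    features <- as.data.frame(features)
    allCols <- unique(unlist(modelFeatures))
    cc <- stats::complete.cases(features[, allCols, drop = FALSE]) &
        !is.na(labels)
    if (!any(cc)) stop("empty common complete-case subset", call. = FALSE)
    aics <- vapply(modelFeatures, function(cols) {
        logisticDiscriminator(features[cc, cols, drop = FALSE],
                              labels[cc])$aic
    }, numeric(1))
    out <- data.frame(model = names(modelFeatures), aic = aics,
                      delta_aic = aics - min(aics), n = sum(cc),
                      row.names = NULL)
    out[order(out$aic), ]
}
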