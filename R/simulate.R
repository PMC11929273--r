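#' Moment-matching helpers
#'
#' `nbParams()` converts a mean/SD pair to negative-binomial
#' (mean, size) parameters; `betaParams()` converts a mean/SD pair on
#' \[0, 1\] to beta shape parameters. Dispersion is clipped to valid ranges
#' (SD must exceed the mean's Poisson floor for the NB; the beta variance
#' must be below m(1-m)).
#'
#' @param mean,sd target moments.
#' @return named list of distribution parameters.
#' @export
nbParams <- function(mean, sd) {
    v <- max(sd^2, mean * 1.001)  # NB requires var > mean
    list(mean = mean, size = mean^2 / (v - mean))
}

#' @rdname nbParams
#' @export
betaParams <- function(mean, sd) {
    v <- min(sd^2, mean * (1 - mean) * 0.999)
    c0 <- mean * (1 - mean) / v - 1
    list(a = mean * c0, b = (1 - mean) * c0)
}

#' Simulation configuration
#'
#' Defines the generative model of a synthetic two-samples-per-patient DCIS
#' cohort: per-cohort SNV burden (negative binomial) and divergence (beta),
#' per-cohort CNA altered-fraction and divergence (beta) on a uniform bin
#' grid with a truncated-normal log2 emission, per-marker Dirichlet IHC
#' profiles, clinical covariate generators with missingness, and a Weibull
#' proportional-hazards outcome model with an administrative censoring
#' window.
#'
#' Two modes couple features and outcomes:
#' \describe{
#'   \item{conditional}{cohort sizes are fixed (`nPatients`), features are
#'     drawn from that cohort's distributions, and the event time is drawn
#'     from the Weibull PH model conditioned on the observed label (events
#'     before the censoring time; nonrecurrents observed at their censoring
#'     time). Per-cohort feature marginals equal the configured ones
#'     exactly.}
#'   \item{latent}{each patient draws a latent group (`latentProbs`),
#'     features from that group, then latent recurrence and progression
#'     times from the unconditioned PH model; the observed outcome is the
#'     earliest of the two event times and the censoring time, and the
#'     cohort label is assigned from it post hoc.}
#' }
#'
#' @param mode `"conditional"` or `"latent"`.
#' @param nPatients named integer vector over
#'   nonrecurrent/recurrent/progressor: per-cohort sizes (conditional) or,
#'   summed, the total (latent).
#' @param latentProbs latent group probabilities (latent mode).
#' @param snvBurden,snvDivergence,cnaBurden,cnaDivergence per-cohort named
#'   lists of distribution parameters ([nbParams()] / [betaParams()];
#'   divergences and burdens on the \[0, 1\] scale). A list of the form
#'   `list(fixed = x)` makes the feature degenerate at `x` (useful for
#'   boundary studies, e.g. divergence identically 0 or 1).
#' @param nBins,binBp CNA grid: number of bins and bin width (bp).
#' @param log2Emission list: `alteredMean`, `alteredSd` (absolute log2 of an
#'   altered bin, sign by direction, truncated outside the calling
#'   threshold), `normalSd` (centred at 0, clipped inside the threshold),
#'   `threshold`.
#' @param ihc named list per marker of per-cohort Dirichlet concentration
#'   vectors (4-level scale).
#' @param treatmentProbs,erPosProb,marginShape,marginScale clinical
#'   covariate generators (treatment multinomial over lumpectomy_only /
#'   lumpectomy_radiation / mastectomy; ER positivity; surgical margin
#'   Gamma, mm).
#' @param hazard list: `shape` (Weibull), `scaleRecurrence`,
#'   `scaleProgression` (months), `betaRecurrence`, `betaProgression`
#'   (named log-hazard coefficients on standardized features / natural 0-1
#'   dummies).
#' @param censoring list `min`, `max`: uniform administrative censoring
#'   window (months).
#' @param missingness named per-covariate missingness rates (observed table
#'   only; outcomes are never masked).
#' @return a classed list (`"SimulationConfig"`).
#' @export
simulationConfig <- function(
    mode = c("conditional", "latent"),
    nPatients = c(nonrecurrent = 99L, recurrent = 69L, progressor = 56L),
    latentProbs = c(nonrecurrent = 0.44, recurrent = 0.31,
                    progressor = 0.25),
    snvBurden = list(nonrecurrent = nbParams(13.4, 18.2),
                     recurrent = nbParams(19.2, 26.4),
                     progressor = nbParams(39.7, 46.2)),
    snvDivergence = list(nonrecurrent = betaParams(0.170, 0.138),
                         recurrent = betaParams(0.282, 0.255),
                         progressor = betaParams(0.184, 0.193)),
    cnaBurden = list(nonrecurrent = betaParams(0.159, 0.150),
                     recurrent = betaParams(0.173, 0.148),
                     progressor = betaParams(0.246, 0.171)),
    cnaDivergence = list(nonrecurrent = betaParams(0.774, 0.164),
                         recurrent = betaParams(0.677, 0.234),
                         progressor = betaParams(0.637, 0.217)),
    nBins = 500L, binBp = 50000L,
    log2Emission = list(alteredMean = 0.5, alteredSd = 0.15,
                        normalSd = 0.05, threshold = 0.3),
    ihc = list(
        ER = list(nonrecurrent = c(3, 3, 2, 1.2),
                  recurrent = c(2.9, 3, 2.1, 1.3),
                  progressor = c(2.8, 3, 2.1, 1.4)),
        GLUT1 = list(nonrecurrent = c(4, 3, 2, 1),
                     recurrent = c(3.9, 3, 2, 1.1),
                     progressor = c(3.7, 3, 2.1, 1.3))),
    treatmentProbs = c(lumpectomy_only = 0.35, lumpectomy_radiation = 0.45,
                       mastectomy = 0.20),
    erPosProb = 0.75, marginShape = 2, marginScale = 2,
    hazard = list(shape = 1.2, scaleRecurrence = 180,
                  scaleProgression = 240,
                  betaRecurrence = c(snv_divergence = 1.3,
                                     treatment_lumpectomy_radiation = -0.9,
                                     treatment_mastectomy = -1.3,
                                     er_status_pos = -0.5),
                  betaProgression = c(snv_burden = 1.2,
                                      surgical_margin_mm = -0.5)),
    censoring = list(min = 60, max = 174),
    missingness = c(surgical_margin_mm = 0.15, er_status = 0.05,
                    bmi = 0.10, ki67_clinical = 0.20,
                    family_history = 0.10)) {
    cfg <- list(mode = match.arg(mode), nPatients = nPatients,
                latentProbs = latentProbs, snvBurden = snvBurden,
                snvDivergence = snvDivergence, cnaBurden = cnaBurden,
                cnaDivergence = cnaDivergence, nBins = as.integer(nBins),
                binBp = as.integer(binBp), log2Emission = log2Emission,
                ihc = ihc, treatmentProbs = treatmentProbs,
                erPosProb = erPosProb, marginShape = marginShape,
                marginScale = marginScale, hazard = hazard,
                censoring = censoring, missingness = missingness)
    known <- c("snv_burden", "snv_divergence", "cna_burden",
               "cna_divergence", "surgical_margin_mm",
               "treatment_lumpectomy_radiation", "treatment_mastectomy",
               "er_status_pos")
    unk <- setdiff(c(names(hazard$betaRecurrence),
                     names(hazard$betaProgression)), known)
    if (length(unk))
        stop("hazard beta map references unknown feature(s): ",
             paste(unk, collapse = ", "), call. = FALSE)
    structure(cfg, class = "SimulationConfig")
}

#' Configuration anchored to the published cohort summaries
#'
#' Returns a [simulationConfig()] whose marginal feature distributions are
#' moment-matched to the study-scale cohort summaries (SNV burden 13.4 /
#' 19.2 / 39.7; CNA burden 15.9% / 17.3% / 24.6%; CNA divergence 77.4% /
#' 67.7% / 63.7%; SNV divergence 17.0% / 28.2% / 18.4% for nonrecurrents /
#' recurrents / progressors; cohort sizes 99 / 69 / 56; censoring window
#' chosen so the reverse-KM median follow-up is about 117 months), with
#' effect directions producing the qualitative association pattern
#' (divergence with recurrence, burden with progression).
#'
#' @return a `SimulationConfig`.
#' @export
paperLikeConfig <- function() simulationConfig(mode = "conditional")

## Population (mixture) mean/SD per feature, used to standardize the true
## features entering the hazard linear predictor.
.mixtureMoments <- function(config) {
    w <- if (config$mode == "conditional")
        config$nPatients / sum(config$nPatients)
    else config$latentProbs
    w <- w[c("nonrecurrent", "recurrent", "progressor")]
    mix <- function(ms, vs) {
        m <- sum(w * ms)
        v <- sum(w * (vs + ms^2)) - m^2
        c(mean = m, sd = sqrt(v))
    }
    nbM <- vapply(config$snvBurden, function(p)
        if (!is.null(p$fixed)) p$fixed else p$mean, numeric(1))
    nbV <- vapply(config$snvBurden, function(p)
        if (!is.null(p$fixed)) 0 else p$mean + p$mean^2 / p$size, numeric(1))
    bM <- function(ps) vapply(ps, function(p)
        if (!is.null(p$fixed)) p$fixed else p$a / (p$a + p$b), numeric(1))
    bV <- function(ps) vapply(ps, function(p) {
        if (!is.null(p$fixed)) return(0)
        s <- p$a + p$b
        p$a * p$b / (s^2 * (s + 1))
    }, numeric(1))
    list(snv_burden = mix(nbM, nbV),
         snv_divergence = mix(100 * bM(config$snvDivergence),
                              1e4 * bV(config$snvDivergence)),
         cna_burden = mix(bM(config$cnaBurden), bV(config$cnaBurden)),
         cna_divergence = mix(100 * bM(config$cnaDivergence),
                              1e4 * bV(config$cnaDivergence)),
         surgical_margin_mm = c(
             mean = config$marginShape * config$marginScale,
             sd = sqrt(config$marginShape) * config$marginScale))
}

## |log2| of an altered bin: Normal(alteredMean, alteredSd) truncated to
## exceed the calling threshold, so emitted calls match the drawn burden.
.rAlteredLog2 <- function(n, em) {
    if (!n) return(numeric())
    lo <- stats::pnorm(em$threshold, em$alteredMean, em$alteredSd)
    stats::qnorm(lo + stats::runif(n) * (1 - lo), em$alteredMean,
                 em$alteredSd)
}

.rNormalLog2 <- function(n, em) {
    cap <- em$threshold * 0.97
    pmax(pmin(stats::rnorm(n, 0, em$normalSd), cap), -cap)
}

.rdirichlet1 <- function(conc) {
    g <- stats::rgamma(length(conc), shape = conc)
    g / sum(g)
}

## Linear predictor of one endpoint's hazard for one patient.
.linpred <- function(beta, feats, mom) {
    if (!length(beta)) return(0)
    z <- vapply(names(beta), function(nm) {
        if (nm %in% names(mom))
            (feats[[nm]] - mom[[nm]][["mean"]]) / mom[[nm]][["sd"]]
        else feats[[nm]]  # 0/1 dummy, natural scale
    }, numeric(1))
    sum(beta * z)
}

## Weibull PH draw: S(t) = exp(-(t/scale)^shape * exp(eta)).
.rWeibullPH <- function(shape, scale, eta) {
    scale * (stats::rexp(1) * exp(-eta))^(1 / shape)
}

## Weibull PH draw conditioned on T < cmax.
.rWeibullPHBefore <- function(shape, scale, eta, cmax) {
    Fc <- 1 - exp(-(cmax / scale)^shape * exp(eta))
    scale * (-log(1 - stats::runif(1) * Fc) * exp(-eta))^(1 / shape)
}

#' Simulate one patient
#'
#' Draws the latent features (union SNV burden, SNV divergence, CNA altered
#' fraction and divergence), synthesizes the two samples' variant sets
#' (private mutations split evenly, remainder to sample 1), copy-number
#' profiles (shared and private altered bins placed disjointly on the grid)
#' and IHC profiles, generates clinical covariates, and draws the outcome
#' under the configured Weibull proportional-hazards model (see
#' [simulationConfig()] for the two coupling modes). Operates on the current
#' RNG state; use [simulateCohort()] for seeded cohorts.
#'
#' @param config a [simulationConfig()].
#' @param patientIndex integer used to form patient/sample ids.
#' @param cohortLabel fixed cohort label (conditional mode); ignored in
#'   latent mode.
#' @return list with `patientRow` (1-row clinical data.frame),
#'   `variantSets`, `cnaProfiles`, `ihcProfiles`, and `truth` (1-row
#'   data.frame of realized latent quantities).
#' @export
simulatePatient <- function(config, patientIndex, cohortLabel = NULL) {
    mom <- .mixtureMoments(config)
    pid <- sprintf("P%04d", patientIndex)
    sid <- paste0(pid, c("_S1", "_S2"))
    g <- if (config$mode == "latent")
        sample(names(config$latentProbs), 1, prob = config$latentProbs)
    else match.arg(cohortLabel, c("nonrecurrent", "recurrent", "progressor"))

    ## --- SNV ---
    nb <- config$snvBurden[[g]]
    U <- if (!is.null(nb$fixed)) nb$fixed
         else stats::rnbinom(1, mu = nb$mean, size = nb$size)
    bp <- config$snvDivergence[[g]]
    d <- if (!is.null(bp$fixed)) bp$fixed else stats::rbeta(1, bp$a, bp$b)
    priv <- round(U * d)
    shared <- U - priv
    p1 <- ceiling(priv / 2)
    mkVar <- function(idx) data.frame(chrom = rep("chr1", length(idx)),
                                      pos = idx,
                                      ref = rep("A", length(idx)),
                                      alt = rep("T", length(idx)))
    idxShared <- seq_len(shared)
    idxP1 <- shared + seq_len(p1)
    idxP2 <- shared + p1 + seq_len(priv - p1)
    vs <- list(SampleVariantSet(sid[1], pid, mkVar(c(idxShared, idxP1))),
               SampleVariantSet(sid[2], pid, mkVar(c(idxShared, idxP2))))

    ## --- CNA ---
    n <- config$nBins
    cb <- config$cnaBurden[[g]]
    f <- if (!is.null(cb$fixed)) cb$fixed else stats::rbeta(1, cb$a, cb$b)
    cd <- config$cnaDivergence[[g]]
    D <- if (!is.null(cd$fixed)) cd$fixed else stats::rbeta(1, cd$a, cd$b)
    a <- min(round(f * n), floor(n * (2 - D) / 2))
    s <- min(round(2 * a * (1 - D) / (2 - D)), a)
    while (2 * a - s > n) a <- a - 1L  # rounding guard
    un <- 2 * a - s
    ids <- sample.int(n, un)
    em <- config$log2Emission
    mkProfile <- function(sampleIdx, altIds, sharedDir, privDir) {
        l2 <- .rNormalLog2(n, em)
        dirs <- c(sharedDir, privDir)
        l2[altIds] <- dirs * .rAlteredLog2(length(altIds), em)
        CopyNumberProfile(sid[sampleIdx], pid, rep("chr1", n),
                          (seq_len(n) - 1) * config$binBp,
                          seq_len(n) * config$binBp, l2)
    }
    sharedIds <- ids[seq_len(s)]
    priv1 <- ids[s + seq_len(a - s)]
    priv2 <- ids[s + (a - s) + seq_len(a - s)]
    sharedDir <- sample(c(-1, 1), s, replace = TRUE)
    cn <- list(mkProfile(1, c(sharedIds, priv1), sharedDir,
                         sample(c(-1, 1), a - s, replace = TRUE)),
               mkProfile(2, c(sharedIds, priv2), sharedDir,
                         sample(c(-1, 1), a - s, replace = TRUE)))
    cnaDivTrue <- if (un > 0) 100 * (un - s) / un else NA_real_

    ## --- IHC ---
    ihc <- list()
    for (mk in names(config$ihc)) {
        conc <- config$ihc[[mk]][[g]]
        ihc <- c(ihc, list(IHCProfile(sid[1], mk, .rdirichlet1(conc)),
                           IHCProfile(sid[2], mk, .rdirichlet1(conc))))
    }

    ## --- clinical covariates (true values; masking comes later) ---
    treatment <- sample(names(config$treatmentProbs), 1,
                        prob = config$treatmentProbs)
    erPos <- stats::runif(1) < config$erPosProb
    margin <- stats::rgamma(1, shape = config$marginShape,
                            scale = config$marginScale)
    clin <- data.frame(
        patient_id = pid, treatment = treatment,
        er_status = if (erPos) "pos" else "neg",
        surgical_margin_mm = margin,
        age = stats::rnorm(1, 57, 10), bmi = stats::rnorm(1, 27, 5),
        size_mm = stats::rgamma(1, 2, scale = 8),
        year_of_diagnosis = sample(1995:2010, 1),
        parity = stats::rpois(1, 2),
        screening_interval_months = stats::rnorm(1, 14, 4),
        ki67_clinical = 100 * stats::rbeta(1, 1.5, 8),
        lesion_count = 1L + stats::rpois(1, 0.3),
        density_score = sample(1:4, 1),
        distance_to_nipple_mm = stats::rgamma(1, 3, scale = 10),
        dcis_grade = sample(c("1", "2", "3"), 1,
                            prob = c(0.25, 0.45, 0.30)),
        necrosis = sample(c("no", "yes"), 1),
        microcalcifications = sample(c("no", "yes"), 1,
                                     prob = c(0.4, 0.6)),
        menopausal_status = sample(c("post", "pre"), 1,
                                   prob = c(0.65, 0.35)),
        family_history = sample(c("no", "yes"), 1, prob = c(0.8, 0.2)))

    feats <- list(snv_burden = U, snv_divergence = 100 * d,
                  cna_burden = f, cna_divergence = 100 * D,
                  surgical_margin_mm = margin,
                  treatment_lumpectomy_radiation =
                      as.numeric(treatment == "lumpectomy_radiation"),
                  treatment_mastectomy =
                      as.numeric(treatment == "mastectomy"),
                  er_status_pos = as.numeric(erPos))
    hz <- config$hazard
    etaR <- .linpred(hz$betaRecurrence, feats, mom)
    etaP <- .linpred(hz$betaProgression, feats, mom)
    C <- stats::runif(1, config$censoring$min, config$censoring$max)
    tR <- NA_real_; tP <- NA_real_
    if (config$mode == "latent") {
        tR <- .rWeibullPH(hz$shape, hz$scaleRecurrence, etaR)
        tP <- .rWeibullPH(hz$shape, hz$scaleProgression, etaP)
        tt <- c(recurrent = tR, progressor = tP, nonrecurrent = C)
        g <- names(tt)[which.min(tt)]
        time <- min(tt)
    } else if (g == "nonrecurrent") {
        time <- C
    } else if (g == "recurrent") {
        time <- tR <- .rWeibullPHBefore(hz$shape, hz$scaleRecurrence,
                                        etaR, C)
    } else {
        time <- tP <- .rWeibullPHBefore(hz$shape, hz$scaleProgression,
                                        etaP, C)
    }
    event <- switch(g, nonrecurrent = "none", recurrent = "dcis_recurrence",
                    progressor = "progression")
    patientRow <- cbind(
        data.frame(patient_id = pid, cohort = g, outcome_time = time,
                   outcome_event = event, sample_id_1 = sid[1],
                   sample_id_2 = sid[2]),
        clin[, -1])

    list(patientRow = patientRow, variantSets = vs, cnaProfiles = cn,
         ihcProfiles = ihc,
         truth = data.frame(
             patient_id = pid, cohort = g,
             snv_burden = U,
             snv_divergence = if (U >= 1) 100 * priv / U else NA_real_,
             snv_divergence_drawn = 100 * d,
             cna_burden = a / n, cna_divergence = cnaDivTrue,
             t_recurrence = tR, t_progression = tP, censor_time = C,
             eta_recurrence = etaR, eta_progression = etaP))
}

#' Simulate a full cohort
#'
#' Draws patients independently under the configured mode, injects clinical
#' missingness (never touching `outcome_time`/`outcome_event`), and bundles
#' everything into a [DCISCohort-class] plus a ground-truth table.
#' Deterministic given the seed.
#'
#' @param config a [simulationConfig()].
#' @param seed integer RNG seed.
#' @return list with `cohort` (a `DCISCohort`), `truth` (`data.frame` of
#'   realized latent quantities per patient), `config`, `seed`.
#' @export
simulateCohort <- function(config = paperLikeConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(seed)
    labels <- if (config$mode == "conditional") {
        if (sum(config$nPatients) == 0L) stop("n = 0", call. = FALSE)
        rep(names(config$nPatients), config$nPatients)
    } else {
        if (sum(config$nPatients) == 0L) stop("n = 0", call. = FALSE)
        rep(NA_character_, sum(config$nPatients))
    }
    sims <- lapply(seq_along(labels), function(i)
        simulatePatient(config, i, labels[i]))
    patientsTab <- do.call(rbind, lapply(sims, `[[`, "patientRow"))
    ## missingness injection on clinical covariates only
    nP <- nrow(patientsTab)
    for (cov in names(config$missingness)) {
        hit <- stats::runif(nP) < config$missingness[[cov]]
        patientsTab[[cov]][hit] <- NA
    }
    if ("er_status" %in% names(patientsTab))
        patientsTab$er_status[is.na(patientsTab$er_status)] <- "unknown"
    cohort <- DCISCohort(
        patients = patientsTab,
        variants = do.call(c, lapply(sims, `[[`, "variantSets")),
        cna = do.call(c, lapply(sims, `[[`, "cnaProfiles")),
        ihc = do.call(c, lapply(sims, `[[`, "ihcProfiles")),
        schema = defaultClinicalSchema())
    list(cohort = cohort,
         truth = do.call(rbind, lapply(sims, `[[`, "truth")),
         config = config, seed = as.integer(seed))
}
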