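test_that("degenerate divergence configs produce identical or disjoint variant sets", {
    fix <- function(d) list(
        nonrecurrent = list(fixed = d), recurrent = list(fixed = d),
        progressor = list(fixed = d))
    cfg0 <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 8L, recurrent = 5L, progressor = 5L),
        snvBurden = fix(20), snvDivergence = fix(0), nBins = 60L)
    sim0 <- simulateCohort(cfg0, seed = 3L)
    pts <- patients(sim0$cohort)
    vs <- variantSets(sim0$cohort)
    for (i in seq_len(nrow(pts))) {
        k1 <- variantKeys(vs[[pts$sample_id_1[i]]])
        k2 <- variantKeys(vs[[pts$sample_id_2[i]]])
        expect_setequal(k1, k2)
    }
    cfg100 <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 8L, recurrent = 5L, progressor = 5L),
        snvBurden = fix(20), snvDivergence = fix(1), nBins = 60L)
    sim100 <- simulateCohort(cfg100, seed = 3L)
    pts <- patients(sim100$cohort)
    vs <- variantSets(sim100$cohort)
    for (i in seq_len(nrow(pts))) {
        k1 <- variantKeys(vs[[pts$sample_id_1[i]]])
        k2 <- variantKeys(vs[[pts$sample_id_2[i]]])
        expect_length(intersect(k1, k2), 0L)
        expect_length(union(k1, k2), 20L)
    }
})

test_that("metric modules recover the generated quantities exactly", {
    sim <- .sharedSim()
    gm <- genomicMetrics(sim$cohort)
    tr <- sim$truth[match(gm$patient_id, sim$truth$patient_id), ]
    expect_equal(gm$snv_burden, tr$snv_burden)
    comp <- !is.na(gm$snv_divergence)
    expect_equal(gm$snv_divergence[comp], tr$snv_divergence[comp])
    # divergence reported only at the union minimum
    expect_identical(is.na(gm$snv_divergence), gm$n_union_snvs < 5)
    expect_equal(gm$cna_burden_s1, tr$cna_burden)
    expect_equal(gm$cna_burden_s2, tr$cna_burden)
    compC <- !is.na(gm$cna_divergence)
    expect_equal(gm$cna_divergence[compC], tr$cna_divergence[compC])
})

test_that("the same seed regenerates the identical cohort", {
    cfg <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 6L, recurrent = 4L, progressor = 4L),
        nBins = 50L)
    a <- simulateCohort(cfg, seed = 11L)
    b <- simulateCohort(cfg, seed = 11L)
    expect_identical(a$truth, b$truth)
    expect_identical(patients(a$cohort), patients(b$cohort))
    expect_identical(lapply(variantSets(a$cohort), variantTable),
                     lapply(variantSets(b$cohort), variantTable))
    c <- simulateCohort(cfg, seed = 12L)
    expect_false(identical(a$truth, c$truth))
})

test_that("generated tables round-trip through the readers", {
    sim <- .sharedSim()
    td <- tempfile(); dir.create(td)
    co <- sim$cohort
    writeVariants(variantSets(co), file.path(td, "v.tsv"))
    writeCnaBins(cnaProfiles(co)[1:4], file.path(td, "c.tsv"))
    writeIhc(ihcProfiles(co)[1:6], file.path(td, "i.tsv"))
    writeClinical(patients(co), file.path(td, "p.tsv"))
    vsBack <- readVariants(file.path(td, "v.tsv"))
    # non-empty sets survive identically
    nonEmpty <- Filter(function(s) length(variantKeys(s)) > 0,
                       variantSets(co))
    expect_length(vsBack, length(nonEmpty))
    cnBack <- readCnaBins(file.path(td, "c.tsv"))
    expect_length(cnBack, 4L)
    orig <- cnaProfiles(co)[[1]]
    back <- cnBack[[which(vapply(cnBack, sampleId, character(1)) ==
                          sampleId(orig))]]
    expect_equal(S4Vectors::mcols(cnaBins(back))$log2,
                 S4Vectors::mcols(cnaBins(orig))$log2)
    ihcBack <- readIhc(file.path(td, "i.tsv"))
    expect_equal(proportions(ihcBack[[1]]),
                 proportions(ihcProfiles(co)[[1]]), tolerance = 1e-12)
    ptsBack <- readClinical(file.path(td, "p.tsv"))
    expect_identical(ptsBack$patient_id, patients(co)$patient_id)
    expect_equal(ptsBack$outcome_time, patients(co)$outcome_time)
})

test_that("mean recovered SNV burden stays within 3 standard errors", {
    cfg <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 500L, recurrent = 0L, progressor = 0L),
        nBins = 40L)
    sim <- simulateCohort(cfg, seed = 21L)
    gm <- genomicMetrics(sim$cohort)
    se <- 18.2 / sqrt(500)
    expect_lt(abs(mean(gm$snv_burden) - 13.4), 3 * se)
})

test_that("missingness injection never touches outcomes and matches the configured rates", {
    cfg <- simulationConfig(
        mode = "conditional",
        nPatients = c(nonrecurrent = 150L, recurrent = 0L, progressor = 0L),
        nBins = 30L,
        missingness = c(bmi = 0.5, surgical_margin_mm = 0.2))
    sim <- simulateCohort(cfg, seed = 31L)
    pts <- patients(sim$cohort)
    expect_false(any(is.na(pts$outcome_time)))
    expect_false(any(is.na(pts$outcome_event)))
    expect_gt(mean(is.na(pts$bmi)), 0.35)
    expect_lt(mean(is.na(pts$bmi)), 0.65)
    expect_gt(mean(is.na(pts$surgical_margin_mm)), 0.08)
})

test_that("latent mode with zero effects decouples cohort labels from features", {
    cfg <- simulationConfig(
        mode = "latent",
        nPatients = c(nonrecurrent = 400L, recurrent = 300L,
                      progressor = 300L),
        nBins = 30L,
        hazard = list(shape = 1.2, scaleRecurrence = 180,
                      scaleProgression = 240,
                      betaRecurrence = c(snv_divergence = 0),
                      betaProgression = c(snv_burden = 0)))
    sim <- simulateCohort(cfg, seed = 41L)
    tr <- sim$truth
    expect_gt(length(unique(tr$cohort)), 1L)
    hiBurden <- tr$snv_burden > median(tr$snv_burden)
    p <- suppressWarnings(chisq.test(table(hiBurden, tr$cohort))$p.value)
    expect_gt(p, 0.05)
})

test_that("latent mode with effects produces the configured association directions", {
    cfg <- simulationConfig(
        mode = "latent",
        nPatients = c(nonrecurrent = 200L, recurrent = 150L,
                      progressor = 150L),
        nBins = 30L)
    sim <- simulateCohort(cfg, seed = 51L)
    tr <- sim$truth
    prog <- tr$cohort == "progressor"
    # burden drives progression in the default beta map
    expect_gt(mean(tr$snv_burden[prog]), mean(tr$snv_burden[!prog]))
})

test_that("the anchored configuration reproduces its own moments", {
    cfg <- paperLikeConfig()
    expect_identical(cfg$mode, "conditional")
    expect_equal(sum(cfg$nPatients), 224L)
    m <- cfg$snvBurden$progressor
    expect_equal(m$mean, 39.7)
    expect_equal(m$mean + m$mean^2 / m$size, 46.2^2, tolerance = 1e-9)
    b <- cfg$cnaDivergence$nonrecurrent
    expect_equal(b$a / (b$a + b$b), 0.774, tolerance = 1e-9)
})
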