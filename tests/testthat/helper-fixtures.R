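# Fixture builders and independent oracles shared across the suite.

makeVS <- function(sid, pid, positions) {
    SampleVariantSet(sid, pid, data.frame(
        chrom = rep("chr1", length(positions)), pos = positions,
        ref = rep("A", length(positions)), alt = rep("T", length(positions))))
}

makeCNA <- function(sid, pid, log2, binBp = 50000L, chrom = NULL) {
    n <- length(log2)
    chrom <- chrom %||% rep("chr1", n)
    widths <- rep(binBp, length.out = n)
    CopyNumberProfile(sid, pid, chrom, (seq_len(n) - 1L) * binBp,
                      (seq_len(n) - 1L) * binBp + widths, log2)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

makeIHC <- function(p, marker = "ER", sid = "S1") IHCProfile(sid, marker, p)

# Brute-force paired-set divergence: classify every element of the union as
# shared or private, one at a time.
bruteSetDivergence <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(NA_real_)
    private <- vapply(u, function(x) xor(x %in% a, x %in% b), logical(1))
    100 * sum(private) / length(u)
}

# Brute-force bin-by-bin CNA divergence on equal-width grids: walk the bins
# and tally union/shared bp, optionally requiring matching direction.
bruteCnaDivergence <- function(la, lb, thr = 0.3, directionAware = FALSE) {
    unionBp <- 0; sharedBp <- 0
    for (i in seq_along(la)) {
        if (is.na(la[i]) || is.na(lb[i])) next
        aAlt <- abs(la[i]) > thr
        bAlt <- abs(lb[i]) > thr
        if (aAlt || bAlt) unionBp <- unionBp + 1
        if (aAlt && bAlt &&
            (!directionAware || sign(la[i]) == sign(lb[i])))
            sharedBp <- sharedBp + 1
    }
    if (unionBp == 0) return(NA_real_)
    100 * (unionBp - sharedBp) / unionBp
}

# Minimum-cost transport between two histograms on ordered categories with
# unit spacing, solved as a linear program (independent of the CDF formula).
lpTransportEmd <- function(pa, pb) {
    k <- length(pa)
    cost <- as.vector(outer(seq_len(k), seq_len(k),
                            function(i, j) abs(i - j)))
    # variables x_ij (row-major i fixed): rows sum to pa, cols sum to pb
    A3 <- matrix(0, nrow = 2 * k - 1, ncol = k * k)
    for (i in seq_len(k))
        A3[i, (i - 1) * k + seq_len(k)] <- 1
    for (j in seq_len(k - 1))           # last column constraint redundant
        A3[k + j, (seq_len(k) - 1) * k + j] <- 1
    b3 <- c(pa, pb[seq_len(k - 1)])
    sol <- boot::simplex(a = cost, A3 = A3, b3 = b3, maxi = FALSE)
    unname(sol$value)
}

# Exhaustive Youden scan over a fine grid spanning beyond the risk range.
bruteYouden <- function(risks, events) {
    grid <- sort(unique(c(risks, min(risks) - 1, max(risks) + 1,
                          seq(min(risks) - 1, max(risks) + 1,
                              length.out = 2001))))
    J <- vapply(grid, function(t) {
        hi <- risks > t
        mean(hi[events == 1]) + mean(!hi[events == 0]) - 1
    }, numeric(1))
    max(J)
}

# Random valid IHC proportion vector.
randomProfile <- function(k) {
    g <- stats::rgamma(k, shape = 1)
    g / sum(g)
}

# Nine-patient cohort covering every outcome type, with hand-derivable
# endpoint tables.
handCohortPatients <- function() {
    data.frame(
        patient_id = paste0("P", 1:9),
        cohort = c("nonrecurrent", "nonrecurrent", "nonrecurrent",
                   "recurrent", "recurrent", "recurrent",
                   "progressor", "progressor", "progressor"),
        outcome_time = c(80, 120, 65, 30, 45, 12, 50, 24, 90),
        outcome_event = c("none", "none", "none",
                          "dcis_recurrence", "dcis_recurrence",
                          "dcis_recurrence",
                          "progression", "progression", "progression"),
        sample_id_1 = paste0("P", 1:9, "_S1"),
        sample_id_2 = paste0("P", 1:9, "_S2"))
}

# Small simulated cohort shared by several test files (generation is cheap
# but not free; memoised per test run).
.sharedSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simulationConfig(
                mode = "conditional",
                nPatients = c(nonrecurrent = 30L, recurrent = 20L,
                              progressor = 15L),
                nBins = 120L)
            cache <<- simulateCohort(cfg, seed = 424L)
        }
        cache
    }
})
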