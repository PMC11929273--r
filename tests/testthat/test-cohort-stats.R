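test_that("mannWhitney reproduces the exact small-sample distribution", {
    # fully separated groups of 3: U = 0, exact two-sided p = 2/20
    res <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
    expect_equal(res$statistic, 0)
    expect_equal(res$p, 0.1)
    # identical groups: p near 1
    res2 <- mannWhitney(1:10, 1:10)
    expect_gt(res2$p, 0.9)
    # location-shift invariance of U
    a <- rnorm(8); b <- rnorm(9)
    expect_equal(mannWhitney(a, b)$statistic,
                 mannWhitney(a + 5, b + 5)$statistic)
    expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("holmSidak is a monotone step-down adjustment, never below raw", {
    p <- c(0.01, 0.04, 0.03, 0.5)
    adj <- holmSidak(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # sorted adjusted values are non-decreasing in raw order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # single comparison: unchanged
    expect_equal(holmSidak(0.2), 0.2)
    # first step is the Sidak correction at full family size
    expect_equal(min(adj), 1 - (1 - 0.01)^4)
})

test_that("kruskalWallisDunn matches hand-computed pooled-rank statistics", {
    v <- c(1, 2, 3, 4, 5, 6)
    g <- c("a", "a", "b", "b", "c", "c")
    res <- kruskalWallisDunn(v, g)
    # H = 12/(6*7) * 2*(1.5^2+3.5^2+5.5^2) - 3*7
    expect_equal(res$statistic, 12 / 42 * 2 * (1.5^2 + 3.5^2 + 5.5^2) - 21)
    pw <- res$pairwise
    # mean ranks 1.5/3.5/5.5; se = sqrt(3.5 * (1/2+1/2)) for each pair
    zAdj <- 2 / sqrt(3.5)
    expect_equal(abs(pw$statistic[pw$group_i == "a" & pw$group_j == "b"]), zAdj)
    expect_equal(abs(pw$statistic[pw$group_i == "b" & pw$group_j == "c"]), zAdj)
    expect_equal(abs(pw$statistic[pw$group_i == "a" & pw$group_j == "c"]), 2 * zAdj)
    expect_true(all(pw$adjusted_p >= pw$raw_p))
    expect_error(kruskalWallisDunn(1:3, rep("a", 3)), "at least 2 groups")
    # two groups: omnibus only
    expect_null(kruskalWallisDunn(1:6, rep(c("a", "b"), 3))$pairwise)
})

test_that("pairedSignTest is the exact binomial test on informative pairs", {
    expect_equal(pairedSignTest(2:9, 1:8), 2 * 0.5^8)
    expect_equal(pairedSignTest(c(1, 2, 3, 4, 8, 7, 6, 5),
                                c(2, 1, 4, 3, 7, 8, 5, 6)), 1)
    # 5 positive, 1 negative, 2 ties -> binomial(6): 14/64
    x <- c(2, 3, 4, 5, 6, 1, 7, 8)
    y <- c(1, 2, 3, 4, 5, 2, 7, 8)
    expect_equal(pairedSignTest(x, y), 14 / 64)
    expect_error(pairedSignTest(1:3, 1:3), "no informative pairs")
})

test_that("anovaTukey reduces to the squared t for two groups and flags no-variance", {
    set.seed(9)
    a <- rnorm(12); b <- rnorm(10, 1)
    res <- anovaTukey(c(a, b), rep(c("a", "b"), c(12, 10)))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2)
    expect_equal(res$p, tt$p.value)
    nov <- anovaTukey(rep(3, 9), rep(c("a", "b", "c"), 3))
    expect_true(is.na(nov$p))
    expect_identical(nov$note, "no variance in values")
})

test_that("anovaTukey gives the shifted pair the smallest adjusted p", {
    set.seed(10)
    v <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 2))
    g <- rep(c("a", "b", "c"), each = 20)
    res <- anovaTukey(v, g)
    pw <- res$pairwise
    acPair <- pw$adjusted_p[(pw$group_i == "c" & pw$group_j == "a") |
                            (pw$group_i == "a" & pw$group_j == "c")]
    expect_equal(min(pw$adjusted_p),
                 min(pw$adjusted_p[pw$group_i == "c" | pw$group_j == "c"]))
    expect_lt(acPair, 0.001)
    abPair <- pw$adjusted_p[(pw$group_i == "b" & pw$group_j == "a") |
                            (pw$group_i == "a" & pw$group_j == "b")]
    expect_lt(acPair, abPair)
})

test_that("mixedAnovaSqrt approaches ordinary ANOVA as within-patient noise vanishes", {
    # with (near-)duplicated samples per patient, inference should collapse
    # to the one-value-per-patient ANOVA on sqrt values; exact duplicates put
    # the residual variance on the boundary, so a tiny jitter is used
    set.seed(12)
    n <- 30
    vals <- rbeta(n, 2, 5) + 0.05
    grp <- rep(c("a", "b", "c"), each = 10)
    jit <- sqrt(rep(vals, each = 2)) + rnorm(2 * n, 0, 1e-4)
    res <- mixedAnovaSqrt(jit^2, rep(seq_len(n), each = 2),
                          rep(grp, each = 2))
    ref <- anovaTukey(sqrt(vals), grp)
    expect_equal(res$statistic, ref$statistic, tolerance = 0.02)
    expect_equal(res$df[1], ref$df[1])
    expect_equal(res$p, ref$p, tolerance = 0.05)
    expect_error(mixedAnovaSqrt(c(-0.1, 0.2), c(1, 1), c("a", "b")),
                 "non-negative")
})

test_that("mixedAnovaSqrt handles per-sample noise and recovers a cohort effect", {
    set.seed(13)
    n <- 45
    grp <- rep(c("a", "b", "c"), each = 15)
    mu <- c(a = 0.15, b = 0.15, c = 0.4)[grp]
    pat <- abs(rnorm(n, mu, 0.05))
    v <- abs(c(pat + rnorm(n, 0, 0.02), pat + rnorm(n, 0, 0.02)))
    res <- mixedAnovaSqrt(v, rep(seq_len(n), 2), rep(grp, 2))
    expect_lt(res$p, 0.01)
    pw <- res$pairwise
    expect_lt(min(pw$adjusted_p), 0.01)
})

test_that("rfGiniRanking is seed-deterministic and finds the informative feature", {
    set.seed(20)
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    X <- as.data.frame(matrix(rnorm(n * 10), n))
    X$V1 <- y + rnorm(n, 0, 0.1)
    r1 <- rfGiniRanking(X, y, nTrees = 200, seed = 42)
    r2 <- rfGiniRanking(X, y, nTrees = 200, seed = 42)
    expect_identical(r1, r2)
    expect_identical(r1$feature[1], "V1")
    expect_true(all(r1$importance >= 0))
    expect_true(all(diff(r1$importance) <= 0))
    # permuting columns still ranks the informative feature first
    perm <- X[, c(5, 1, 7, 2, 3, 4, 6, 8, 9, 10)]
    expect_identical(rfGiniRanking(perm, y, nTrees = 200, seed = 42)$feature[1],
                     "V1")
    expect_error(rfGiniRanking(X, rep(1, n)), "single class")
})

test_that("logisticDiscriminator reports Wald inference, AIC and degeneracies", {
    set.seed(21)
    n <- 2000
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.4)           # independent of x
    res <- logisticDiscriminator(data.frame(x = x), y)
    cf <- res$coefficients
    expect_lt(abs(cf$estimate[cf$term == "x"]), 0.12)
    expect_gt(cf$wald_p[cf$term == "x"], 0.01)
    expect_equal(res$n, n)
    # intercept-only AIC closed form: 2k - 2 logL at the fitted prevalence
    k <- sum(y)
    res0 <- logisticDiscriminator(as.data.frame(matrix(numeric(), n, 0)), y)
    expect_equal(res0$aic,
                 2 - 2 * (k * log(k / n) + (n - k) * log(1 - k / n)))
    # duplicated feature: rank deficiency flagged
    expect_warning(
        resDup <- logisticDiscriminator(data.frame(a = x, b = x), y),
        "rank-deficient")
    expect_true(resDup$rankDeficient)
    # separable data flagged
    set.seed(30)
    xs <- c(rnorm(20) - 5, rnorm(20) + 5)
    expect_warning(
        resSep <- logisticDiscriminator(data.frame(x = xs),
                                        rep(c(0, 1), each = 20)),
        "separation")
    expect_true(resSep$separationFlagged)
})

test_that("aicCompare refits on the common complete-case subset", {
    set.seed(23)
    n <- 800
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(x1))
    feats <- data.frame(x1 = x1, x2 = x2)
    feats$x2[sample(n, 100)] <- NA
    cmp <- aicCompare(list(full = c("x1", "x2"), reduced = "x1"), feats, y)
    expect_equal(unique(cmp$n), n - sum(is.na(feats$x2)))
    # a pure-noise extra feature can lower AIC by at most its 2k penalty
    expect_lte(cmp$aic[cmp$model == "full"] -
               cmp$aic[cmp$model == "reduced"], 2 + 1e-8)
    # identical specifications get identical AIC
    cmp2 <- aicCompare(list(a = "x1", b = "x1"), feats, y)
    expect_equal(cmp2$aic[1], cmp2$aic[2])
    expect_error(aicCompare(list(a = "x1", b = "x2"),
                            data.frame(x1 = NA_real_, x2 = NA_real_), 1),
                 "empty common complete-case")
})

test_that("nested logistic models never lose log-likelihood", {
    set.seed(24)
    n <- 300
    f <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, plogis(0.5 * f$a))
    small <- logisticDiscriminator(f["a"], y)
    big <- logisticDiscriminator(f, y)
    # -2logL = AIC - 2k
    expect_lte(big$aic - 2 * 3, small$aic - 2 * 2 + 1e-8)
})
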