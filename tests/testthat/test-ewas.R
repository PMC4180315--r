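test_that("null p-values are uniform and an injected effect is detected", {
    set.seed(51)
    n <- 400
    pheno <- rbinom(n, 1, 0.3)
    chips <- rep(sprintf("c%02d", 1:34), length.out = n)
    covs <- data.frame(age = rnorm(n, 56, 6))
    # null probes, no chip variance: OLS p-values uniform by KS
    pv <- replicate(400, {
        fitProbeAssociation(rnorm(n, 0.5, 0.05), pheno, covs,
                            chips, mode = "ols")$pvalue
    })
    expect_gt(ks.test(pv, "punif")$p.value, 0.01)
    # delta-beta 0.15 at n = 400 is detected far below genome-wide alpha
    y <- 0.4 + 0.15 * pheno + rnorm(n, 0, 0.05)
    hit <- fitProbeAssociation(y, pheno, covs, chips, mode = "lmm")
    expect_lt(hit$pvalue, 1e-7)
    expect_lt(abs(hit$estimate - 0.15), 0.01)
})

test_that("chip random effect absorbs batch structure that inflates OLS", {
    set.seed(52)
    n <- 480
    chips <- rep(sprintf("c%02d", 1:40), each = 12)
    # phenotype correlated with chip (confounded batches)
    chipEff <- rnorm(40, 0, 0.05)
    pheno <- rbinom(40, 1, 0.5)[match(chips, sprintf("c%02d", 1:40))]
    y <- 0.5 + chipEff[match(chips, sprintf("c%02d", 1:40))] +
        rnorm(n, 0, 0.01)
    lmm <- fitProbeAssociation(y, pheno, NULL, chips, mode = "lmm")
    ols <- fitProbeAssociation(y, pheno, NULL, chips, mode = "ols")
    # the pure chip-effect probe: lmm stays calm, ols inflates
    expect_lt(abs(lmm$estimate / lmm$se), abs(ols$estimate / ols$se))
    expect_gt(lmm$pvalue, 1e-4)
})

test_that("zero-variance and undersized probes are refused or skipped", {
    expect_error(fitProbeAssociation(rep(0.5, 10), rbinom(10, 1, 0.5)),
                 "at least 30")
    r <- fitProbeAssociation(rep(0.5, 50), rbinom(50, 1, 0.5),
                             NULL, rep(c("a", "b"), 25), mode = "ols")
    expect_true(is.na(r$pvalue))
    expect_match(r$note, "zero variance")
})

test_that("runEwas collapses replicates and summarizes by cluster", {
    sim <- smallSim(seed = 61)
    ew <- runEwas(sim$study, mode = "ols", alpha = 1e-7)
    cd <- SummarizedExperiment::colData(sim$study)
    expect_equal(S4Vectors::metadata(ew)$nSamples,
                 length(unique(cd$subject_id)))
    expect_equal(nrow(ew), nrow(sim$study))
    # alpha = 1 flags every probe not SNP-masked
    ew1 <- runEwas(sim$study, mode = "ols", alpha = 1 - 1e-12,
                   applySnpMask = TRUE)
    expect_true(all(ew1$significant[!ew1$snp_masked &
                                    !is.na(ew1$pvalue)]))
    expect_false(any(ew1$significant[ew1$snp_masked]))
    # cluster summary counts partition the significant hits
    tab <- iccTable(sim$study)
    fit <- fitTruncatedMixture(tab$icc[!is.na(tab$icc)])
    cl <- classifySites(tab, fit)
    summ <- summarizeByCluster(ew, cl)
    expect_equal(sum(summ$counts$significant), sum(ew$significant))
    expect_equal(sum(summ$counts$total), sum(!is.na(cl$cluster)))
    # mismatched probe universes are refused
    expect_error(summarizeByCluster(ew[-1, ], cl), "universes differ")
})

test_that("effects land in the high-reliability cluster and ols >= lmm hits", {
    sim <- simulateMethylationStudy(simulationConfig(
        nSubjects = 300, nReplicatePairs = 60, nReplicateTriples = 2,
        nProbes = 150, effectProbes = 12, effectSize = 0.15, seed = 62))
    ewL <- runEwas(sim$study, alpha = 1e-7, mode = "lmm")
    ewO <- runEwas(sim$study, alpha = 1e-7, mode = "ols")
    expect_gte(sum(ewO$significant), sum(ewL$significant))
    expect_gt(sum(ewL$significant), 0)
    tab <- iccTable(sim$study)
    fit <- fitTruncatedMixture(tab$icc[!is.na(tab$icc)])
    summ <- summarizeByCluster(ewL, classifySites(tab, fit))
    expect_gte(summ$fractionHigh, 0.9)
})

test_that("Bonferroni power follows the noncentral distribution", {
    # null limit: power tends to the per-test level
    expect_equal(powerBonferroni(2500, 1e-12, 10, alphaTotal = 0.05),
                 0.005, tolerance = 1e-4)
    # monotone in n, r2; decreasing in the test burden
    expect_gt(powerBonferroni(3000, 0.01, 1e5),
              powerBonferroni(2500, 0.01, 1e5))
    expect_gt(powerBonferroni(2500, 0.02, 1e5),
              powerBonferroni(2500, 0.01, 1e5))
    expect_gt(powerBonferroni(2500, 0.01, 1e4),
              powerBonferroni(2500, 0.01, 1e5))
    # Monte-Carlo rejection rate agrees with the analytic power
    set.seed(71)
    n <- 300; r2 <- 0.05; nTests <- 100
    crit <- 0.05 / nTests
    rej <- mean(replicate(4000, {
        x <- rnorm(n)
        b <- sqrt(r2 / (1 - r2))
        y <- b * x + rnorm(n)
        summary(lm(y ~ x))$coefficients[2, 4] < crit
    }))
    expect_equal(rej, powerBonferroni(n, r2, nTests), tolerance = 0.02)
    expect_error(powerBonferroni(2500, 1.2, 10), "r2")
})

test_that("power gain behaves at its limits", {
    expect_equal(powerGain(fractionExcluded = 0)$maxGain, 0)
    g <- powerGain(r2Grid = c(0.2, 0.4))   # saturated effects
    expect_lt(g$maxGain, 1e-6)
    expect_error(powerGain(r2Grid = numeric()), "empty")
})
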