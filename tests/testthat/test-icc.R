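test_that("variance components match hand ANOVA on toy tables", {
    # {0.2,0.3} vs {0.6,0.7}: MSW = 0.005, MSB = 0.16, k0 = 2
    vc <- anovaComponents(c(0.2, 0.3, 0.6, 0.7), c("a", "a", "b", "b"))
    expect_equal(vc$sigma2Within, 0.005)
    expect_equal(vc$sigma2Between, 0.0775)
    expect_equal(vc$k0, 2)
    expect_equal(iccFromComponents(vc), 0.0775 / 0.0825)
    # zero within-variance
    vc2 <- anovaComponents(c(0.5, 0.5, 0.8, 0.8), c("a", "a", "b", "b"))
    expect_equal(vc2$sigma2Within, 0)
    expect_gt(vc2$sigma2Between, 0)
    expect_equal(iccFromComponents(vc2), 1)
    # MSB < MSW: raw estimate negative, truncated to exactly 0
    vc3 <- anovaComponents(c(0.2, 0.8, 0.8, 0.2), c("a", "a", "b", "b"))
    expect_lt(vc3$sigma2BetweenRaw, 0)
    expect_identical(vc3$sigma2Between, 0)
    expect_identical(iccFromComponents(vc3), 0)
})

test_that("unbalanced sets use the k0 coefficient", {
    # sets of size 2 and 3: k0 = (5 - (4+9)/5) / 1 = 2.4
    vc <- anovaComponents(c(0.1, 0.2, 0.5, 0.6, 0.7),
                          c("a", "a", "b", "b", "b"))
    expect_equal(vc$k0, 2.4)
    N <- 5; J <- 2
    msw <- (0.005 + 0.02) / (N - J)
    grand <- 2.1 / 5
    msb <- (2 * (0.15 - grand)^2 + 3 * (0.6 - grand)^2) / (J - 1)
    expect_equal(vc$sigma2Within, msw)
    expect_equal(vc$sigma2Between, (msb - msw) / 2.4)
})

test_that("degenerate layouts are flagged unestimable, not zero", {
    vc <- anovaComponents(c(0.1, 0.2, 0.3), c("a", "a", "b"))
    expect_false(vc$estimable)
    expect_true(is.na(vc$sigma2Between))
    expect_true(is.na(iccFromComponents(vc)))
    # missingness shrinking a set below 2 drops it
    vc2 <- anovaComponents(c(0.1, NA, 0.3, 0.4, 0.5, 0.6),
                           c("a", "a", "b", "b", "c", "c"))
    expect_true(vc2$estimable)
    expect_equal(vc2$nSets, 2)
})

test_that("ICC is invariant to affine transformation", {
    set.seed(42)
    y <- rnorm(20, 0.5, 0.1)
    g <- rep(letters[1:10], each = 2)
    base <- iccFromComponents(anovaComponents(y, g))
    for (ab in list(c(2.5, -0.3), c(-1.7, 10), c(0.01, 0))) {
        tr <- iccFromComponents(anovaComponents(ab[1] * y + ab[2], g))
        expect_lt(abs(tr - base), 1e-12)
    }
})

test_that("ICC rises with the true between/within variance ratio", {
    set.seed(7)
    ratios <- c(0.1, 0.5, 1, 3, 10)
    J <- 400
    est <- vapply(ratios, function(r) {
        tau <- rnorm(J, 0, sqrt(r))
        y <- rep(tau, each = 2) + rnorm(2 * J)
        iccFromComponents(anovaComponents(y, rep(seq_len(J), each = 2)))
    }, numeric(1))
    expect_true(all(diff(est) > 0))
    expect_true(all(est >= 0 & est <= 1))
})

test_that("method of moments agrees with REML on balanced duplicates", {
    set.seed(19)
    J <- 2000
    tau <- rnorm(J, 0, sqrt(0.03))
    y <- rep(tau, each = 2) + rnorm(2 * J, 0, sqrt(0.01))
    g <- rep(seq_len(J), each = 2)
    vc <- anovaComponents(y, g)
    fit <- lme4::lmer(y ~ 1 + (1 | g),
                      control = lme4::lmerControl(calc.derivs = FALSE))
    v <- as.data.frame(lme4::VarCorr(fit))$vcov
    expect_equal(vc$sigma2Between, v[1], tolerance = 0.02)
    expect_equal(vc$sigma2Within, v[2], tolerance = 0.02)
})

test_that("iccTable reproduces per-probe ANOVA and subject-level SD", {
    me <- tinyStudy()
    tab <- iccTable(me)
    expect_equal(tab$icc[1], 0.0775 / 0.0825)   # cg1 is the toy table
    expect_identical(tab$icc[3], 0)             # constant probe
    expect_identical(tab$sd[3], 0)
    # SD over first sample per subject: cg1 -> sd(0.2, 0.6, 0.5)
    expect_equal(tab$sd[1], sd(c(0.2, 0.6, 0.5)))
    expect_equal(tab$n_sets[1], 2)
    # no replicates -> error
    sheet <- data.frame(sample_id = c("s1", "s2"),
                        subject_id = c("a", "b"))
    b <- matrix(runif(4), 2, 2,
                dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
    expect_error(iccTable(MethylationExperiment(b, sheet)),
                 "no replicate sets")
})

test_that("estimated ICC tracks the generator truth", {
    sim <- simulateMethylationStudy(simulationConfig(
        nSubjects = 200, nReplicatePairs = 80, nReplicateTriples = 4,
        nProbes = 400, effectProbes = 0, seed = 15))
    tab <- iccTable(sim$study)
    rho <- cor(tab$icc, sim$truth$icc, method = "spearman",
               use = "complete.obs")
    expect_gt(rho, 0.8)
    # high-SD probes are predominantly high-ICC (monotone trend)
    hi <- tab$sd > quantile(tab$sd, 0.8)
    expect_gt(mean(tab$icc[hi], na.rm = TRUE),
              mean(tab$icc[!hi], na.rm = TRUE))
})

test_that("chip-effect ICC separates batch-dominated from reliable probes", {
    # sigma2_chip dominant: icc_chip near 1, replicate ICC near 0
    lawChip <- function(n) data.frame(sigma2_chip = rep(0.02, n),
                                      sigma2_e = rep(1e-5, n),
                                      icc = rep(0.01, n))
    simC <- simulateMethylationStudy(simulationConfig(
        nSubjects = 150, nReplicatePairs = 60, nReplicateTriples = 0,
        nProbes = 60, effectProbes = 0, varianceLaw = lawChip,
        fractionZeroIcc = 0, seed = 23))
    tabC <- iccTable(simC$study)
    expect_gt(median(tabC$icc_chip, na.rm = TRUE), 0.6)
    expect_lt(median(tabC$icc, na.rm = TRUE), 0.3)
    # no chip variance: icc_chip concentrated near 0
    lawNo <- function(n) data.frame(sigma2_chip = rep(0, n),
                                    sigma2_e = rep(4e-4, n),
                                    icc = rep(0.5, n))
    simN <- simulateMethylationStudy(simulationConfig(
        nSubjects = 150, nReplicatePairs = 60, nReplicateTriples = 0,
        nProbes = 60, effectProbes = 0, varianceLaw = lawNo,
        fractionZeroIcc = 0, seed = 24))
    expect_lt(median(iccChip(simN$study), na.rm = TRUE), 0.2)
    # balanced two-chip toy equals hand ANOVA with chip as grouping
    me <- tinyStudy()
    byChip <- iccChip(me)
    hand <- iccFromComponents(anovaComponents(
        c(0.2, 0.3, 0.6, 0.7), c("c1", "c2", "c1", "c2")))
    expect_equal(unname(byChip[1]), hand)
    # single chip is unestimable
    sheet1 <- data.frame(sample_id = paste0("s", 1:4),
                         subject_id = c("a", "a", "b", "b"),
                         chip_id = "c1")
    b <- matrix(runif(8), 2, 4,
                dimnames = list(c("cg1", "cg2"), paste0("s", 1:4)))
    expect_error(iccChip(MethylationExperiment(b, sheet1)), "single chip")
})

test_that("ICC-SD trend is monotone for monotone input and flat for constant", {
    sdv <- seq(0.01, 0.3, length.out = 200)
    tab <- S4Vectors::DataFrame(probe_id = as.character(1:200),
                                icc = pmin(1, sdv * 3), sd = sdv)
    tr <- iccSdTrend(tab)
    expect_true(all(diff(tr$icc) > -1e-6))
    expect_gt(cor(tr$sd, tr$icc, method = "spearman"), 0.9)
    tab$icc <- rep(0.4, 200)
    trFlat <- iccSdTrend(tab)
    expect_equal(trFlat$icc, rep(0.4, nrow(trFlat)), tolerance = 1e-10)
    tab$sd <- rep(0.1, 200)
    expect_warning(iccSdTrend(tab), "flat")
    expect_error(iccSdTrend(tab[1:10, ]), "at least 50")
})
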