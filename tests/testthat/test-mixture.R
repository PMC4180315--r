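# draw from the censored mixture itself: component, then normal, then
# censor at 0 (used as the generating process for censored-model tests)
rCensoredMixture <- function(n, p, mu1, s1, mu2, s2) {
    low <- runif(n) < p
    x <- ifelse(low, rnorm(n, mu1, s1), rnorm(n, mu2, s2))
    pmin(pmax(x, 0), 1)
}

test_that("censored log likelihood matches analytic values", {
    expect_equal(censoredMixtureLoglik(
        list(p = 1, mu1 = 0, sigma1 = 1, mu2 = 0.7, sigma2 = 0.1),
        rep(0, 4)), 4 * log(0.5))
    # p = 0 reduces to the plain normal log likelihood of component 2
    x <- c(0.3, 0.5, 0.72, 0.9)
    expect_equal(censoredMixtureLoglik(
        list(p = 0, mu1 = 0.1, sigma1 = 0.1, mu2 = 0.7, sigma2 = 0.12), x),
        sum(dnorm(x, 0.7, 0.12, log = TRUE)))
    expect_error(censoredMixtureLoglik(
        list(p = 0.5, mu1 = 0, sigma1 = -1, mu2 = 0, sigma2 = 1), x),
        "> 0")
})

test_that("the true parameters maximize the expected censored loglik", {
    set.seed(31)
    x <- rCensoredMixture(2e4, 0.55, 0.15, 0.14, 0.67, 0.14)
    true <- list(p = 0.55, mu1 = 0.15, sigma1 = 0.14, mu2 = 0.67,
                 sigma2 = 0.14)
    llTrue <- censoredMixtureLoglik(true, x) / length(x)
    for (d in list(c(mu1 = 0.08), c(mu2 = -0.08), c(p = 0.2),
                   c(sigma2 = 0.08))) {
        pert <- true
        pert[[names(d)]] <- pert[[names(d)]] + d
        expect_gt(llTrue, censoredMixtureLoglik(pert, x) / length(x))
    }
})

test_that("truncated log likelihood matches analytic values", {
    x <- c(0.3, 0.5, 0.9)
    expect_equal(truncatedMixtureLoglik(
        list(p = 0, mu1 = 0.1, sigma1 = 0.2, mu2 = 0.7, sigma2 = 0.12),
        x, n0 = 0),
        sum(dnorm(x, 0.7, 0.12, log = TRUE)))
    # single point at mu1 with p = 1, p0 = 0
    expect_equal(truncatedMixtureLoglik(
        list(p = 1, mu1 = 0.4, sigma1 = 0.2, mu2 = 0.7, sigma2 = 0.1),
        0.4, n0 = 0),
        log(dnorm(0) / (0.2 * (1 - pnorm(-0.4 / 0.2)))))
    # zero term uses the sample proportion
    ll <- truncatedMixtureLoglik(
        list(p = 0.5, mu1 = 0.1, sigma1 = 0.2, mu2 = 0.7, sigma2 = 0.1),
        c(0.2, 0.8), n0 = 2)
    expect_true(is.finite(ll))
    expect_error(truncatedMixtureLoglik(
        list(p = 0.5, mu1 = 0.1, sigma1 = 0.2, mu2 = 0.7, sigma2 = 0.1),
        c(0, 0.5)), "strictly positive")
})

test_that("censored EM recovers generating parameters", {
    set.seed(77)
    x <- rCensoredMixture(2e4, 0.4, 0.1, 0.1, 0.7, 0.1)
    fit <- fitCensoredMixture(x, seed = 3)
    expect_true(fit@converged)
    expect_equal(fit@p, 0.4, tolerance = 0.03)
    expect_equal(fit@mu1, 0.1, tolerance = 0.03)
    expect_equal(fit@sigma1, 0.1, tolerance = 0.03)
    expect_equal(fit@mu2, 0.7, tolerance = 0.03)
    expect_equal(fit@sigma2, 0.1, tolerance = 0.03)
})

test_that("with no zeros the censored fit matches a plain Gaussian-mixture EM", {
    set.seed(78)
    x <- rCensoredMixture(5e3, 0.5, 0.25, 0.05, 0.75, 0.05)
    stopifnot(all(x > 0))
    fit <- fitCensoredMixture(x, seed = 2)
    suppressPackageStartupMessages(library(mclust))
    mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    mu <- mc$parameters$mean
    expect_equal(fit@mu1, unname(min(mu)), tolerance = 0.01)
    expect_equal(fit@mu2, unname(max(mu)), tolerance = 0.01)
    expect_equal(sort(c(fit@p, 1 - fit@p)),
                 sort(unname(mc$parameters$pro)), tolerance = 0.02)
    expect_equal(fit@loglik, mc$loglik, tolerance = 1e-3)
})

test_that("truncated EM recovers the published-scale parameters", {
    x <- simulateICCSample(0.076, 0.67, 0.04, 0.28, 0.72, 0.11,
                           n = 1e4, seed = 5)
    fit <- fitTruncatedMixture(x, seed = 5)
    expect_true(fit@converged)
    expect_equal(fit@p0, mean(x == 0))
    expect_equal(fit@p, 0.67, tolerance = 0.05)
    expect_equal(fit@mu1, 0.04, tolerance = 0.06)
    expect_equal(fit@sigma1, 0.28, tolerance = 0.06)
    expect_equal(fit@mu2, 0.72, tolerance = 0.02)
    expect_equal(fit@sigma2, 0.11, tolerance = 0.02)
})

test_that("degenerate inputs are handled: all zeros, two-point data", {
    fitZ <- fitTruncatedMixture(rep(0, 200))
    expect_equal(fitZ@p0, 1)
    expect_false(fitZ@converged)
    # two repeated values, no zeros: components center on the points
    x <- rep(c(0.2, 0.8), each = 100)
    fit2 <- fitTruncatedMixture(x, seed = 1)
    expect_equal(fit2@mu1, 0.2, tolerance = 0.02)
    expect_equal(fit2@mu2, 0.8, tolerance = 0.02)
    expect_equal(fit2@p, 0.5, tolerance = 0.02)
})

test_that("fitted mixture densities integrate to one", {
    x <- simulateICCSample(0.08, 0.6, 0.05, 0.25, 0.7, 0.1,
                           n = 5e3, seed = 9)
    ft <- fitTruncatedMixture(x, seed = 9)
    dens <- function(z) ft@p * dTruncNorm(z, ft@mu1, ft@sigma1) +
        (1 - ft@p) * dnorm(z, ft@mu2, ft@sigma2)
    total <- ft@p0 +
        (1 - ft@p0) * integrate(dens, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
    fc <- fitCensoredMixture(x, seed = 9)
    densC <- function(z) fc@p * dnorm(z, fc@mu1, fc@sigma1) +
        (1 - fc@p) * dnorm(z, fc@mu2, fc@sigma2)
    massC <- fc@p * pnorm(-fc@mu1 / fc@sigma1) +
        (1 - fc@p) * pnorm(-fc@mu2 / fc@sigma2)
    totalC <- massC + integrate(densC, 0, Inf, rel.tol = 1e-10)$value
    expect_equal(totalC, 1, tolerance = 1e-6)
})

test_that("posterior probabilities behave as the fitted densities dictate", {
    fit <- table1TruncatedFit()
    # the wide low component (sigma1 = 0.28) keeps real density at 0.9,
    # so the posterior there is ~0.956, not arbitrarily close to 1
    expect_gt(posteriorHigh(fit, 0.9), 0.95)
    expect_gt(posteriorHigh(fit, 0.72), posteriorHigh(fit, 0.5))
    expect_lt(abs(posteriorHigh(fit, 0.37) - 0.01), 0.002)
    expect_lt(posteriorHigh(fit, 0.10), 0.01)
    pNone <- mixtureFit("truncated", p = 0, mu1 = 0.1, sigma1 = 0.1,
                        mu2 = 0.7, sigma2 = 0.1)
    expect_equal(posteriorHigh(pNone, c(0.05, 0.5, 0.95)), rep(1, 3))
    expect_error(posteriorHigh(fit, 0), "undefined at ICC = 0")
    # censored model defines a posterior at 0 through the censored masses
    fc <- table1CensoredFit()
    expect_lt(posteriorHigh(fc, 0), 0.01)
})

test_that("posterior-cutoff threshold solves pi(x) = cutoff", {
    fit <- table1TruncatedFit()
    th <- iccThresholdForPosterior(fit, 0.01)
    expect_lt(abs(posteriorHigh(fit, th) - 0.01), 1e-6)
    expect_lt(abs(th - 0.37), 0.01)
    # monotone in the cutoff
    expect_gt(iccThresholdForPosterior(fit, 0.5), th)
    # symmetric fit, cutoff 0.5 -> threshold at the midpoint
    sym <- mixtureFit("censored", p = 0.5, mu1 = 0.3, sigma1 = 0.1,
                      mu2 = 0.7, sigma2 = 0.1)
    expect_lt(abs(iccThresholdForPosterior(sym, 0.5) - 0.5), 1e-6)
})

test_that("classification partitions probes into zero/low/high", {
    fit <- table1TruncatedFit()
    icc <- c(0, 0.10, 0.37, 0.80, 0.45, 0, 0.2, NA)
    cl <- classifySites(icc, fit)
    expect_equal(as.character(cl$cluster[1]), "zero")
    expect_equal(as.character(cl$cluster[2]), "low")
    expect_equal(as.character(cl$cluster[4]), "high")
    expect_true(is.na(cl$cluster[8]))
    counts <- table(cl$cluster)
    expect_equal(sum(counts), sum(!is.na(icc)))
    # boundary: posterior exactly at the cutoff goes to high
    th <- iccThresholdForPosterior(fit, 0.01)
    clB <- classifySites(th, fit, piCutoff = posteriorHigh(fit, th))
    expect_equal(as.character(clB$cluster[1]), "high")
})

test_that("model comparison prefers the better likelihood, tie to truncated", {
    x <- simulateICCSample(0.12, 0.6, 0.05, 0.25, 0.7, 0.1,
                           n = 4e3, seed = 14)
    fc <- fitCensoredMixture(x, seed = 14)
    ft <- fitTruncatedMixture(x, seed = 14)
    cmp <- compareModels(fc, ft)
    # genuine excess of exact zeros beyond any censored-normal mass
    expect_equal(cmp$model, "truncated")
    expect_gt(cmp$loglikDiff, 0)
    # data generated from the censored model: censored fit within
    # sampling error of the winner
    set.seed(15)
    y <- rCensoredMixture(4e3, 0.55, 0.15, 0.14, 0.67, 0.14)
    cmp2 <- compareModels(fitCensoredMixture(y, seed = 15),
                          fitTruncatedMixture(y, seed = 15))
    if (cmp2$model == "truncated")
        expect_lt(cmp2$loglikDiff, 0.01 * abs(cmp2$chosen@loglik))
    # mismatched data sizes are refused
    ft2 <- fitTruncatedMixture(x[1:2000], seed = 1)
    expect_error(compareModels(fc, ft2), "different data sizes")
})
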