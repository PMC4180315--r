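# Scale floor for mixture components, on the ICC scale. Prevents the
# likelihood from diverging when a component collapses onto a point mass;
# degenerate data (e.g. two repeated values) converge with sigma at the
# floor instead of collapsing.
.MIN_SIGMA <- 1e-3

paramList <- function(params) {
    if (is(params, "MixtureFit"))
        params <- list(p = params@p, mu1 = params@mu1, sigma1 = params@sigma1,
                       mu2 = params@mu2, sigma2 = params@sigma2,
                       p0 = params@p0)
    if (is.null(params$p0)) params$p0 <- 0
    if (params$sigma1 <= 0 || params$sigma2 <= 0)
        stop("component standard deviations must be > 0")
    if (params$p < 0 || params$p > 1) stop("p must lie in [0,1]")
    params
}

# log of the normal density truncated below at 0, evaluated at x > 0
logdTN <- function(x, mu, sigma) {
    stats::dnorm(x, mu, sigma, log = TRUE) -
        stats::pnorm(mu / sigma, log.p = TRUE)
}

#' Truncated-normal density on (0, Inf)
#'
#' @param x evaluation points (> 0).
#' @param mu,sigma location and scale of the parent normal.
#' @return density values.
#' @export
dTruncNorm <- function(x, mu, sigma) exp(logdTN(x, mu, sigma))

# inverse-Mills quantities for a normal truncated ABOVE at 0 (censored
# observations): E[y | y <= 0] and E[y^2 | y <= 0]
censoredMoments <- function(mu, sigma) {
    alpha <- -mu / sigma
    h <- exp(stats::dnorm(alpha, log = TRUE) -
             stats::pnorm(alpha, log.p = TRUE))
    ey <- mu - sigma * h
    vy <- sigma^2 * pmax(1 - alpha * h - h^2, 0)
    list(ey = ey, ey2 = vy + ey^2)
}

#' Log likelihood of the censored normal mixture
#'
#' Both components are censored at 0: an observation equal to 0 contributes
#' the sub-zero mass \eqn{\Phi(-\mu_k/\sigma_k)} of its component, a
#' positive observation the normal density. The mixture is
#' \eqn{p \cdot c_1(x) + (1-p) \cdot c_2(x)} with p the low-reliability
#' (component 1) proportion.
#'
#' @param params a \linkS4class{MixtureFit} or list with \code{p},
#'   \code{mu1}, \code{sigma1}, \code{mu2}, \code{sigma2}.
#' @param iccs ICC values in [0, 1] (zeros are the censored observations).
#' @return total log likelihood.
#' @examples
#' censoredMixtureLoglik(list(p = 1, mu1 = 0, sigma1 = 1,
#'                            mu2 = 0.7, sigma2 = 0.1), rep(0, 4))
#' @export
censoredMixtureLoglik <- function(params, iccs) {
    q <- paramList(params)
    cens <- iccs == 0
    l1 <- ifelse(cens, stats::pnorm(-q$mu1 / q$sigma1, log.p = TRUE),
                 stats::dnorm(iccs, q$mu1, q$sigma1, log = TRUE))
    l2 <- ifelse(cens, stats::pnorm(-q$mu2 / q$sigma2, log.p = TRUE),
                 stats::dnorm(iccs, q$mu2, q$sigma2, log = TRUE))
    sum(logSumExpPair(log(q$p) + l1, log1p(-q$p) + l2))
}

logSumExpPair <- function(a, b) {
    m <- pmax(a, b)
    bad <- !is.finite(m)
    out <- m + log(exp(a - m) + exp(b - m))
    out[bad] <- m[bad]
    out
}

#' Log likelihood of the zero-inflated truncated normal mixture
#'
#' The zero-ICC sites form their own cluster with sample-proportion mass
#' \eqn{p_0}; non-zero values follow a mixture of a normal truncated below
#' at 0 (component 1, low reliability) and a normal (component 2), with
#' full-data weights \eqn{p_1 = p(1-p_0)} and \eqn{p_2 = (1-p)(1-p_0)}:
#' \deqn{\ell = n_0 \log p_0 + \sum_i \log[p_1 f_{TN}(x_i) + p_2
#'   \phi((x_i-\mu_2)/\sigma_2)/\sigma_2]}
#' When \eqn{n_0 = 0} the zero term is omitted (0 log 0 = 0 convention).
#'
#' @param params a \linkS4class{MixtureFit} or parameter list (see
#'   \code{\link{censoredMixtureLoglik}}).
#' @param nonzeroIccs strictly positive ICC values.
#' @param n0 number of exact-zero ICCs; \eqn{p_0} is taken as
#'   \code{n0 / (n0 + length(nonzeroIccs))}.
#' @return total log likelihood on the full data.
#' @export
truncatedMixtureLoglik <- function(params, nonzeroIccs, n0 = 0L) {
    q <- paramList(params)
    if (any(nonzeroIccs <= 0)) stop("nonzeroIccs must be strictly positive")
    m <- length(nonzeroIccs)
    p0 <- n0 / (n0 + m)
    ll <- if (n0 > 0) n0 * log(p0) else 0
    if (m > 0) {
        l1 <- log(q$p) + log1p(-p0) + logdTN(nonzeroIccs, q$mu1, q$sigma1)
        l2 <- log1p(-q$p) + log1p(-p0) +
            stats::dnorm(nonzeroIccs, q$mu2, q$sigma2, log = TRUE)
        ll <- ll + sum(logSumExpPair(l1, l2))
    }
    ll
}

# shared EM scaffolding ------------------------------------------------

defaultInit <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    s <- max(diff(q) / 2, 0.02)
    list(p = 0.5, mu1 = q[1], sigma1 = s, mu2 = q[2], sigma2 = s)
}

jitterInit <- function(init) {
    list(p = min(max(init$p + stats::runif(1, -0.3, 0.3), 0.05), 0.95),
         mu1 = init$mu1 + stats::rnorm(1, 0, 0.1),
         sigma1 = max(init$sigma1 * stats::runif(1, 0.5, 2), .MIN_SIGMA),
         mu2 = init$mu2 + stats::rnorm(1, 0, 0.1),
         sigma2 = max(init$sigma2 * stats::runif(1, 0.5, 2), .MIN_SIGMA))
}

#' Fit the censored normal mixture by EM
#'
#' Two-component mixture of normals, both censored at 0, fit to the full
#' ICC sample (zeros included as censored observations). The E-step
#' computes component responsibilities; censored observations contribute
#' expected sufficient statistics of a normal truncated above 0
#' (inverse-Mills corrections) in the M-step. Component scales are floored
#' at 0.001 on the ICC scale. Initialization places the component means at
#' the 25th/75th percentiles with scale IQR/2 and p = 0.5; additional
#' jittered restarts are run and the best likelihood kept.
#'
#' @param iccs ICC values in [0, 1].
#' @param init optional list \code{p, mu1, sigma1, mu2, sigma2}.
#' @param tol relative log-likelihood convergence tolerance, default 1e-8.
#' @param maxIter maximum EM iterations, default 2000.
#' @param nRestarts jittered restarts beyond the default start, default 5.
#' @param seed seed for restart jitter, default 1.
#' @return a \linkS4class{MixtureFit} (model \code{"censored"}); the
#'   per-iteration log-likelihood trace of the winning run is kept in
#'   \code{@loglikTrace}.
#' @export
fitCensoredMixture <- function(iccs, init = NULL, tol = 1e-8,
                               maxIter = 2000L, nRestarts = 5L, seed = 1L) {
    if (length(iccs) < 100L)
        stop("need at least 100 ICC values to fit the mixture")
    stopIfNot01(iccs, "iccs")
    x <- iccs
    cens <- x == 0
    emOnce <- function(par) {
        trace <- numeric()
        for (it in seq_len(maxIter)) {
            l1 <- ifelse(cens, stats::pnorm(-par$mu1 / par$sigma1, log.p = TRUE),
                         stats::dnorm(x, par$mu1, par$sigma1, log = TRUE))
            l2 <- ifelse(cens, stats::pnorm(-par$mu2 / par$sigma2, log.p = TRUE),
                         stats::dnorm(x, par$mu2, par$sigma2, log = TRUE))
            a <- log(par$p) + l1
            b <- log1p(-par$p) + l2
            den <- logSumExpPair(a, b)
            trace <- c(trace, sum(den))
            r1 <- exp(a - den)
            # expected moments for censored entries, per component
            m1 <- censoredMoments(par$mu1, par$sigma1)
            m2 <- censoredMoments(par$mu2, par$sigma2)
            ey1 <- ifelse(cens, m1$ey, x); ey1sq <- ifelse(cens, m1$ey2, x^2)
            ey2 <- ifelse(cens, m2$ey, x); ey2sq <- ifelse(cens, m2$ey2, x^2)
            w1 <- sum(r1); w2 <- sum(1 - r1)
            mu1 <- sum(r1 * ey1) / w1
            mu2 <- sum((1 - r1) * ey2) / w2
            s1 <- sqrt(max(sum(r1 * (ey1sq - 2 * mu1 * ey1)) / w1 + mu1^2,
                           .MIN_SIGMA^2))
            s2 <- sqrt(max(sum((1 - r1) * (ey2sq - 2 * mu2 * ey2)) / w2 + mu2^2,
                           .MIN_SIGMA^2))
            new <- list(p = min(max(w1 / length(x), 1e-10), 1 - 1e-10),
                        mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2)
            if (it > 1L) {
                dll <- trace[it] - trace[it - 1L]
                if (abs(dll) < tol * (abs(trace[it]) + tol)) {
                    par <- new
                    return(list(par = par, trace = trace, converged = TRUE,
                                iter = it))
                }
            }
            par <- new
        }
        list(par = par, trace = trace, converged = FALSE, iter = maxIter)
    }
    starts <- list(init %||% defaultInit(x[!cens]))
    if (nRestarts > 0)
        starts <- c(starts, withSeed(seed, replicate(
            nRestarts, jitterInit(starts[[1L]]), simplify = FALSE)))
    best <- NULL
    for (s in starts) {
        run <- tryCatch(emOnce(s), error = function(e) NULL)
        if (is.null(run) || !is.finite(max(run$trace))) next
        if (is.null(best) || max(run$trace) > max(best$trace)) best <- run
    }
    if (is.null(best)) stop("censored mixture EM failed from every start")
    # low-reliability component stored first
    par <- best$par
    if (par$mu1 > par$mu2)
        par <- list(p = 1 - par$p, mu1 = par$mu2, sigma1 = par$sigma2,
                    mu2 = par$mu1, sigma2 = par$sigma1)
    ll <- censoredMixtureLoglik(par, x)
    new("MixtureFit", model = "censored", p = par$p, mu1 = par$mu1,
        sigma1 = par$sigma1, mu2 = par$mu2, sigma2 = par$sigma2, p0 = 0,
        loglik = ll, nObs = length(x), nZero = sum(cens),
        nIter = best$iter, converged = best$converged,
        loglikTrace = best$trace)
}

#' Fit the zero-inflated truncated normal mixture by EM
#'
#' The zero-ICC mass is estimated by the sample proportion \eqn{p_0}; EM
#' runs on the non-zero values with component 1 a normal truncated below
#' at 0 and component 2 a normal. The truncated component's M-step
#' maximizes its weighted truncated-normal likelihood numerically
#' (safeguarded: the update is only accepted if it improves the weighted
#' objective, preserving EM ascent). The reported log likelihood is on the
#' full data via \code{\link{truncatedMixtureLoglik}}.
#'
#' @inheritParams fitCensoredMixture
#' @return a \linkS4class{MixtureFit} (model \code{"truncated"}). With all
#'   values zero the fit is degenerate: \code{p0 = 1}, parameters NA,
#'   \code{converged = FALSE}.
#' @export
fitTruncatedMixture <- function(iccs, init = NULL, tol = 1e-8,
                                maxIter = 2000L, nRestarts = 5L, seed = 1L) {
    if (length(iccs) < 100L)
        stop("need at least 100 ICC values to fit the mixture")
    stopIfNot01(iccs, "iccs")
    n0 <- sum(iccs == 0)
    x <- iccs[iccs > 0]
    if (!length(x))
        return(new("MixtureFit", model = "truncated", p = NA_real_,
                   mu1 = NA_real_, sigma1 = NA_real_, mu2 = NA_real_,
                   sigma2 = NA_real_, p0 = 1, loglik = 0,
                   nObs = length(iccs), nZero = n0, nIter = 0L,
                   converged = FALSE, loglikTrace = numeric()))
    p0 <- n0 / length(iccs)
    # The weighted truncated-normal objective depends on the data only
    # through (sum r, sum r*x, sum r*x^2), so each evaluation is O(1).
    q1 <- function(theta, w, s1x, s2x) {
        mu <- theta[1]; sg <- exp(theta[2])
        w * (log(sg) + stats::pnorm(mu / sg, log.p = TRUE)) +
            (s2x - 2 * mu * s1x + mu^2 * w) / (2 * sg^2)
    }
    emOnce <- function(par) {
        trace <- numeric()
        for (it in seq_len(maxIter)) {
            a <- log(par$p) + logdTN(x, par$mu1, par$sigma1)
            b <- log1p(-par$p) + stats::dnorm(x, par$mu2, par$sigma2,
                                              log = TRUE)
            den <- logSumExpPair(a, b)
            trace <- c(trace, sum(den))
            r1 <- exp(a - den)
            w1 <- sum(r1); w2 <- length(x) - w1
            # component 2: closed-form weighted normal update
            mu2 <- sum((1 - r1) * x) / w2
            s2 <- sqrt(max(sum((1 - r1) * (x - mu2)^2) / w2, .MIN_SIGMA^2))
            # component 1: safeguarded numerical truncated-normal update
            s1x <- sum(r1 * x); s2x <- sum(r1 * x^2)
            th0 <- c(par$mu1, log(par$sigma1))
            opt <- tryCatch(stats::nlminb(th0, q1, w = w1, s1x = s1x,
                                          s2x = s2x,
                                          lower = c(-2, log(.MIN_SIGMA)),
                                          upper = c(2, log(2))),
                            error = function(e) NULL)
            if (!is.null(opt) && is.finite(opt$objective) &&
                opt$objective <= q1(th0, w1, s1x, s2x)) {
                mu1 <- opt$par[1]; s1 <- exp(opt$par[2])
            } else { mu1 <- par$mu1; s1 <- par$sigma1 }
            new <- list(p = min(max(w1 / length(x), 1e-10), 1 - 1e-10),
                        mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2)
            if (it > 1L) {
                dll <- trace[it] - trace[it - 1L]
                if (abs(dll) < tol * (abs(trace[it]) + tol))
                    return(list(par = new, trace = trace, converged = TRUE,
                                iter = it))
            }
            par <- new
        }
        list(par = par, trace = trace, converged = FALSE, iter = maxIter)
    }
    starts <- list(init %||% defaultInit(x))
    if (nRestarts > 0)
        starts <- c(starts, withSeed(seed, replicate(
            nRestarts, jitterInit(starts[[1L]]), simplify = FALSE)))
    best <- NULL
    for (s in starts) {
        run <- tryCatch(emOnce(s), error = function(e) NULL)
        if (is.null(run) || !is.finite(max(run$trace))) next
        if (is.null(best) || max(run$trace) > max(best$trace)) best <- run
    }
    if (is.null(best)) stop("truncated mixture EM failed from every start")
    par <- best$par
    if (par$mu1 > par$mu2)
        par <- list(p = 1 - par$p, mu1 = par$mu2, sigma1 = par$sigma2,
                    mu2 = par$mu1, sigma2 = par$sigma1)
    ll <- truncatedMixtureLoglik(par, x, n0)
    new("MixtureFit", model = "truncated", p = par$p, mu1 = par$mu1,
        sigma1 = par$sigma1, mu2 = par$mu2, sigma2 = par$sigma2, p0 = p0,
        loglik = ll, nObs = length(iccs), nZero = n0,
        nIter = best$iter, converged = best$converged,
        loglikTrace = best$trace)
}

#' Maximized log likelihood of a mixture fit
#'
#' @param object a \linkS4class{MixtureFit}.
#' @param ... ignored.
#' @return the maximized log likelihood on the full data.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "MixtureFit", function(object, ...) object@loglik)

#' Posterior probability of high-reliability membership
#'
#' \eqn{\pi(x) = p_2 g_2(x) / (p_1 g_1(x) + p_2 g_2(x))} with the fitted
#' component densities: for the truncated model \eqn{g_1} is the truncated
#' normal and \eqn{g_2} the normal (the \eqn{1-p_0} factors cancel); for
#' the censored model both are censored normals, so a posterior is also
#' defined at \eqn{x = 0} through the censored masses.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param icc ICC value(s); must be strictly positive for the truncated
#'   model (the zero-ICC cluster is handled separately).
#' @return posterior probabilities in [0, 1].
#' @examples
#' fit <- mixtureFit("truncated", p = 0.67, mu1 = 0.04, sigma1 = 0.28,
#'                   mu2 = 0.72, sigma2 = 0.11, p0 = 36017 / 473788)
#' posteriorHigh(fit, c(0.1, 0.37, 0.9))
#' @export
posteriorHigh <- function(fit, icc) {
    q <- paramList(fit)
    if (fit@model == "truncated") {
        if (any(icc <= 0))
            stop("posterior is undefined at ICC = 0 under the truncated model; the zero cluster is classified separately")
        l1 <- logdTN(icc, q$mu1, q$sigma1)
        l2 <- stats::dnorm(icc, q$mu2, q$sigma2, log = TRUE)
    } else {
        cens <- icc == 0
        l1 <- ifelse(cens, stats::pnorm(-q$mu1 / q$sigma1, log.p = TRUE),
                     stats::dnorm(icc, q$mu1, q$sigma1, log = TRUE))
        l2 <- ifelse(cens, stats::pnorm(-q$mu2 / q$sigma2, log.p = TRUE),
                     stats::dnorm(icc, q$mu2, q$sigma2, log = TRUE))
    }
    if (q$p == 0) return(rep(1, length(icc)))
    if (q$p == 1) return(rep(0, length(icc)))
    a <- log(q$p) + l1
    b <- log1p(-q$p) + l2
    exp(b - logSumExpPair(a, b))
}

#' ICC value at which the posterior equals a cutoff
#'
#' Solves \eqn{\pi(x) = } \code{piCutoff} on (0, 1) by bracketed root
#' finding (absolute tolerance 1e-6), after verifying that the posterior
#' crosses the cutoff exactly once.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param piCutoff posterior cutoff, e.g. 0.01.
#' @return the ICC threshold.
#' @examples
#' fit <- mixtureFit("truncated", p = 0.67, mu1 = 0.04, sigma1 = 0.28,
#'                   mu2 = 0.72, sigma2 = 0.11, p0 = 36017 / 473788)
#' iccThresholdForPosterior(fit, 0.01)  # ~0.37
#' @export
iccThresholdForPosterior <- function(fit, piCutoff) {
    stopifnot(piCutoff > 0, piCutoff < 1)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 2001L)
    f <- posteriorHigh(fit, grid) - piCutoff
    sgn <- sign(f)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(cross) != 1L)
        stop(sprintf(
            "posterior crosses the cutoff %d times on (0,1); degenerate fit (p=%.3f, mu1=%.3f, sigma1=%.3f, mu2=%.3f, sigma2=%.3f)",
            length(cross), fit@p, fit@mu1, fit@sigma1, fit@mu2, fit@sigma2))
    stats::uniroot(function(x) posteriorHigh(fit, x) - piCutoff,
                   c(grid[cross], grid[cross + 1L]), tol = 1e-8)$root
}

#' Classify probes into zero / low / high reliability clusters
#'
#' Sites with ICC exactly 0 form the zero-ICC cluster; sites with non-zero
#' ICC are assigned to the high-reliability cluster when their posterior
#' probability of component-2 membership is at least \code{piCutoff}
#' (boundary assigned to high, maximizing the high-reliability cluster),
#' and to the low-reliability cluster otherwise.
#'
#' @param iccTab ICC table from \code{\link{iccTable}}, or a numeric vector
#'   of ICCs.
#' @param fit a converged \linkS4class{MixtureFit}.
#' @param piCutoff posterior cutoff, default 0.01.
#' @return \link[S4Vectors]{DataFrame} with \code{probe_id}, \code{icc},
#'   \code{posterior} (NA in the zero cluster under the truncated model)
#'   and \code{cluster} (factor zero/low/high); the cutoff is kept in
#'   \code{metadata()}.
#' @export
classifySites <- function(iccTab, fit, piCutoff = 0.01) {
    if (is.numeric(iccTab))
        iccTab <- DataFrame(probe_id = as.character(seq_along(iccTab)),
                            icc = iccTab)
    icc <- iccTab$icc
    post <- rep(NA_real_, length(icc))
    pos <- !is.na(icc) & icc > 0
    post[pos] <- posteriorHigh(fit, icc[pos])
    if (fit@model == "censored" && any(!is.na(icc) & icc == 0))
        post[!is.na(icc) & icc == 0] <- posteriorHigh(fit, 0)
    cluster <- rep(NA_character_, length(icc))
    cluster[!is.na(icc) & icc == 0] <- "zero"
    cluster[pos] <- ifelse(post[pos] >= piCutoff, "high", "low")
    out <- DataFrame(probe_id = iccTab$probe_id, icc = icc,
                     posterior = post,
                     cluster = factor(cluster, c("zero", "low", "high")),
                     row.names = rownames(iccTab))
    S4Vectors::metadata(out) <- list(piCutoff = piCutoff, model = fit@model)
    out
}

#' Compare censored and truncated mixture fits
#'
#' Both maximized log likelihoods must refer to the same full data set
#' (zeros included); the fit with the larger value wins, with a
#' deterministic tie-break to the truncated model.
#'
#' @param fitCensored,fitTruncated \linkS4class{MixtureFit} objects fitted
#'   to the same ICC sample.
#' @return list with \code{chosen} (the winning fit), \code{model} and
#'   \code{loglikDiff} (truncated minus censored).
#' @export
compareModels <- function(fitCensored, fitTruncated) {
    stopifnot(fitCensored@model == "censored",
              fitTruncated@model == "truncated")
    if (fitCensored@nObs != fitTruncated@nObs)
        stop(sprintf("fits were computed on different data sizes (%d vs %d)",
                     fitCensored@nObs, fitTruncated@nObs))
    d <- fitTruncated@loglik - fitCensored@loglik
    chosen <- if (d >= 0) fitTruncated else fitCensored
    list(chosen = chosen, model = chosen@model, loglikDiff = d)
}

#' Serialize a mixture fit as JSON
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMixtureFit <- function(fit, path) {
    jsonlite::write_json(list(
        model = fit@model, p = fit@p, mu1 = fit@mu1, sigma1 = fit@sigma1,
        mu2 = fit@mu2, sigma2 = fit@sigma2, p0 = fit@p0,
        loglik = fit@loglik, n_obs = fit@nObs, n_zero = fit@nZero,
        n_iter = fit@nIter, converged = fit@converged),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
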