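#' Default per-probe variance-component law
#'
#' Draws the technical variance components and a target reliability for each
#' probe. Chip-to-chip standard deviations are uniform on [0.005, 0.02] and
#' residual technical standard deviations uniform on [0.01, 0.03] — the
#' scale of replicate noise seen on Infinium arrays after normalization.
#' Target ICCs follow a bimodal law (55\% from N(0.10, 0.05^2), 45\% from
#' N(0.75, 0.08^2), clamped to [0.005, 0.97]) so the estimated genome-wide
#' ICC distribution shows the characteristic low mode near 0.1 and high
#' mode near 0.75. The between-subject variance is derived downstream as
#' sigma2_b = icc/(1-icc) * (sigma2_chip + sigma2_e).
#'
#' @param n number of probes.
#' @return data.frame with columns \code{sigma2_chip}, \code{sigma2_e},
#'   \code{icc}.
#' @export
defaultVarianceLaw <- function(n) {
    lowMode <- runif(n) < 0.55
    icc <- ifelse(lowMode, rnorm(n, 0.10, 0.05), rnorm(n, 0.75, 0.08))
    icc <- pmin(pmax(icc, 0.005), 0.97)
    data.frame(sigma2_chip = runif(n, 0.005, 0.02)^2,
               sigma2_e = runif(n, 0.01, 0.03)^2,
               icc = icc)
}

# Assign samples to chips so that members of a replicate set land on
# distinct chips, except `sameChipPairs` duplicate sets forced onto one
# chip. Random placement followed by a swap-repair pass.
assignChips <- function(subjectOfSample, samplesPerChip, sameChipPairs) {
    n <- length(subjectOfSample)
    nChips <- ceiling(n / samplesPerChip)
    slot <- sample.int(n)                      # sample -> slot on the plates
    chipOf <- function(slots) (slots - 1L) %/% samplesPerChip + 1L
    chip <- chipOf(slot)

    setsOf <- split(seq_len(n), subjectOfSample)
    setsOf <- setsOf[lengths(setsOf) >= 2L]
    pairSets <- names(setsOf)[lengths(setsOf) == 2L]
    forced <- head(pairSets, sameChipPairs)
    forcedMembers <- unlist(setsOf[forced], use.names = FALSE)
    doSwap <- function(a, b) {
        tmp <- slot[a]; slot[a] <<- slot[b]; slot[b] <<- tmp
        chip <<- chipOf(slot)
    }
    # chips occupied by the rest of sample k's replicate set
    otherChips <- function(k) {
        mem <- setsOf[[subjectOfSample[k]]]
        if (is.null(mem)) integer() else chip[setdiff(mem, k)]
    }

    if (nChips >= 2L) {
        for (s in forced) {                    # co-locate designated pairs
            mem <- setsOf[[s]]
            if (chip[mem[1L]] == chip[mem[2L]]) next
            cand <- setdiff(which(chip == chip[mem[1L]]), forcedMembers)
            if (length(cand)) doSwap(mem[2L], cand[1L])
        }
        for (iter in seq_len(20L)) {           # separate the others
            fixedAny <- FALSE
            for (s in setdiff(names(setsOf), forced)) {
                mem <- setsOf[[s]]
                for (m in mem[duplicated(chip[mem])]) {
                    ok <- which(!(chip %in% chip[mem]))
                    ok <- setdiff(ok, forcedMembers)
                    ok <- ok[vapply(ok, function(k)
                        !chip[m] %in% otherChips(k), logical(1))]
                    if (!length(ok)) next
                    doSwap(m, if (length(ok) == 1L) ok else sample(ok, 1L))
                    fixedAny <- TRUE
                }
            }
            conflict <- any(vapply(setdiff(names(setsOf), forced),
                                   function(s) anyDuplicated(chip[setsOf[[s]]]) > 0L,
                                   logical(1)))
            if (!conflict || !fixedAny) break
        }
    }
    list(slot = slot, chip = chip,
         posInChip = (slot - 1L) %% samplesPerChip + 1L)
}

#' Simulate a complete synthetic methylation study
#'
#' Runs the measurement model forward: for probe g and sample i of subject
#' j on chip l,
#' \deqn{y_{ij} = clamp(\mu_g + \tau_j + b_l + \beta_g x_j + e_{ij},\ 0,\ 1)}
#' with \eqn{\tau_j \sim N(0, \sigma^2_b)} shared by all replicates of a
#' subject, \eqn{b_l \sim N(0, \sigma^2_{chip})} shared by all samples on a
#' chip, independent residual noise \eqn{e_{ij}}, and a phenotype effect
#' \eqn{\beta_g} on designated probes. Replicates of a set are placed on
#' distinct chips (except a configurable number of same-chip pairs). Probe
#' means are drawn from a trimodal Beta mixture (modes near 0.05, 0.5,
#' 0.95) and per-probe standard deviations are damped by \eqn{4\mu(1-\mu)}
#' so boundary clamping stays rare. A stated fraction of probes has
#' \eqn{\sigma^2_b = 0} exactly (the zero-ICC mass). Detection p-values are
#' drawn so each entry independently exceeds 0.01 with probability
#' \code{detectionFailRate}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{study}
#'   (\linkS4class{MethylationExperiment} with beta and detectionP assays,
#'   sample sheet in colData, annotation in rowData) and \code{truth}
#'   (\link[S4Vectors]{DataFrame} of per-probe true variance components,
#'   true ICC and phenotype effect).
#' @examples
#' sim <- simulateMethylationStudy(simulationConfig(
#'     nSubjects = 40, nReplicatePairs = 15, nReplicateTriples = 2,
#'     nProbes = 50, effectProbes = 2, seed = 7))
#' sim$study
#' @export
simulateMethylationStudy <- function(config) {
    validObject(config)
    withSeed(config@seed, {
        nS <- config@nSubjects
        nP <- config@nProbes
        # replicate structure: which subjects are measured 2x / 3x
        repSubj <- sample.int(nS, config@nReplicatePairs + config@nReplicateTriples)
        nCopies <- rep(1L, nS)
        nCopies[repSubj] <- c(rep(2L, config@nReplicatePairs),
                              rep(3L, config@nReplicateTriples))
        subjIdx <- rep(seq_len(nS), nCopies)
        repIdx <- sequence(nCopies)
        nSamples <- length(subjIdx)
        subjectIds <- sprintf("subj%04d", seq_len(nS))
        sampleIds <- sprintf("%s_r%d", subjectIds[subjIdx], repIdx)

        layout <- assignChips(subjectIds[subjIdx], config@samplesPerChip,
                              config@sameChipPairs)
        chipRow <- (layout$posInChip - 1L) %% config@chipRows + 1L
        chipCol <- (layout$posInChip - 1L) %/% config@chipRows + 1L

        # subject phenotype and covariates (cohort-style defaults)
        smoker <- rbinom(nS, 1L, config@phenotypePrevalence)
        covs <- data.frame(
            age = rnorm(nS, 56.7, 5.9),
            sex = rbinom(nS, 1L, 0.634),            # 1 = female
            bmi = rnorm(nS, 30, 6),
            alcohol = rbinom(nS, 1L, 0.3),          # 1 = current drinker
            pc1 = rnorm(nS), pc2 = rnorm(nS),
            visit = sample(c(2L, 3L), nS, replace = TRUE, prob = c(0.85, 0.15)),
            center = sample(c("J", "F"), nS, replace = TRUE, prob = c(0.8, 0.2)))

        # per-probe means and variance components
        shape <- sample.int(3L, nP, replace = TRUE, prob = c(0.35, 0.30, 0.35))
        mu <- numeric(nP)
        mu[shape == 1L] <- rbeta(sum(shape == 1L), 2.5, 30)
        mu[shape == 2L] <- rbeta(sum(shape == 2L), 10, 10)
        mu[shape == 3L] <- rbeta(sum(shape == 3L), 30, 2.5)

        law <- config@varianceLaw(nP)
        damp2 <- (4 * mu * (1 - mu))^2           # variance damping near 0/1
        sigma2_chip <- law$sigma2_chip * damp2
        sigma2_e <- law$sigma2_e * damp2
        sigma2_b <- law$icc / (1 - law$icc) * (sigma2_chip + sigma2_e)
        nZero <- round(config@fractionZeroIcc * nP)
        zeroProbes <- sample.int(nP, nZero)
        sigma2_b[zeroProbes] <- 0
        trueIcc <- sigma2_b / (sigma2_b + sigma2_chip + sigma2_e)

        # phenotype effects
        effect <- numeric(nP)
        if (config@effectProbes > 0L) {
            pool <- if (config@effectPlacement == "high")
                which(trueIcc >= 0.5) else seq_len(nP)
            if (length(pool) < config@effectProbes)
                pool <- order(trueIcc, decreasing = TRUE)[seq_len(config@effectProbes)]
            effect[sample(pool, config@effectProbes)] <- config@effectSize
        }

        nChips <- max(layout$chip)
        tau <- matrix(rnorm(nP * nS, 0, sqrt(sigma2_b)), nP, nS)
        bChip <- matrix(rnorm(nP * nChips, 0, sqrt(sigma2_chip)), nP, nChips)
        e <- matrix(rnorm(nP * nSamples, 0, sqrt(sigma2_e)), nP, nSamples)

        y <- mu + tau[, subjIdx, drop = FALSE] +
            bChip[, layout$chip, drop = FALSE] + e +
            outer(effect, smoker[subjIdx])
        y <- pmin(pmax(y, 0), 1)
        probeIds <- sprintf("cg%07d", seq_len(nP))
        dimnames(y) <- list(probeIds, sampleIds)

        fail <- matrix(runif(nP * nSamples) < config@detectionFailRate,
                       nP, nSamples)
        detp <- matrix(runif(nP * nSamples, 0, 0.01), nP, nSamples)
        detp[fail] <- runif(sum(fail), 0.01, 1)
        dimnames(detp) <- dimnames(y)

        sheet <- data.frame(
            sample_id = sampleIds,
            subject_id = subjectIds[subjIdx],
            chip_id = sprintf("chip%03d", layout$chip),
            chip_row = chipRow, chip_col = chipCol,
            smoking = smoker[subjIdx],
            covs[subjIdx, , drop = FALSE],
            row.names = NULL)

        annot <- data.frame(
            probe_id = probeIds,
            design_type = sample(c("I", "II"), nP, replace = TRUE,
                                 prob = c(0.28, 0.72)),
            island_relation = sample(c("island", "shore", "shelf", "open_sea"),
                                     nP, replace = TRUE,
                                     prob = c(0.31, 0.23, 0.10, 0.36)),
            snp_within_50bp = runif(nP) < 0.06,
            cross_reactive = runif(nP) < 0.06)

        truth <- DataFrame(
            probe_id = probeIds, mu = mu, sigma2_b = sigma2_b,
            sigma2_chip = sigma2_chip, sigma2_e = sigma2_e,
            icc = trueIcc, effect = effect, row.names = probeIds)

        list(study = MethylationExperiment(y, sheet, annot, detp),
             truth = truth)
    })
}

#' Draw ICC values directly from the reliability mixture
#'
#' Direct sampler for the zero-inflated two-component model: exactly
#' \code{round(n * p0)} values are exact zeros; the remainder come from the
#' low-reliability component (a normal truncated below at 0, with
#' probability \code{p}) or the high-reliability normal clipped to (0, 1].
#'
#' @param p0 proportion of exact zeros.
#' @param p component-1 (low-reliability) mixing proportion among non-zero
#'   values.
#' @param mu1,sigma1 component-1 location and scale.
#' @param mu2,sigma2 component-2 location and scale.
#' @param n sample size.
#' @param seed RNG seed.
#' @return numeric vector of length \code{n}, values in [0, 1].
#' @examples
#' x <- simulateICCSample(0.076, 0.67, 0.04, 0.28, 0.72, 0.11,
#'                        n = 1000, seed = 1)
#' mean(x == 0)
#' @export
simulateICCSample <- function(p0, p, mu1, sigma1, mu2, sigma2, n,
                              seed = 1L) {
    stopIfNot01(p0, "p0"); stopIfNot01(p, "p")
    if (sigma1 <= 0 || sigma2 <= 0) stop("sigma1 and sigma2 must be > 0")
    if (n < 0) stop("n must be >= 0")
    withSeed(seed, {
        nZero <- round(n * p0)
        m <- n - nZero
        fromLow <- runif(m) < p
        x <- numeric(m)
        n1 <- sum(fromLow)
        if (n1) {
            # inverse-CDF draw from N(mu1, sigma1) truncated below at 0
            lo <- pnorm(-mu1 / sigma1)
            u <- runif(n1, lo, 1)
            x[fromLow] <- mu1 + sigma1 * qnorm(u)
        }
        n2 <- m - n1
        if (n2) x[!fromLow] <- rnorm(n2, mu2, sigma2)
        x <- pmin(pmax(x, .Machine$double.eps), 1)
        sample(c(numeric(nZero), x))
    })
}
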