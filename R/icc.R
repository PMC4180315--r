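# Vectorized one-way random-effects method-of-moments ANOVA.
# beta: probes x samples matrix; g: grouping factor of length ncol(beta).
# Sets reduced below size 2 by missingness are dropped per probe; probes
# with fewer than 2 usable sets are returned as NA (unestimable).
momAnovaMatrix <- function(beta, g) {
    g <- droplevels(as.factor(g))
    M <- !is.na(beta)
    b0 <- beta; b0[!M] <- 0
    Cnt <- t(rowsum(t(M) + 0, g))              # probes x J set sizes
    S <- t(rowsum(t(b0), g))                   # set sums
    S2 <- t(rowsum(t(b0^2), g))                # set sums of squares
    U <- Cnt >= 2                              # usable sets
    N <- rowSums(Cnt * U)
    J <- rowSums(U)
    CntSafe <- pmax(Cnt, 1)
    SSW <- rowSums((S2 - S^2 / CntSafe) * U)
    grand <- rowSums(S * U) / N
    SSB <- rowSums(S^2 / CntSafe * U) - N * grand^2
    MSW <- SSW / (N - J)
    MSB <- SSB / (J - 1)
    k0 <- (N - rowSums(Cnt^2 * U) / N) / (J - 1)
    raw <- (MSB - MSW) / k0
    est <- J >= 2
    raw[!est] <- NA_real_
    MSW[!est] <- NA_real_
    grand[!est] <- NA_real_
    trunc <- pmax(raw, 0)
    tot <- trunc + MSW
    icc <- ifelse(!est, NA_real_, ifelse(tot > 0, trunc / tot, 0))
    list(grandMean = grand, sigma2Within = MSW, sigma2BetweenRaw = raw,
         sigma2Between = trunc, icc = icc, nSets = J, k0 = k0,
         estimable = est)
}

#' One-way random-effects variance components for a single probe
#'
#' Method-of-moments estimator for the model
#' \eqn{y_{ij} = \mu + \tau_j + \epsilon_{ij}} with replicate sets j:
#' the within-set mean square estimates \eqn{\sigma^2_\epsilon}, and
#' \eqn{\hat\sigma^2_\tau = (MSB - MSW)/k_0} with
#' \eqn{k_0 = (N - \sum n_j^2/N)/(J - 1)} for unbalanced sets. A negative
#' between-set estimate is truncated to 0 (the raw value is retained for
#' diagnostics).
#'
#' @param values numeric vector of measurements (e.g. one probe's beta
#'   values over replicate samples).
#' @param sets replicate-set identifier, same length as \code{values}.
#' @return list with \code{grandMean}, \code{sigma2Within},
#'   \code{sigma2BetweenRaw}, \code{sigma2Between}, \code{nSets},
#'   \code{k0} and \code{estimable}. With fewer than 2 usable sets (size
#'   >= 2 after dropping NAs) the estimate is flagged unestimable, never
#'   silently 0.
#' @examples
#' anovaComponents(c(0.2, 0.3, 0.6, 0.7), c("a", "a", "b", "b"))
#' @export
anovaComponents <- function(values, sets) {
    stopifnot(length(values) == length(sets))
    r <- momAnovaMatrix(matrix(values, nrow = 1), sets)
    lapply(r[c("grandMean", "sigma2Within", "sigma2BetweenRaw",
               "sigma2Between", "nSets", "k0", "estimable")], `[`, 1L)
}

#' Intraclass correlation from variance components
#'
#' \eqn{ICC = \sigma^2_\tau / (\sigma^2_\tau + \sigma^2_\epsilon)}, with
#' the truncated between-set component; 0/0 (both components zero) is
#' defined as 0. An ICC of 1 indicates perfect measurement reproducibility;
#' 0 means replicate noise swamps between-subject variation.
#'
#' @param vc a list as returned by \code{\link{anovaComponents}}.
#' @return ICC in [0, 1], or NA if unestimable.
#' @export
iccFromComponents <- function(vc) {
    if (!isTRUE(vc$estimable)) return(NA_real_)
    tot <- vc$sigma2Between + vc$sigma2Within
    if (tot <= 0) 0 else vc$sigma2Between / tot
}

replicateMask <- function(study) {
    subj <- SummarizedExperiment::colData(study)$subject_id
    tab <- table(subj)
    subj %in% names(tab)[tab >= 2L]
}

#' Per-probe ICC table from a replicated methylation study
#'
#' For every probe, estimates the between/within replicate-set variance
#' components and the ICC over the replicated samples; the per-probe SD of
#' beta is computed over distinct subjects (first sample per subject, all
#' subjects) to avoid double-counting replicates; the chip-effect ICC
#' (\code{icc_chip}: the proportion of variance attributable to chip
#' differences, computed over replicate samples grouped by chip) is
#' attached when at least two chips are observed.
#'
#' @param study a \linkS4class{MethylationExperiment} whose colData has
#'   \code{subject_id} and (for icc_chip) \code{chip_id}.
#' @return \link[S4Vectors]{DataFrame} with columns \code{probe_id},
#'   \code{icc}, \code{sigma2_between_raw}, \code{sigma2_between},
#'   \code{sigma2_within}, \code{sd}, \code{icc_chip}, \code{n_sets}.
#' @export
iccTable <- function(study) {
    stopifnot(is(study, "SummarizedExperiment"))
    cd <- SummarizedExperiment::colData(study)
    beta <- SummarizedExperiment::assay(study, "beta")
    rep <- replicateMask(study)
    if (!any(rep)) stop("no replicate sets (subjects with >= 2 samples) in the sample sheet")
    a <- momAnovaMatrix(beta[, rep, drop = FALSE], cd$subject_id[rep])
    firstOfSubject <- !duplicated(cd$subject_id)
    sdSubj <- apply(beta[, firstOfSubject, drop = FALSE], 1L, stats::sd,
                    na.rm = TRUE)
    chipIcc <- rep(NA_real_, nrow(beta))
    if ("chip_id" %in% colnames(cd) &&
        length(unique(cd$chip_id[rep])) >= 2L)
        chipIcc <- momAnovaMatrix(beta[, rep, drop = FALSE],
                                  cd$chip_id[rep])$icc
    DataFrame(probe_id = rownames(beta) %||% as.character(seq_len(nrow(beta))),
              icc = unname(a$icc),
              sigma2_between_raw = unname(a$sigma2BetweenRaw),
              sigma2_between = unname(a$sigma2Between),
              sigma2_within = unname(a$sigma2Within),
              sd = unname(sdSubj),
              icc_chip = unname(chipIcc),
              n_sets = unname(a$nSets),
              row.names = rownames(beta))
}

#' Chip-effect ICC per probe
#'
#' One-way random-effects ANOVA with chip as the grouping factor: the
#' fraction of measurement variance attributable to chip (batch)
#' differences. Values near 1 flag probes whose measurements are dominated
#' by batch effects (and whose replicate ICC is correspondingly low).
#'
#' @param study a \linkS4class{MethylationExperiment}; colData needs
#'   \code{chip_id}.
#' @param samples \code{"replicates"} (default; same data as the replicate
#'   ICC, for comparability) or \code{"all"}.
#' @return named numeric vector of per-probe chip ICCs (NA when fewer than
#'   two chips are observed).
#' @export
iccChip <- function(study, samples = c("replicates", "all")) {
    samples <- match.arg(samples)
    cd <- SummarizedExperiment::colData(study)
    if (!"chip_id" %in% colnames(cd)) stop("colData lacks 'chip_id'")
    keep <- if (samples == "replicates") replicateMask(study)
            else rep(TRUE, ncol(study))
    if (length(unique(cd$chip_id[keep])) < 2L)
        stop("chip-effect ICC is unestimable with a single chip")
    beta <- SummarizedExperiment::assay(study, "beta")
    out <- momAnovaMatrix(beta[, keep, drop = FALSE], cd$chip_id[keep])$icc
    names(out) <- rownames(beta)
    out
}

#' LOWESS trend of ICC against methylation SD
#'
#' Locally weighted linear smoother of per-probe ICC on per-probe SD,
#' summarizing how reliability improves with inter-individual variation.
#'
#' @param table an ICC table from \code{\link{iccTable}} (needs \code{icc}
#'   and \code{sd} columns).
#' @param bandwidth smoother span (fraction of points), default 2/3.
#' @return data.frame with the SD evaluation grid and fitted ICC.
#' @export
iccSdTrend <- function(table, bandwidth = 2/3) {
    tab <- as.data.frame(table)
    ok <- is.finite(tab$icc) & is.finite(tab$sd)
    if (sum(ok) < 50L) stop("need at least 50 probes with finite ICC and SD")
    x <- tab$sd[ok]; y <- tab$icc[ok]
    if (diff(range(x)) == 0) {
        warning("all probe SDs are equal; returning a flat trend")
        return(data.frame(sd = unique(x), icc = mean(y)))
    }
    fit <- stats::lowess(x, y, f = bandwidth)
    data.frame(sd = fit$x, icc = fit$y)
}

#' Write an ICC table as TSV
#'
#' @param table ICC table from \code{\link{iccTable}}.
#' @param path output file (.tsv, optionally .gz).
#' @return invisibly, \code{path}.
#' @export
writeICCTable <- function(table, path) {
    data.table::fwrite(as.data.frame(table), path, sep = "\t")
    invisible(path)
}
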