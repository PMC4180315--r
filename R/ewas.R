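#' Per-probe association of methylation with a binary phenotype
#'
#' Fits one probe's beta values against the phenotype and covariates.
#' \code{mode = "lmm"} adds a chip-level random intercept (batch effects as
#' random effects, via \pkg{lme4}) and reports a Wald p-value for the
#' phenotype coefficient from the normal approximation;
#' \code{mode = "ols"} fits ordinary least squares with no chip terms. A
#' non-convergent mixed fit falls back to OLS for that probe, flagged in
#' \code{note}.
#'
#' @param betaRow numeric vector, one probe's beta values.
#' @param phenotype binary (0/1) phenotype vector.
#' @param covariates data.frame of fixed covariates (may be NULL).
#' @param chipIds chip identifier per sample (required for lmm).
#' @param mode "lmm" or "ols".
#' @return list with \code{estimate} (mean beta difference), \code{se},
#'   \code{pvalue}, \code{mode}, \code{note}; or NULL-entries with a
#'   \code{note} when the probe is skipped (zero variance or singular
#'   design).
#' @export
fitProbeAssociation <- function(betaRow, phenotype, covariates = NULL,
                                chipIds = NULL, mode = c("lmm", "ols")) {
    mode <- match.arg(mode)
    if (length(betaRow) < 30L)
        stop("need at least 30 samples for a per-probe association fit")
    skip <- function(note) list(estimate = NA_real_, se = NA_real_,
                                pvalue = NA_real_, mode = mode, note = note)
    if (stats::sd(betaRow, na.rm = TRUE) == 0) return(skip("zero variance"))
    df <- data.frame(y = betaRow, pheno = phenotype)
    if (!is.null(covariates) && ncol(as.data.frame(covariates)))
        df <- cbind(df, as.data.frame(covariates))
    covTerms <- setdiff(colnames(df), c("y", "pheno"))
    # drop covariates that are constant or collinear with others
    covTerms <- covTerms[vapply(covTerms, function(v)
        length(unique(df[[v]])) > 1L, logical(1))]
    form <- stats::reformulate(c("pheno", covTerms), response = "y")
    wald <- function(est, se) {
        z <- est / se
        list(estimate = est, se = se, pvalue = 2 * stats::pnorm(-abs(z)))
    }
    fitOls <- function(note = "") {
        m <- stats::lm(form, data = df)
        cf <- summary(m)$coefficients
        if (!"pheno" %in% rownames(cf)) return(skip("singular design"))
        c(wald(cf["pheno", 1L], cf["pheno", 2L]),
          list(mode = "ols", note = note))
    }
    if (mode == "ols") return(fitOls())
    if (is.null(chipIds)) stop("lmm mode requires chip identifiers")
    df$.chip <- factor(chipIds)
    formL <- stats::update.formula(form, . ~ . + (1 | .chip))
    m <- tryCatch(
        suppressMessages(suppressWarnings(
            lme4::lmer(formL, data = df, REML = TRUE,
                       control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
    if (is.null(m)) return(fitOls(note = "lmm failed; ols fallback"))
    cf <- tryCatch(summary(m)$coefficients, error = function(e) NULL)
    if (is.null(cf) || !"pheno" %in% rownames(cf))
        return(fitOls(note = "lmm failed; ols fallback"))
    c(wald(cf["pheno", 1L], cf["pheno", 2L]), list(mode = "lmm", note = ""))
}

#' Epigenome-wide association scan
#'
#' Per-probe regression of methylation on a binary phenotype with fixed
#' covariates, chip modeled as a random intercept (\code{mode = "lmm"}) or
#' ignored (\code{mode = "ols"}). Replicates are collapsed to the first
#' sample per subject before fitting. Probes carrying the SNP-within-50bp
#' flag can be excluded from the significant-hit summary.
#'
#' @param study a QC-filtered \linkS4class{MethylationExperiment}; colData
#'   must carry the phenotype, covariates and \code{chip_id}.
#' @param phenotype name of the binary phenotype column, default
#'   \code{"smoking"}.
#' @param covariates character vector of covariate column names present in
#'   colData (missing ones are dropped with a message).
#' @param mode "lmm" (chip random effect) or "ols".
#' @param alpha genome-wide significance threshold, default 1e-7
#'   (Bonferroni scale).
#' @param applySnpMask exclude SNP-flagged probes from the significant
#'   flag, default TRUE.
#' @return \link[S4Vectors]{DataFrame} with per-probe \code{estimate},
#'   \code{se}, \code{pvalue}, \code{significant} (p < alpha and not
#'   SNP-masked), \code{snp_masked}, \code{mode}, \code{note}.
#' @export
runEwas <- function(study, phenotype = "smoking",
                    covariates = c("age", "sex", "bmi", "alcohol", "pc1",
                                   "pc2", "visit", "center", "chip_row"),
                    mode = c("lmm", "ols"), alpha = 1e-7,
                    applySnpMask = TRUE) {
    mode <- match.arg(mode)
    stopifnot(alpha > 0, alpha < 1)
    cd <- SummarizedExperiment::colData(study)
    if (!phenotype %in% colnames(cd))
        stop("phenotype column '", phenotype, "' not found in colData")
    keep <- !duplicated(cd$subject_id)
    study1 <- study[, keep]
    cd <- SummarizedExperiment::colData(study1)
    ph <- cd[[phenotype]]
    if (mean(is.na(ph)) > 0.1)
        stop("phenotype missing for more than 10% of samples")
    if (length(unique(stats::na.omit(ph))) != 2L)
        stop("phenotype must be binary")
    miss <- setdiff(covariates, colnames(cd))
    if (length(miss))
        stageLog("ewas", "covariates absent from colData, dropped: %s",
                 paste(miss, collapse = ", "))
    covariates <- intersect(covariates, colnames(cd))
    covs <- as.data.frame(cd[, covariates, drop = FALSE])
    beta <- SummarizedExperiment::assay(study1, "beta")
    chips <- if ("chip_id" %in% colnames(cd)) cd$chip_id else NULL
    res <- vector("list", nrow(beta))
    for (g in seq_len(nrow(beta)))
        res[[g]] <- fitProbeAssociation(beta[g, ], ph, covs, chips, mode)
    masked <- if (applySnpMask &&
                  "snp_within_50bp" %in%
                  colnames(SummarizedExperiment::rowData(study1)))
        rownames(study1) %in% snpProbeMask(study1)
    else rep(FALSE, nrow(study1))
    pv <- vapply(res, `[[`, numeric(1), "pvalue")
    out <- DataFrame(
        probe_id = rownames(beta),
        estimate = vapply(res, `[[`, numeric(1), "estimate"),
        se = vapply(res, `[[`, numeric(1), "se"),
        pvalue = pv,
        significant = !is.na(pv) & pv < alpha & !masked,
        snp_masked = masked,
        mode = vapply(res, `[[`, character(1), "mode"),
        note = vapply(res, `[[`, character(1), "note"),
        row.names = rownames(beta))
    S4Vectors::metadata(out) <- list(alpha = alpha, mode = mode,
                                     phenotype = phenotype,
                                     nSamples = ncol(study1))
    nSkip <- sum(is.na(pv))
    stageLog("ewas", "%d probes fit (%s), %d skipped, %d significant at p < %.2g",
             nrow(out) - nSkip, mode, nSkip, sum(out$significant), alpha)
    out
}

#' Cross-tabulate association hits by reliability cluster
#'
#' @param results EWAS table from \code{\link{runEwas}}.
#' @param assignment cluster assignment from \code{\link{classifySites}};
#'   probe universes must match.
#' @return list with \code{counts} (cluster x significant/total),
#'   \code{fractionHigh} (share of significant hits in the
#'   high-reliability cluster).
#' @export
summarizeByCluster <- function(results, assignment) {
    mism <- c(setdiff(results$probe_id, assignment$probe_id),
              setdiff(assignment$probe_id, results$probe_id))
    if (length(mism))
        stop("probe universes differ between EWAS results and cluster assignment; e.g. ",
             paste(head(mism, 5L), collapse = ", "))
    cl <- assignment$cluster[match(results$probe_id, assignment$probe_id)]
    sig <- results$significant
    counts <- data.frame(
        cluster = levels(cl),
        significant = as.integer(table(cl[sig])[levels(cl)]),
        total = as.integer(table(cl)[levels(cl)]))
    counts[is.na(counts)] <- 0L
    nsig <- sum(counts$significant)
    list(counts = counts,
         fractionHigh = if (nsig > 0)
             counts$significant[counts$cluster == "high"] / nsig
         else NA_real_)
}

#' Power of a single Bonferroni-corrected association test
#'
#' Two-sided power for one regressor explaining a fraction \code{r2} of
#' outcome variance at sample size \code{n}, tested at per-test level
#' \code{alphaTotal / nTests}, from the noncentral F distribution with
#' noncentrality \eqn{n \cdot r^2 / (1 - r^2)}.
#'
#' @param n sample size.
#' @param r2 proportion of variance explained (scalar or vector), in
#'   (0, 1).
#' @param nTests number of tests in the Bonferroni family.
#' @param alphaTotal family-wise significance level, default 0.05.
#' @return power in [0, 1], same length as \code{r2}.
#' @examples
#' powerBonferroni(2500, 0.01, 473788)
#' @export
powerBonferroni <- function(n, r2, nTests, alphaTotal = 0.05) {
    if (n < 3) stop("n must be at least 3")
    if (any(r2 <= 0 | r2 >= 1)) stop("r2 must lie strictly in (0, 1)")
    lambda <- n * r2 / (1 - r2)
    crit <- stats::qf(1 - alphaTotal / nTests, 1, n - 2)
    1 - stats::pf(crit, 1, n - 2, ncp = lambda)
}

#' Power gain from excluding unreliable probes
#'
#' Excluding a fraction of probes (e.g. the low-reliability half) shrinks
#' the Bonferroni family and relaxes the per-test threshold; this computes
#' the resulting power increase over a grid of effect sizes and reports
#' the maximum.
#'
#' @param n sample size, default 2500.
#' @param r2Grid effect-size grid (fractions of variance explained),
#'   default \code{seq(0.002, 0.03, by = 0.0005)}.
#' @param nTestsFull total number of probes tested, default 473788.
#' @param fractionExcluded fraction of probes removed, in (0, 1).
#' @param alphaTotal family-wise level, default 0.05.
#' @return list with \code{r2} (the grid), \code{gain} (per-grid-point
#'   power difference) and \code{maxGain}.
#' @examples
#' powerGain()$maxGain  # ~0.05 at n = 2500 with half the probes excluded
#' @export
powerGain <- function(n = 2500, r2Grid = seq(0.002, 0.03, by = 0.0005),
                      nTestsFull = 473788, fractionExcluded = 0.5,
                      alphaTotal = 0.05) {
    if (!length(r2Grid)) stop("effect-size grid is empty")
    if (fractionExcluded < 0 || fractionExcluded >= 1)
        stop("fractionExcluded must lie in [0, 1)")
    reduced <- nTestsFull * (1 - fractionExcluded)
    gain <- powerBonferroni(n, r2Grid, reduced, alphaTotal) -
        powerBonferroni(n, r2Grid, nTestsFull, alphaTotal)
    list(r2 = r2Grid, gain = gain, maxGain = max(gain))
}
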