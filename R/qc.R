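getDetP <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"detectionP" %in% SummarizedExperiment::assayNames(x))
            stop("no 'detectionP' assay present")
        SummarizedExperiment::assay(x, "detectionP")
    } else as.matrix(x)
}

#' Per-sample detection pass rates
#'
#' For each sample, the fraction of probes whose detection p-value is at or
#' below \code{detectionAlpha} (the boundary counts as a pass; failures are
#' strictly above the threshold).
#'
#' @param x a \linkS4class{MethylationExperiment} with a detectionP assay,
#'   or a detection p-value matrix (probes x samples).
#' @param detectionAlpha detection p-value threshold, default 0.01.
#' @return named numeric vector of pass rates in [0, 1].
#' @export
samplePassRates <- function(x, detectionAlpha = 0.01) {
    dp <- getDetP(x)
    if (!length(dp)) stop("empty detection p-value matrix")
    colMeans(dp <= detectionAlpha, na.rm = TRUE)
}

#' Per-probe detection pass rates
#'
#' @inheritParams samplePassRates
#' @return named numeric vector, one pass rate per probe.
#' @export
probePassRates <- function(x, detectionAlpha = 0.01) {
    dp <- getDetP(x)
    if (!length(dp)) stop("empty detection p-value matrix")
    rowMeans(dp <= detectionAlpha, na.rm = TRUE)
}

#' Apply sample- and probe-level pass-rate filters
#'
#' Samples whose pass rate falls below \code{minSamplePass} are removed
#' first; probe pass rates are then recomputed on the retained samples and
#' probes below \code{minProbePass} removed. Boundary values are retained
#' (a pass rate exactly at the threshold passes). Values are never
#' modified, only rows/columns dropped.
#'
#' @param x a \linkS4class{MethylationExperiment} carrying beta and
#'   detectionP assays.
#' @param minSamplePass minimum sample pass rate, default 0.99.
#' @param minProbePass minimum probe pass rate, default 0.99.
#' @param detectionAlpha detection p-value threshold, default 0.01.
#' @return list with \code{study} (the filtered
#'   \linkS4class{MethylationExperiment}) and \code{report}
#'   (a \linkS4class{QCReport}).
#' @export
applyPassRateFilters <- function(x, minSamplePass = 0.99,
                                 minProbePass = 0.99,
                                 detectionAlpha = 0.01) {
    stopifnot(is(x, "MethylationExperiment"))
    before <- c(probes = nrow(x), samples = ncol(x))
    sr <- samplePassRates(x, detectionAlpha)
    dropS <- sr < minSamplePass
    if (all(dropS))
        stop("no data remaining: every sample falls below the pass-rate threshold")
    x2 <- x[, !dropS]
    pr <- probePassRates(x2, detectionAlpha)
    dropP <- pr < minProbePass
    x3 <- x2[!dropP, ]
    report <- new("QCReport",
                  excludedSamples = sr[dropS],
                  excludedProbes = pr[dropP],
                  thresholds = c(detectionAlpha = detectionAlpha,
                                 minSamplePass = minSamplePass,
                                 minProbePass = minProbePass),
                  countsBefore = before,
                  countsAfter = c(probes = nrow(x3), samples = ncol(x3)))
    list(study = x3, report = report)
}

#' Probes flagged for SNP proximity
#'
#' Returns the IDs of probes with a common SNP (MAF > 0.05) within 50 bp of
#' the interrogated CpG, as recorded in the annotation's
#' \code{snp_within_50bp} flag. These probes are excluded from
#' genome-wide-significant association summaries.
#'
#' @param annotation a data.frame/DataFrame with columns \code{probe_id}
#'   and \code{snp_within_50bp}, or a \linkS4class{MethylationExperiment}
#'   whose rowData carries them.
#' @return character vector of flagged probe IDs.
#' @export
snpProbeMask <- function(annotation) {
    if (is(annotation, "SummarizedExperiment"))
        annotation <- as.data.frame(SummarizedExperiment::rowData(annotation))
    annotation <- as.data.frame(annotation)
    if (!"snp_within_50bp" %in% colnames(annotation))
        stop("annotation lacks the 'snp_within_50bp' flag column")
    ids <- if ("probe_id" %in% colnames(annotation)) annotation$probe_id
           else rownames(annotation)
    ids[as.logical(annotation$snp_within_50bp) %in% TRUE]
}

#' Write a QC report to disk
#'
#' @param report a \linkS4class{QCReport}.
#' @param path output path for the JSON report; a sibling \code{.txt}
#'   summary is written alongside.
#' @return invisibly, the JSON path.
#' @export
writeQCReport <- function(report, path) {
    obj <- list(thresholds = as.list(report@thresholds),
                counts_before = as.list(report@countsBefore),
                counts_after = as.list(report@countsAfter),
                excluded_samples = as.list(report@excludedSamples),
                excluded_probes = as.list(report@excludedProbes))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    txt <- sub("\\.json$", ".txt", path)
    if (identical(txt, path)) txt <- paste0(path, ".txt")
    writeLines(utils::capture.output(show(report)), txt)
    invisible(path)
}
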