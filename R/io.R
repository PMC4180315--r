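# fread that handles .gz transparently without optional helper packages
freadAny <- function(path, ...) {
    if (grepl("\\.gz$", path)) {
        con <- gzfile(path, "rt")
        on.exit(close(con))
        data.table::fread(text = readLines(con), ...)
    } else data.table::fread(path, ...)
}

#' Read a beta-value matrix
#'
#' Tab-separated, probes as rows; first column holds probe IDs, header
#' holds sample IDs. Gzip-compressed files are handled transparently.
#' Values outside [0, 1] are rejected with the offending cell named.
#'
#' @param path path to a TSV(.gz) file.
#' @return numeric matrix, probes x samples.
#' @export
readBetaMatrix <- function(path) {
    dt <- freadAny(path, sep = "\t")
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- as.character(dt[[1L]])
    storage.mode(m) <- "double"
    if (anyDuplicated(rownames(m))) stop("duplicate probe IDs in ", path)
    if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in ", path)
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad)) {
        ij <- arrayInd(bad[1L], dim(m))
        stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (value %.4g)",
                     rownames(m)[ij[1L]], colnames(m)[ij[2L]], m[bad[1L]]))
    }
    m
}

#' @rdname readBetaMatrix
#' @details \code{readDetectionP} reads a detection p-value matrix in the
#'   same layout.
#' @export
readDetectionP <- function(path) {
    dt <- freadAny(path, sep = "\t")
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- as.character(dt[[1L]])
    storage.mode(m) <- "double"
    if (any(!is.na(m) & (m < 0 | m > 1)))
        stop("detection p-values out of [0,1] in ", path)
    m
}

#' Read a sample sheet
#'
#' CSV with one row per sample; must contain \code{sample_id} and
#' \code{subject_id} columns (chip and covariate columns as available).
#'
#' @param path path to a CSV file.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
    df <- as.data.frame(freadAny(path))
    need <- c("sample_id", "subject_id")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample sheet lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in ", path)
    df
}

#' Read a probe annotation table
#'
#' CSV with \code{probe_id}, \code{design_type} (I/II),
#' \code{island_relation} (island/shore/shelf/open_sea),
#' \code{snp_within_50bp} and \code{cross_reactive} flags.
#'
#' @param path path to a CSV file.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
    df <- as.data.frame(freadAny(path))
    if (!"probe_id" %in% colnames(df))
        stop("annotation lacks a 'probe_id' column")
    if (anyDuplicated(df$probe_id)) stop("duplicate probe IDs in ", path)
    if ("design_type" %in% colnames(df)) {
        bad <- setdiff(unique(df$design_type), c("I", "II"))
        if (length(bad))
            stop("unknown design_type level(s): ", paste(bad, collapse = ", "))
    }
    if ("island_relation" %in% colnames(df)) {
        bad <- setdiff(unique(df$island_relation),
                       c("island", "shore", "shelf", "open_sea"))
        if (length(bad))
            stop("unknown island_relation level(s): ",
                 paste(bad, collapse = ", "))
    }
    df
}

writeMatrixTSV <- function(m, path, idCol = "probe_id") {
    # %.17g guarantees the decimal text round-trips to the same double
    txt <- as.data.frame(lapply(seq_len(ncol(m)), function(j)
        sprintf("%.17g", m[, j])))
    colnames(txt) <- colnames(m)
    df <- cbind(stats::setNames(data.frame(rownames(m)), idCol), txt)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Write a simulated study to an output directory
#'
#' Emits the beta and detection-p matrices as gzip-compressed TSV, the
#' sample sheet and annotation as CSV, the truth table as TSV, and the
#' configuration as JSON.
#'
#' @param sim list from \code{\link{simulateMethylationStudy}}.
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{SimulationConfig} used (echoed as JSON).
#' @return invisibly, the directory.
#' @export
writeStudy <- function(sim, dir, config = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    study <- sim$study
    writeMatrixTSV(SummarizedExperiment::assay(study, "beta"),
                   file.path(dir, "beta.tsv.gz"))
    if ("detectionP" %in% SummarizedExperiment::assayNames(study))
        writeMatrixTSV(SummarizedExperiment::assay(study, "detectionP"),
                       file.path(dir, "detection_p.tsv.gz"))
    data.table::fwrite(as.data.frame(SummarizedExperiment::colData(study)),
                       file.path(dir, "sample_sheet.csv"))
    data.table::fwrite(as.data.frame(SummarizedExperiment::rowData(study)),
                       file.path(dir, "annotation.csv"))
    if (!is.null(sim$truth))
        data.table::fwrite(as.data.frame(sim$truth),
                           file.path(dir, "truth.tsv"), sep = "\t")
    if (!is.null(config)) {
        cfg <- sapply(slotNames(class(config)),
                      function(s) slot(config, s), simplify = FALSE)
        cfg$varianceLaw <- if (identical(config@varianceLaw,
                                         defaultVarianceLaw))
            "default" else "custom"
        jsonlite::write_json(cfg, file.path(dir, "config.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}

#' Assemble a MethylationExperiment from files
#'
#' @param betaPath,sheetPath TSV beta matrix and CSV sample sheet
#'   (required).
#' @param annotationPath,detectionPPath optional annotation CSV and
#'   detection p-value TSV.
#' @return a \linkS4class{MethylationExperiment}.
#' @export
readStudy <- function(betaPath, sheetPath, annotationPath = NULL,
                      detectionPPath = NULL) {
    beta <- readBetaMatrix(betaPath)
    sheet <- readSampleSheet(sheetPath)
    annot <- if (!is.null(annotationPath)) readAnnotation(annotationPath)
    detp <- if (!is.null(detectionPPath)) readDetectionP(detectionPPath)
    if (!is.null(detp)) {
        if (!identical(dim(detp), dim(beta)))
            stop("detection p-value matrix dimensions do not match the beta matrix")
        detp <- detp[rownames(beta), colnames(beta)]
    }
    MethylationExperiment(beta, sheet, annot, detp)
}

#' Stratified ICC distribution summary
#'
#' For each probe stratum (Infinium design type, CpG-island relation,
#' cross-reactive flag, SNP flag), the fraction of probes whose ICC
#' exceeds each threshold, plus fixed-width histogram counts (bin width
#' 0.05 on [0, 1]).
#'
#' @param iccTab ICC table from \code{\link{iccTable}}.
#' @param annotation probe annotation (data.frame with \code{probe_id}),
#'   or a \linkS4class{MethylationExperiment} whose rowData carries it.
#' @param thresholds ICC thresholds, default \code{c(0.2, 0.4, 0.8)}.
#' @return list with \code{fractions} (long data.frame: stratum variable,
#'   level, threshold, fraction, n) and \code{histogram} (bin counts per
#'   stratum level). Empty strata are absent from the tables rather than
#'   reported as 0/0.
#' @export
stratifiedICCSummary <- function(iccTab, annotation,
                                 thresholds = c(0.2, 0.4, 0.8)) {
    if (is(annotation, "SummarizedExperiment"))
        annotation <- data.frame(
            probe_id = rownames(annotation),
            as.data.frame(SummarizedExperiment::rowData(annotation)))
    annotation <- as.data.frame(annotation)
    tab <- as.data.frame(iccTab)
    idx <- match(tab$probe_id, annotation$probe_id)
    strataVars <- intersect(c("design_type", "island_relation",
                              "cross_reactive", "snp_within_50bp"),
                            colnames(annotation))
    icc <- tab$icc
    breaks <- seq(0, 1, by = 0.05)
    rows <- list(); hists <- list()
    groups <- c(list(all = rep("all", length(icc))),
                lapply(annotation[idx, strataVars, drop = FALSE],
                       as.character))
    for (v in names(groups)) {
        for (lev in sort(unique(stats::na.omit(groups[[v]])))) {
            sel <- !is.na(icc) & groups[[v]] %in% lev
            if (!any(sel)) next
            for (th in thresholds)
                rows[[length(rows) + 1L]] <- data.frame(
                    stratum = v, level = lev, threshold = th,
                    fraction = mean(icc[sel] > th), n = sum(sel))
            h <- hist(pmin(icc[sel], 1 - 1e-12), breaks = breaks,
                      plot = FALSE)
            hists[[paste(v, lev, sep = ":")]] <- data.frame(
                stratum = v, level = lev, bin_lo = head(breaks, -1L),
                bin_hi = breaks[-1L], count = h$counts)
        }
    }
    list(fractions = do.call(rbind, rows),
         histogram = do.call(rbind, hists))
}

#' Run the full reliability pipeline
#'
#' Composes the stages: pass-rate QC, per-probe ICC estimation, censored
#' and truncated mixture fits, model comparison, posterior classification,
#' the EWAS demonstration, the cluster summary and the stratified ICC
#' summaries. All tabular outputs are written as TSV, fits and the
#' manifest as JSON. Deterministic for a given study and seed.
#'
#' @param study a \linkS4class{MethylationExperiment} (with detectionP for
#'   the QC stage).
#' @param outdir output directory.
#' @param seed seed for mixture restarts, default 1.
#' @param detectionAlpha,minSamplePass,minProbePass QC thresholds.
#' @param piCutoff posterior cutoff for classification, default 0.01.
#' @param ewasAlpha genome-wide significance threshold, default 1e-7.
#' @param phenotype,covariates passed to \code{\link{runEwas}}.
#' @param runEwasStage set FALSE to skip the association stage.
#' @return invisibly, a list with all stage results.
#' @export
runPipeline <- function(study, outdir, seed = 1L,
                        detectionAlpha = 0.01, minSamplePass = 0.99,
                        minProbePass = 0.99, piCutoff = 0.01,
                        ewasAlpha = 1e-7, phenotype = "smoking",
                        covariates = c("age", "sex", "bmi", "alcohol",
                                       "pc1", "pc2", "visit", "center",
                                       "chip_row"),
                        runEwasStage = TRUE) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stage <- "qc"
    res <- list()
    tryCatch({
        if ("detectionP" %in% SummarizedExperiment::assayNames(study)) {
            qc <- applyPassRateFilters(study, minSamplePass, minProbePass,
                                       detectionAlpha)
            writeQCReport(qc$report, file.path(outdir, "qc_report.json"))
            stageLog(stage, "samples %d -> %d, probes %d -> %d",
                     ncol(study), ncol(qc$study), nrow(study),
                     nrow(qc$study))
            study <- qc$study
            res$qc <- qc$report
        } else stageLog(stage, "no detectionP assay; QC skipped")

        stage <- "icc"
        tab <- iccTable(study)
        writeICCTable(tab, file.path(outdir, "icc_table.tsv"))
        nUnest <- sum(is.na(tab$icc))
        stageLog(stage, "%d probes, %d unestimable, median ICC %.3f",
                 nrow(tab), nUnest, stats::median(tab$icc, na.rm = TRUE))
        if (nUnest > 0)
            warning(nUnest, " probes had fewer than 2 usable replicate sets")
        res$icc <- tab
        trend <- iccSdTrend(tab)
        data.table::fwrite(trend, file.path(outdir, "icc_sd_trend.tsv"),
                           sep = "\t")
        res$trend <- trend

        stage <- "fit-mixture"
        iccs <- tab$icc[!is.na(tab$icc)]
        fitC <- fitCensoredMixture(iccs, seed = seed)
        fitT <- fitTruncatedMixture(iccs, seed = seed)
        writeMixtureFit(fitC, file.path(outdir, "fit_censored.json"))
        writeMixtureFit(fitT, file.path(outdir, "fit_truncated.json"))
        cmp <- compareModels(fitC, fitT)
        stageLog(stage, "censored loglik %.1f, truncated loglik %.1f -> %s",
                 fitC@loglik, fitT@loglik, cmp$model)
        res$fits <- list(censored = fitC, truncated = fitT,
                         comparison = cmp)

        stage <- "classify"
        assign <- classifySites(tab, cmp$chosen, piCutoff)
        data.table::fwrite(as.data.frame(assign),
                           file.path(outdir, "clusters.tsv"), sep = "\t")
        cc <- table(assign$cluster)
        stageLog(stage, "zero %d / low %d / high %d",
                 cc[["zero"]], cc[["low"]], cc[["high"]])
        res$clusters <- assign

        stage <- "report"
        strat <- stratifiedICCSummary(tab, study)
        data.table::fwrite(strat$fractions,
                           file.path(outdir, "icc_stratified.tsv"),
                           sep = "\t")
        data.table::fwrite(strat$histogram,
                           file.path(outdir, "icc_histogram.tsv"),
                           sep = "\t")
        res$stratified <- strat

        if (runEwasStage) {
            stage <- "ewas"
            ew <- runEwas(study, phenotype = phenotype,
                          covariates = covariates, alpha = ewasAlpha)
            data.table::fwrite(as.data.frame(ew),
                               file.path(outdir, "ewas.tsv"), sep = "\t")
            res$ewas <- ew
            summ <- summarizeByCluster(ew, assign)
            data.table::fwrite(summ$counts,
                               file.path(outdir, "ewas_by_cluster.tsv"),
                               sep = "\t")
            res$ewasSummary <- summ
        }

        stage <- "manifest"
        jsonlite::write_json(list(
            package = "methylICC",
            version = as.character(utils::packageVersion("methylICC")),
            seed = seed,
            thresholds = list(detection_alpha = detectionAlpha,
                              min_sample_pass = minSamplePass,
                              min_probe_pass = minProbePass,
                              pi_cutoff = piCutoff,
                              ewas_alpha = ewasAlpha),
            phenotype = phenotype, covariates = covariates,
            ewas_stage = runEwasStage,
            chosen_model = res$fits$comparison$model),
            file.path(outdir, "manifest.json"), auto_unbox = TRUE,
            digits = NA)
    }, error = function(e)
        stop(sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE))
    invisible(res)
}
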