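#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MethylationExperiment: beta values plus replicate/chip design
#'
#' A thin subclass of \linkS4class{SummarizedExperiment} holding a probe x
#' sample matrix of methylation beta values in the \code{"beta"} assay and,
#' optionally, a matching matrix of detection p-values in the
#' \code{"detectionP"} assay. \code{colData} is the sample sheet (subject,
#' chip, chip row, phenotype and covariates); \code{rowData} is the probe
#' annotation (Infinium design type, CpG-island relation, SNP-within-50bp
#' and cross-reactive flags).
#'
#' Validity requires beta values in [0, 1] (NA allowed), detection p-values
#' in [0, 1] with dimensions matching beta, and a \code{subject_id} column
#' in \code{colData} defining the replicate sets.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    nms <- SummarizedExperiment::assayNames(object)
    if (!"beta" %in% nms)
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        bad <- which(!is.na(b) & (b < 0 | b > 1))
        if (length(bad)) {
            ij <- arrayInd(bad[1L], dim(b))
            msg <- c(msg, sprintf(
                "beta values must lie in [0,1]; first offending cell: probe '%s', sample '%s' (value %.4g)",
                rownames(b)[ij[1L]] %||% ij[1L],
                colnames(b)[ij[2L]] %||% ij[2L], b[bad[1L]]))
        }
    }
    if ("detectionP" %in% nms) {
        dp <- SummarizedExperiment::assay(object, "detectionP")
        if (any(!is.na(dp) & (dp < 0 | dp > 1)))
            msg <- c(msg, "detection p-values must lie in [0,1]")
    }
    if (!"subject_id" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'subject_id' column (replicate-set identifier)")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate probe IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param beta numeric matrix of beta values, probes as rows, samples as
#'   columns; values in [0,1].
#' @param sampleSheet data.frame (or DataFrame) with one row per column of
#'   \code{beta}; must contain \code{subject_id}. If a \code{sample_id}
#'   column is present it is matched against \code{colnames(beta)}.
#' @param annotation optional data.frame with one row per probe
#'   (\code{probe_id} column matched against \code{rownames(beta)}).
#' @param detectionP optional matrix of detection p-values, same dimensions
#'   and dimnames as \code{beta}.
#' @return A \linkS4class{MethylationExperiment}.
#' @examples
#' b <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4),
#'                     subject_id = c("a", "a", "b", "c"),
#'                     chip_id = c("c1", "c2", "c1", "c2"))
#' me <- MethylationExperiment(b, sheet)
#' @export
MethylationExperiment <- function(beta, sampleSheet, annotation = NULL,
                                  detectionP = NULL) {
    beta <- as.matrix(beta)
    storage.mode(beta) <- "double"
    sampleSheet <- as.data.frame(sampleSheet)
    if ("sample_id" %in% colnames(sampleSheet)) {
        if (!is.null(colnames(beta))) {
            idx <- match(colnames(beta), sampleSheet$sample_id)
            if (anyNA(idx))
                stop("sample sheet is missing samples present in the beta matrix: ",
                     paste(head(setdiff(colnames(beta), sampleSheet$sample_id)),
                           collapse = ", "))
            extra <- setdiff(sampleSheet$sample_id, colnames(beta))
            if (length(extra))
                stop("sample sheet references samples absent from the beta matrix: ",
                     paste(head(extra), collapse = ", "))
            sampleSheet <- sampleSheet[idx, , drop = FALSE]
        } else colnames(beta) <- sampleSheet$sample_id
    }
    rownames(sampleSheet) <- colnames(beta)
    assays <- list(beta = beta)
    if (!is.null(detectionP)) {
        detectionP <- as.matrix(detectionP)
        if (!identical(dim(detectionP), dim(beta)))
            stop("detection p-value matrix dimensions do not match the beta matrix")
        dimnames(detectionP) <- dimnames(beta)
        assays$detectionP <- detectionP
    }
    rowDat <- NULL
    if (!is.null(annotation)) {
        annotation <- as.data.frame(annotation)
        if ("probe_id" %in% colnames(annotation) && !is.null(rownames(beta))) {
            idx <- match(rownames(beta), annotation$probe_id)
            if (anyNA(idx))
                stop("annotation is missing probes present in the beta matrix")
            annotation <- annotation[idx, , drop = FALSE]
        }
        rownames(annotation) <- rownames(beta)
        rowDat <- DataFrame(annotation)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = DataFrame(sampleSheet))
    if (!is.null(rowDat)) SummarizedExperiment::rowData(se) <- rowDat
    new("MethylationExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SimulationConfig: design of a synthetic methylation study
#'
#' Holds the study design the generator runs forward: cohort size,
#' replicate structure (duplicate/triplicate sets spread over chips), probe
#' count, the per-probe variance-component law, the zero-ICC mass, the
#' phenotype effect structure and the detection-failure rate.
#'
#' @slot nSubjects number of biological subjects.
#' @slot nReplicatePairs subjects measured twice.
#' @slot nReplicateTriples subjects measured three times.
#' @slot nProbes number of CpG probes.
#' @slot samplesPerChip chip capacity (HM450: 12 = 6 rows x 2 columns).
#' @slot chipRows rows per chip.
#' @slot fractionZeroIcc fraction of probes with between-subject variance
#'   exactly 0.
#' @slot varianceLaw function(n) returning a data.frame with columns
#'   \code{sigma2_chip}, \code{sigma2_e}, \code{icc} (target ICC used to set
#'   sigma2_b) for n probes.
#' @slot effectProbes number of probes carrying a phenotype effect.
#' @slot effectSize mean beta difference between phenotype groups.
#' @slot effectPlacement "high" restricts effect probes to reliable
#'   (target ICC >= 0.5) probes; "any" places them uniformly.
#' @slot sameChipPairs replicate pairs deliberately placed on one chip.
#' @slot detectionFailRate per-entry probability of detection p > 0.01.
#' @slot phenotypePrevalence probability a subject is a case
#'   (e.g. current smoker).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nSubjects = "integer", nReplicatePairs = "integer",
    nReplicateTriples = "integer", nProbes = "integer",
    samplesPerChip = "integer", chipRows = "integer",
    fractionZeroIcc = "numeric", varianceLaw = "function",
    effectProbes = "integer", effectSize = "numeric",
    effectPlacement = "character", sameChipPairs = "integer",
    detectionFailRate = "numeric", phenotypePrevalence = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(nSubjects = object@nSubjects,
             nReplicatePairs = object@nReplicatePairs,
             nReplicateTriples = object@nReplicateTriples,
             nProbes = object@nProbes,
             samplesPerChip = object@samplesPerChip,
             effectProbes = object@effectProbes,
             sameChipPairs = object@sameChipPairs)
    if (any(cnt < 0L)) msg <- c(msg, "all counts must be >= 0")
    prp <- c(fractionZeroIcc = object@fractionZeroIcc,
             detectionFailRate = object@detectionFailRate,
             phenotypePrevalence = object@phenotypePrevalence)
    if (any(prp < 0 | prp > 1)) msg <- c(msg, "proportions must lie in [0,1]")
    if (object@nReplicatePairs + object@nReplicateTriples > object@nSubjects)
        msg <- c(msg, "replicated subjects cannot exceed nSubjects")
    if (object@effectProbes > object@nProbes)
        msg <- c(msg, "effectProbes cannot exceed nProbes")
    if (!object@effectPlacement %in% c("high", "any"))
        msg <- c(msg, "effectPlacement must be 'high' or 'any'")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class constructor with the package's default
#'   study conditions: a 500-subject cohort with the canonical replicate
#'   layout of 125 duplicate and 5 triplicate sets (130 sets, 265 replicate
#'   samples) on 12-sample chips, 2000 probes with an 8\% zero-ICC mass and
#'   a bimodal reliability law (target ICC modes near 0.10 and 0.75), 30
#'   effect probes at a beta difference of 0.15, and a 0.5\% detection
#'   failure rate.
#' @param nSubjects,nReplicatePairs,nReplicateTriples,nProbes,samplesPerChip
#'   see slots.
#' @param chipRows,fractionZeroIcc,varianceLaw,effectProbes,effectSize see
#'   slots.
#' @param effectPlacement,sameChipPairs,detectionFailRate see slots.
#' @param phenotypePrevalence,seed see slots.
#' @export
simulationConfig <- function(nSubjects = 500L, nReplicatePairs = 125L,
                             nReplicateTriples = 5L, nProbes = 2000L,
                             samplesPerChip = 12L, chipRows = 6L,
                             fractionZeroIcc = 0.08,
                             varianceLaw = defaultVarianceLaw,
                             effectProbes = 30L, effectSize = 0.15,
                             effectPlacement = "high",
                             sameChipPairs = 2L,
                             detectionFailRate = 0.005,
                             phenotypePrevalence = 0.256,
                             seed = 1L) {
    new("SimulationConfig",
        nSubjects = as.integer(nSubjects),
        nReplicatePairs = as.integer(nReplicatePairs),
        nReplicateTriples = as.integer(nReplicateTriples),
        nProbes = as.integer(nProbes),
        samplesPerChip = as.integer(samplesPerChip),
        chipRows = as.integer(chipRows),
        fractionZeroIcc = fractionZeroIcc,
        varianceLaw = varianceLaw,
        effectProbes = as.integer(effectProbes),
        effectSize = effectSize,
        effectPlacement = effectPlacement,
        sameChipPairs = as.integer(sameChipPairs),
        detectionFailRate = detectionFailRate,
        phenotypePrevalence = phenotypePrevalence,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  subjects: %d (%d duplicate + %d triplicate replicate sets)\n",
                object@nSubjects, object@nReplicatePairs,
                object@nReplicateTriples))
    cat(sprintf("  probes: %d (zero-ICC fraction %.3f)\n",
                object@nProbes, object@fractionZeroIcc))
    cat(sprintf("  chips: %d samples/chip, %d rows; %d same-chip pairs\n",
                object@samplesPerChip, object@chipRows, object@sameChipPairs))
    cat(sprintf("  effects: %d probes, delta-beta %.3f (%s placement)\n",
                object@effectProbes, object@effectSize,
                object@effectPlacement))
    cat(sprintf("  detection fail rate: %.4f; phenotype prevalence: %.3f; seed: %d\n",
                object@detectionFailRate, object@phenotypePrevalence,
                object@seed))
})

#' MixtureFit: a fitted two-component reliability mixture
#'
#' Parameters of a censored- or truncated-normal mixture for the genome-wide
#' ICC distribution. Component 1 is the low-reliability cluster, component 2
#' the high-reliability cluster; \code{p} is the component-1 mixing
#' proportion among modeled (non-zero, for the truncated model) sites, and
#' \code{p0} the sample proportion of exact-zero ICCs (truncated model
#' only; 0 for the censored model). \code{loglik} is the maximized log
#' likelihood on the full data including zeros.
#'
#' @slot model "censored" or "truncated".
#' @slot p,mu1,sigma1,mu2,sigma2 mixture parameters.
#' @slot p0 proportion of exact zeros.
#' @slot loglik maximized log likelihood (full data).
#' @slot nObs,nZero data sizes the likelihood was evaluated on.
#' @slot nIter EM iterations used.
#' @slot converged logical.
#' @slot loglikTrace per-iteration log likelihood (EM ascent diagnostic).
#' @export
setClass("MixtureFit", representation(
    model = "character", p = "numeric", mu1 = "numeric", sigma1 = "numeric",
    mu2 = "numeric", sigma2 = "numeric", p0 = "numeric", loglik = "numeric",
    nObs = "integer", nZero = "integer", nIter = "integer",
    converged = "logical", loglikTrace = "numeric"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    if (!object@model %in% c("censored", "truncated"))
        msg <- c(msg, "model must be 'censored' or 'truncated'")
    if (!is.na(object@p) && (object@p < 0 || object@p > 1))
        msg <- c(msg, "p must lie in [0,1]")
    if (object@p0 < 0 || object@p0 > 1) msg <- c(msg, "p0 must lie in [0,1]")
    if (!is.na(object@sigma1) && object@sigma1 <= 0)
        msg <- c(msg, "sigma1 must be > 0")
    if (!is.na(object@sigma2) && object@sigma2 <= 0)
        msg <- c(msg, "sigma2 must be > 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn MixtureFit-class constructor; builds a fit object directly
#'   from parameter values (e.g. published estimates) so posterior
#'   classification can be run without refitting.
#' @param model,p,mu1,sigma1,mu2,sigma2,p0,loglik,nObs,nZero,nIter,converged
#'   slot values.
#' @export
mixtureFit <- function(model, p, mu1, sigma1, mu2, sigma2, p0 = 0,
                       loglik = NA_real_, nObs = NA_integer_,
                       nZero = NA_integer_, nIter = 0L, converged = TRUE) {
    new("MixtureFit", model = model, p = p, mu1 = mu1, sigma1 = sigma1,
        mu2 = mu2, sigma2 = sigma2, p0 = p0, loglik = loglik,
        nObs = as.integer(nObs), nZero = as.integer(nZero),
        nIter = as.integer(nIter), converged = converged,
        loglikTrace = numeric())
}

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf("MixtureFit (%s normal mixture)\n", object@model))
    cat(sprintf("  p (low-reliability proportion): %.4f\n", object@p))
    cat(sprintf("  component 1: mu = %.4f, sigma = %.4f\n",
                object@mu1, object@sigma1))
    cat(sprintf("  component 2: mu = %.4f, sigma = %.4f\n",
                object@mu2, object@sigma2))
    if (object@model == "truncated")
        cat(sprintf("  p0 (zero-ICC mass): %.4f\n", object@p0))
    cat(sprintf("  loglik: %.2f on %s sites (%s zeros); %d iterations; converged: %s\n",
                object@loglik, object@nObs, object@nZero, object@nIter,
                object@converged))
})

#' QCReport: record of pass-rate filtering
#'
#' @slot excludedSamples named numeric vector, pass rate of each removed
#'   sample.
#' @slot excludedProbes named numeric vector, pass rate of each removed
#'   probe.
#' @slot thresholds detection alpha and pass-rate cutoffs used.
#' @slot countsBefore,countsAfter c(probes, samples).
#' @export
setClass("QCReport", representation(
    excludedSamples = "numeric", excludedProbes = "numeric",
    thresholds = "numeric", countsBefore = "integer",
    countsAfter = "integer"))

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    cat(sprintf("  thresholds: detection alpha %.3g, sample pass >= %.3g, probe pass >= %.3g\n",
                object@thresholds[["detectionAlpha"]],
                object@thresholds[["minSamplePass"]],
                object@thresholds[["minProbePass"]]))
    cat(sprintf("  samples: %d -> %d (%d excluded)\n",
                object@countsBefore[["samples"]],
                object@countsAfter[["samples"]],
                length(object@excludedSamples)))
    cat(sprintf("  probes: %d -> %d (%d excluded)\n",
                object@countsBefore[["probes"]],
                object@countsAfter[["probes"]],
                length(object@excludedProbes)))
})
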