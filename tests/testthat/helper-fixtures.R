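# Shared fixtures, all built in code.

# hand-sized study: 3 subjects, two of them replicated, two chips
tinyStudy <- function(beta = NULL, detp = NULL) {
    sheet <- data.frame(
        sample_id = c("s1", "s2", "s3", "s4", "s5"),
        subject_id = c("a", "a", "b", "b", "c"),
        chip_id = c("c1", "c2", "c1", "c2", "c1"),
        chip_row = c(1L, 2L, 3L, 4L, 5L))
    if (is.null(beta))
        beta <- matrix(c(0.20, 0.30, 0.60, 0.70, 0.50,
                         0.80, 0.80, 0.50, 0.50, 0.10,
                         0.40, 0.40, 0.40, 0.40, 0.40),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(paste0("cg", 1:3), sheet$sample_id))
    annot <- data.frame(
        probe_id = rownames(beta),
        design_type = c("I", "II", "II")[seq_len(nrow(beta))],
        island_relation = rep("island", nrow(beta)),
        snp_within_50bp = c(FALSE, TRUE, FALSE)[seq_len(nrow(beta))],
        cross_reactive = rep(FALSE, nrow(beta)))
    MethylationExperiment(beta, sheet, annot, detp)
}

# fast generator defaults for unit tests
smallSim <- function(..., seed = 11) {
    simulateMethylationStudy(simulationConfig(
        nSubjects = 60, nReplicatePairs = 20, nReplicateTriples = 2,
        nProbes = 120, effectProbes = 5, seed = seed, ...))
}

# the published truncated-mixture estimates, with the zero-ICC proportion
# taken as 36,017 of 473,788 analyzed sites
table1TruncatedFit <- function() {
    mixtureFit("truncated", p = 0.67, mu1 = 0.04, sigma1 = 0.28,
               mu2 = 0.72, sigma2 = 0.11, p0 = 36017 / 473788)
}

table1CensoredFit <- function() {
    mixtureFit("censored", p = 0.55, mu1 = 0.15, sigma1 = 0.14,
               mu2 = 0.67, sigma2 = 0.14)
}
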