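# methylICC

Reliability of array-based DNA methylation measurements, quantified from
technical replicates.

Epigenome-wide association studies (EWAS) on Infinium-style arrays test
hundreds of thousands of CpG probes whose beta values (methylated signal
fraction, in [0, 1]) differ wildly in how reproducibly they can be
measured: many probes show so little inter-individual variation that
chip-to-chip batch effects dominate the signal. When a study includes
technical replicates — the same DNA measured two or three times, spread
across chips — every probe's reliability can be estimated and unreliable
probes flagged or excluded before association testing. `methylICC` is for
analysts of such replicated methylation studies.

## What it computes

**Per-probe ICC.** At each probe, replicate measurements follow a one-way
random-effects model `y_ij = mu + tau_j + eps_ij`, with `tau_j` the effect
of biological sample *j* and `eps_ij` technical noise. The intraclass
correlation

```
ICC = sigma2_tau / (sigma2_tau + sigma2_eps)
```

is estimated by method-of-moments ANOVA (unbalanced sets handled by the
k0 coefficient; negative between-set estimates truncated to 0, producing
the characteristic point mass of probes at ICC = 0). A chip-grouped
analogue `ICC_chip` quantifies how much of each probe's variance is batch.

**Mixture classification.** The genome-wide ICC distribution is fit by EM
with two two-component models — a censored normal mixture, and a
zero-inflated mixture of a truncated normal and a normal — compared on
maximized log likelihood. Probes are classified zero / low / high
reliability by the posterior probability of high-component membership
(cutoff 0.01; under published parameter estimates this corresponds to an
ICC threshold of about 0.37).

**Association demonstration.** A per-probe EWAS of a binary phenotype with
covariates and a chip random intercept (lme4), summarized by reliability
cluster, plus the Bonferroni power calculation showing what excluding
unreliable probes buys (noncentral-F power with noncentrality
`n * r2 / (1 - r2)`).

**Synthetic studies.** A generator runs the measurement model forward
(replicate sets spread over 12-sample chips, bimodal per-probe reliability
with an exact zero-ICC mass, phenotype effects, detection p-values) and
returns the ground truth, so the entire pipeline is testable without
cohort data.

## Worked example

```r
library(methylICC)

sim <- simulateMethylationStudy(simulationConfig(seed = 42))
sim$study
#> class: MethylationExperiment
#> dim: 2000 635
#> assays(2): beta detectionP

tab <- iccTable(sim$study)
summary(tab$icc)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.00000 0.06609 0.18579 0.35572 0.71932 0.99902

iccs <- tab$icc[!is.na(tab$icc)]
fitC <- fitCensoredMixture(iccs)
fitT <- fitTruncatedMixture(iccs)
compareModels(fitC, fitT)$model
#> [1] "truncated"

fitT
#> MixtureFit (truncated normal mixture)
#>   p (low-reliability proportion): 0.5522
#>   component 1: mu = 0.0946, sigma = 0.0993
#>   component 2: mu = 0.7559, sigma = 0.0974
#>   p0 (zero-ICC mass): 0.1270
#>   loglik: -70.53 on 2000 sites (254 zeros); 11 iterations; converged: TRUE

cl <- classifySites(tab, fitT, piCutoff = 0.01)
table(cl$cluster)
#> zero  low high
#>  254  962  784

ew <- runEwas(sim$study, phenotype = "smoking", mode = "lmm")
#> [ewas] 2000 probes fit (lmm), 0 skipped, 29 significant at p < 1e-07
summarizeByCluster(ew, cl)$fractionHigh
#> [1] 1
```

The ICC distribution is bimodal (modes near 0.1 and 0.75) with a spike at
exactly 0 — probes whose replicate noise exceeds their biological signal.
The truncated model fits better than the censored one, the probe universe
splits into the three reliability clusters, and every genome-wide
significant smoking association lands in the high-reliability cluster:
excluding low-ICC probes would cost no discoveries here while halving the
multiple-testing burden.

The classical threshold and the power argument, from published mixture
estimates rather than simulation:

```r
fit <- mixtureFit("truncated", p = 0.67, mu1 = 0.04, sigma1 = 0.28,
                  mu2 = 0.72, sigma2 = 0.11, p0 = 36017 / 473788)
iccThresholdForPosterior(fit, 0.01)
#> [1] 0.3739938
100 * powerGain(n = 2500, nTestsFull = 473788, fractionExcluded = 0.5)$maxGain
#> [1] 5.11556
```

An ICC of 0.37 marks the posterior-0.01 boundary of the high-reliability
cluster, and dropping half the probes buys about 5 percentage points of
power at its most favorable effect size.

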