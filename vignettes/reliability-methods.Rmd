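---
title: "Measuring and modeling the reliability of array methylation probes"
author: "methylICC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling the reliability of array methylation probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylICC)
```

## The problem

Infinium-style methylation arrays report a beta value per CpG probe and
sample — the fraction of methylated signal, bounded in [0, 1]. A large share
of probes interrogate CpGs with little inter-individual variation, so even
modest technical noise (chip-to-chip "batch" differences above all) can
dominate the measured signal at those sites and produce spurious
associations in epigenome-wide association studies (EWAS). When a study
carries technical replicates — the same bisulfite-converted DNA measured
twice or three times, ideally on different chips — the reliability of every
probe can be quantified and unreliable probes down-weighted or excluded.

`methylICC` implements that workflow: per-probe intraclass correlation
(ICC) from replicate sets, a mixture model for the genome-wide ICC
distribution, posterior classification of probes into zero / low / high
reliability clusters, and an association demonstration quantifying how the
clusters behave in an EWAS.

## The ICC model

At one probe, the measurement for replicate $i$ of biological sample
(replicate set) $j$ is modeled by a one-way random-effects ANOVA,

$$y_{ij} = \mu + \tau_j + \epsilon_{ij}, \qquad
\tau_j \sim (0, \sigma^2_\tau), \quad \epsilon_{ij} \sim (0, \sigma^2_\epsilon),$$

where $\sigma^2_\tau$ is variance between replicate sets (biology) and
$\sigma^2_\epsilon$ variance within sets (technical error). The intraclass
correlation

$$\mathrm{ICC} = \frac{\sigma^2_\tau}{\sigma^2_\tau + \sigma^2_\epsilon}$$

is 1 for a perfectly reproducible probe and 0 when replicate noise swamps
biology. `anovaComponents()` uses the method-of-moments estimator:
$\hat\sigma^2_\epsilon = MSW$, $\hat\sigma^2_\tau = (MSB - MSW)/k_0$ with
$k_0 = (N - \sum_j n_j^2/N)/(J-1)$ for unbalanced sets (duplicates mixed
with triplicates), and negative between-set estimates truncated to 0.

The estimator choice matters: truncation of negative moment estimates is
what produces a point mass of probes at ICC exactly 0, and that spike is a
real, interpretable feature of the genome-wide distribution (probes where
technical error clearly exceeds biological signal). A REML fit would reach
the zero boundary differently and smear the mass. The raw (possibly
negative) estimate is kept alongside for diagnostics.

Decomposing the technical term by chip, $y_{ij} = \mu + \tau_j + b_{l(ij)} +
\sum_p \beta_p X_{jp} + e_{ij}$, gives the batch-effect view of the same
model. `iccChip()` computes the analogous intraclass correlation with chip
as the grouping factor: probes with ICC$_{chip}$ near 1 are batch-dominated
and show replicate ICC near 0. By default it uses the replicate samples
only, so the two ICCs are computed from identical data; this is a
convention — the chip ICC is equally well-defined on all samples
(`samples = "all"`).

Per-probe SD is computed over one sample per subject (the first
occurrence), not over all samples, so replicated subjects are not counted
twice. `iccSdTrend()` smooths ICC against SD with `lowess`; high-SD probes
are overwhelmingly high-ICC, which is why an SD filter alone is a poor
substitute for reliability filtering — most probes sit at low SD where the
two quantities decouple.

## Mixture models for the ICC distribution

The genome-wide ICC distribution is bimodal with a spike at 0. Two
two-component models are fit by EM (`fitCensoredMixture()`,
`fitTruncatedMixture()`), and probes classified by the posterior
probability of high-reliability membership:

* **Censored normal mixture** — observations at 0 are treated as censored
  draws (true value $\le 0$): a zero contributes $\Phi(-\mu_k/\sigma_k)$
  for component $k$, a positive value the normal density. We censor *both*
  components: at fitted scales the high component's sub-zero mass is
  $\Phi(-0.67/0.14) \approx 10^{-6}$, so the choice is numerically
  indistinguishable from censoring only the low component, and a single
  coherent likelihood avoids a discontinuity. The M-step uses the expected
  sufficient statistics of a normal truncated above 0 (inverse-Mills
  corrections).
* **Zero-inflated truncated normal mixture** — the zero-ICC sites are split
  off as their own cluster with mass estimated by the sample proportion
  $p_0$; non-zero values follow a mixture of a normal truncated below at 0
  and a plain normal. For comparability the reported log likelihood
  includes the zeros: $\ell = n_0\log p_0 + \sum_i \log[p_1 f_{TN}(x_i) +
  p_2\,\phi((x_i-\mu_2)/\sigma_2)/\sigma_2]$ with $p_1 = p(1-p_0)$,
  $p_2 = (1-p)(1-p_0)$. The truncated component has no closed-form M-step;
  it is updated by a safeguarded numerical maximization of its weighted
  likelihood (which depends on the data only through three sufficient
  statistics, so the update is O(1) per evaluation), accepted only when it
  improves the objective — a generalized EM step that preserves monotone
  ascent, which the tests assert on every iteration trace.

Throughout, $p$ is stored as the mixing proportion of the **low**-
reliability (first) component. The truncated component is truncated below
at 0 only; mass above 1 is negligible at fitted scales and an upper
truncation is deliberately omitted. Component scales are floored at 0.001
on the ICC scale so that degenerate inputs (e.g. two repeated values)
converge to a point-mass-like fit instead of a diverging likelihood.
Initialization puts the component means at the 25th/75th percentiles of
the non-zero values with scale IQR/2 and $p = 0.5$; a handful of jittered
restarts (deterministic given `seed`) guard against local maxima.
Convergence is declared at a relative log-likelihood change below $10^{-8}$
(cap 2000 iterations). Models are compared on the full-data maximized log
likelihood (`compareModels()`; ties break to the truncated model, which is
also the better-fitting model on data with a genuine excess of zeros).

Classification (`classifySites()`): ICC = 0 is its own cluster; positive
ICCs go to the high cluster when $\pi(x) = p_2 g_2(x) / (p_1 g_1(x) + p_2
g_2(x)) \ge 0.01$, low otherwise; the boundary is assigned to high, which
maximizes the high-reliability cluster. The deliberately permissive cutoff
0.01 keeps moderate-ICC sites in the high cluster — the high component is
slightly left-skewed in real data, and a normal fit under-covers the 0.2 to
0.5 range, so a stricter cutoff would misclassify usable probes. Under the
published parameter estimates the 0.01 cutoff corresponds to an ICC
threshold of 0.37 (`iccThresholdForPosterior()`, bracketed root solve,
verified to cross the cutoff exactly once).

## The association demonstration

`runEwas()` regresses each probe's beta on a binary phenotype (e.g.
current smoking) with fixed covariates and a chip-level random intercept
(`lme4`), collapsing replicates to one sample per subject first. P-values
are Wald tests on the normal approximation; a non-convergent mixed fit
falls back to OLS for that probe and is flagged. The OLS mode (no chip
terms) exists to demonstrate the cost of ignoring batch structure: on data
with chip effects it yields at least as many "significant" probes, the
excess being technical false positives. Probes with a common SNP within
50 bp are dropped from the significant-hit summary (the flag is consumed
from the annotation, not computed). Significance uses the conventional
genome-wide $p < 10^{-7}$ Bonferroni-scale threshold.

`powerBonferroni()` computes two-sided power for a single regressor
explaining $r^2$ of variance from the noncentral F distribution with
noncentrality $n\,r^2/(1-r^2)$ at per-test level $\alpha/m$;
`powerGain()` evaluates the benefit of excluding a fraction of probes from
the Bonferroni family. At $n = 2500$ with 473,788 tests and half the
probes excluded, the maximum gain over an $r^2$ grid of 0.002 to 0.03 is
about 5 percentage points (peaking near $r^2 \approx 0.011$). The grid
bounds are a design choice: below 0.002 both powers are essentially zero,
above 0.03 both saturate at 1, so the maximum is interior; the "maximum
over the grid" reading is our interpretation of a gain quoted at
unspecified effect sizes.

## The synthetic-data generator

No suitable replicated cohort is freely available at this scale, so the
package ships a generator (`simulateMethylationStudy()`) that runs the
measurement model forward and returns the ground truth alongside. What it
emulates, and the default study conditions:

* **Replicate layout**: 130 replicate sets — 125 duplicates plus 5
  triplicates (265 replicate samples) — spread across 12-sample chips
  (6 rows x 2 columns, the standard HM450 arrangement, adopted as default
  since only the row position enters the model as a covariate), with
  replicates of a set on distinct chips except 2 same-chip pairs,
  mirroring the layout the method was developed on.
* **Cohort**: 500 subjects and 2000 probes by default — large enough for
  stable mixture fits and a powered EWAS, small enough that the full
  pipeline runs in minutes on one CPU; phenotype prevalence 0.256 and
  age/sex distributions echo the cohort the method was demonstrated on.
* **Variance components**: per-probe $(\sigma^2_b, \sigma^2_{chip},
  \sigma^2_e)$ from a configurable law. The default draws technical SDs of
  0.005–0.03 and a bimodal target ICC (modes near 0.10 and 0.75); 8% of
  probes get $\sigma^2_b = 0$ exactly (the zero-ICC mass; the count is
  `round(fraction * nProbes)`, so the realized fraction is exact). Probe
  means come from a trimodal Beta mixture (modes near 0.05, 0.5, 0.95).
* **Boundedness**: beta values are clamped to [0, 1] after summing the
  Gaussian terms — chosen over logit-scale simulation for transparency. To
  keep clamping rare, all component SDs are damped by $4\mu(1-\mu)$, the
  same heteroscedasticity beta values show near the boundaries; at default
  settings about 0.1% of entries clamp.
* **Effects**: 30 probes carry a mean beta difference of 0.15 between
  phenotype groups, placed on reliable probes (target ICC $\ge$ 0.5) by
  default — matching the empirical finding that genuine associations
  concentrate in the high-reliability cluster; `effectPlacement = "any"`
  removes the restriction.
* **Detection p-values**: each entry independently fails (p > 0.01) with
  probability 0.005.

What it does **not** emulate: fluorescence intensities and dye chemistry,
probe-type-specific distributional differences, cell-type composition,
genetic ancestry structure, or correlated detection failures. Passing
tests therefore show that the statistical machinery is correct under the
stated model, not that the model captures every feature of production
array data.

`simulateICCSample()` draws ICC values directly from the mixture law
(exact zero count `round(n * p0)`), used to test the EM machinery against
known parameters.

## Numerical choices and degenerate inputs

* Pass-rate QC (`applyPassRateFilters()`): samples filtered before probes
  — the order changes probe pass rates, so it is fixed and documented;
  boundary pass rates (exactly 99%) are retained and detection p exactly
  0.01 counts as a pass. Filtering is idempotent and never alters values.
* A replicate set reduced below size 2 by missingness is dropped from that
  probe's ANOVA; a probe with fewer than 2 usable sets is flagged
  unestimable (NA), never silently 0.
* Posterior at ICC = 0 is undefined under the truncated model (the zero
  cluster is handled separately) and raises an error; the censored model
  defines it through the censored masses.
* Likelihoods are computed on the log scale with log-sum-exp throughout;
  inverse-Mills ratios use `pnorm(..., log.p = TRUE)` to stay finite in
  far tails.
* All randomness (generator, restart jitter) is seeded and scoped: package
  functions restore the caller's RNG state.

## Problem sizes used in the checks

The shipped tests run the generator at its default 2000 probes / 130
replicate sets for the end-to-end check (estimated-vs-true ICC Spearman
correlation above 0.8; at least 90% of genome-wide-significant hits in the
high-reliability cluster), 20 replicates of n = 50,000 draws for mixture
parameter recovery (median absolute error at most 0.03 per parameter), 100
random datasets for the EM ascent property, and 200 replicate null studies
for the family-wise error check of the mixed model. These sizes give
stable Monte-Carlo behaviour while keeping a full run in the minutes
range.

## Known limitations

* The weighting of ICC estimates by their own uncertainty is not
  implemented; all probes enter the mixture fit equally.
* Three-component mixtures are deliberately not offered (they fit worse on
  the data the method was built for, and add identifiability trouble).
* The mixed-model p-values use the normal approximation; at small sample
  sizes a t-reference would be more accurate.
* The generator's clamping produces a small excess of exact 0/1 beta
  values that a logit-scale model would avoid.
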