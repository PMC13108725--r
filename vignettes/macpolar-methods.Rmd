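---
title: "Scoring macrophage polarization capacity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring macrophage polarization capacity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macpolar)
```

## The problem

Tumor cells condition their microenvironment partly by reprogramming
macrophages. A standard in vitro readout applies tumor-conditioned media
(TCM) from a panel of cancer cell lines to primary monocyte-derived
macrophages from a few blood donors and measures the cytokines and
chemokines the macrophages then secrete (multiplexed immunoassays and
ELISA, pg/mL). The scientific questions are: which cell lines most strongly
polarize macrophages, analyte by analyte; how much of the measured variation
is donor idiosyncrasy rather than tumor-cell biology; and which tumor-cell
transcripts track the polarization phenotype, making them candidate
mechanisms or biomarkers.

`macpolar` implements that analysis chain end to end — robust phenotype
scoring, donor variance decomposition, transcriptome association screens,
quartile differential expression, gene set enrichment, permutation
overrepresentation tests, and the downstream mixed models for exosome
fractionation and chemokine dose–response experiments — together with a
synthetic-data module that generates the whole study design with known
ground truth, so every stage can be validated by parameter recovery rather
than by eye.

## Robust phenotype scoring

Concentrations across analytes and donors differ by orders of magnitude and
are strongly right-skewed, so the phenotype statistic is the **modified
z-score**

$$z_i = 0.6745 \, \frac{x_i - \mathrm{median}(x)}{\mathrm{MAD}(x)},
\qquad \mathrm{MAD}(x) = \mathrm{median}_i\,|x_i - \mathrm{median}(x)|,$$

computed per analyte over the pooled "dataset" of all observations of that
analyte (all donors, all cell lines, and the untreated control wells). The
MAD here is the raw median absolute deviation; 0.6745 is the multiplicative
consistency constant, so a score of +0.6745 means the observation sits
exactly one MAD above the dataset median and scores are comparable to
classical z-scores under normality without being driven by outliers. No
observations are excluded as outliers — with three donors every point
carries real biological information.

Two deliberately exposed choices:

* **Pooling.** Whether the "dataset" is pooled across donors (default) or
  formed per donor is genuinely open; pooled is the default because control
  means are displayed on the same z-scale as treated wells, which requires
  a common reference distribution. `score_observations(pooling =
  "per_donor")` provides the alternative.
* **Zero MAD.** If more than half the observations are identical the MAD
  is zero; the fallback rescales by the mean absolute deviation with the
  analogous constant 0.7979, or the caller can request a hard failure.

**LLoQ handling.** Each analyte has an assay lower limit of quantification.
An analyte is dropped when more than 40% of its observations are censored:
any threshold strictly between the most-censored retained analyte and the
least-censored excluded analyte reproduces the canonical 7-of-15 retention
pattern of such panels, and 0.40 is the midpoint of that feasible band; it
is exposed as `max_censored_fraction`. Sporadic censored values in retained
analytes are imputed at LLoQ/2 by default — standard practice for
left-censored assay data, not a choice the source experiments dictate —
with `lloq` and `drop` as alternatives.

**Aggregation and quartiles.** Per-observation scores are averaged across
donors per cell line (mean ± SEM). For each analyte the cell lines are
split into top and bottom quartiles of size $\lceil n/4 \rceil$ (6 of 23
lines with expression data; 7 of 25), with ties at the boundary broken by
lexicographic unit id so the grouping is reproducible run to run.

## Donor variance: random-intercept models and ICC

How repeatable is an analyte across donors? For each analyte we fit the
Gaussian random-intercept model

$$y = X\beta + u_{\mathrm{donor}} + \varepsilon, \qquad
u \sim N(0, \sigma_d^2), \quad \varepsilon \sim N(0, \sigma_e^2),$$

with treatment (cell line) as the fixed effect, and report the intraclass
correlation $\mathrm{ICC} = \sigma_d^2 / (\sigma_d^2 + \sigma_e^2)$ — the
fraction of residual variance attributable to donor identity after
accounting for treatment.

The fitter profiles $\beta$ and $\sigma_e^2$ out in closed form by
generalized least squares and maximizes the one-dimensional profile
likelihood over $\log\theta$, $\theta = \sigma_d^2/\sigma_e^2$, with the
$\theta = 0$ boundary always evaluated; a unit test verifies the optimum
against a 1000-point grid search to within $10^{-6}$ log-likelihood units,
and another verifies log-likelihood, coefficients and ICC against
`lme4::lmer`. ML is the default so the likelihood-ratio test comparing
models with and without the random intercept is valid; REML is available
for variance reporting (and, on balanced one-way designs, reproduces the
ANOVA moment estimator exactly). The headline LRT p-value uses the plain
$\chi^2_1$ reference; because $\sigma_d^2 = 0$ sits on the boundary of the
parameter space that convention is conservative, and the half-mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ p-value is reported alongside.

Standard errors, contrasts and the fixed-effect F-test use the
degrees-of-freedom-corrected residual variance (the ML plug-in would be
anti-conservative) with containment denominator df
$n - \mathrm{rank}(X) - (n_{\mathrm{donors}} - 1)$ — for a 63-observation,
3-condition, 3-donor fractionation design this yields the familiar
F(2, 58) shape. Satterthwaite or Kenward–Roger corrections are out of
scope; the containment choice is documented rather than hidden. Post-hoc
pairwise contrasts use the Tukey–Kramer studentized-range adjustment at
that df. Nakagawa's marginal and conditional $R^2$ are computed from the
variance of the fixed-effect predictions and the two variance components.
Model diagnostics (residual vs fitted, normal Q–Q) are available via
`autoplot()` on any fit but never gate results.

## Association screens

Cytokine–cytokine structure and the transcriptome screen both use
Spearman's rank correlation on donor-averaged per-unit scores (mid-ranks
under ties). For small tie-free samples an exact two-sided p-value is
computed by enumerating all $n!$ rank permutations; otherwise the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation is used. Pairwise analyte
correlations are BH-adjusted across the $\binom{k}{2}$ pairs. The
genome-wide screen correlates every non-constant gene's expression with one
analyte's scores and reports both BH-adjusted p-values and Storey q-values
with $\hat\pi_0$ estimated at $\lambda = 0.5$; the q-value is the default
for the gene screen because, with thousands of mostly-null genes,
estimating the null proportion recovers power that plain BH concedes. This
is a deliberate, documented divergence from density-based FDR estimators
that fit a null to the statistic distribution; the thresholds and call
semantics are preserved while exact q-values on any given dataset will
differ.

## Quartile differential expression

The DE stage between top- and bottom-quartile stimulator groups is a
self-contained negative-binomial Wald pipeline with the standard call
semantics:

1. **Filter**: drop genes with total count ≤ 3 across samples or detected
   in fewer than half the samples (exactly half is kept). The total-count
   reading of the "≤ 3 counts" rule is used because a per-sample reading
   would be subsumed by the detection rule.
2. **Size factors**: median-of-ratios over all-positive reference genes,
   with the median taken on the log-ratio scale; a positive-entry
   (poscounts-style) fallback covers matrices with no all-positive gene.
   A test pins the implementation to `DESeq2::estimateSizeFactorsForMatrix`
   on a shared fixture.
3. **Dispersion**: per-gene method-of-moments
   $\hat\alpha = \max(\alpha_{\min}, (s^2-\bar\mu)/\bar\mu^2)$ on
   normalized counts, moderated 50/50 in log space toward a robust
   $a + b/\bar\mu$ mean–dispersion trend with the decreasing shape
   enforced. This fixed blend replaces the Cox–Reid empirical-Bayes
   machinery of full DE packages — simpler, and adequate for the 6-vs-6
   designs the stage targets.
4. **Wald tests**: per-gene log-link NB GLM `[intercept, group]` with
   log-size-factor offsets, fitted by IRLS vectorized across genes. A
   ridge penalty of $10^{-6}$ on the group coefficient plus a floor of 0.5
   on the fitted means inside the weights (and a matching floor on the
   working response) keeps the fold change and its standard error finite
   when one group is observed entirely at zero — such genes get a large
   but bounded |log2 FC| and a small p-value instead of a numerical
   failure. Convergence is declared on the relative deviance change
   ($<10^{-8}$); genes not converged after 100 iterations are flagged and
   their p-values withheld.
5. **Shrinkage**: normal-prior empirical Bayes. The prior variance
   $\tau^2$ matches the excess of the observed squared fold changes over
   the average squared SE (floored at $10^{-4}$), and the posterior mean
   $\hat\beta \tau^2/(\tau^2 + \mathrm{se}^2)$ shrinks imprecise estimates
   hardest. This replaces adaptive-mixture shrinkage; a single global
   normal prior is more conservative on strong outlying signals, which is
   documented behaviour, not a defect.
6. **Calls**: BH across tested genes; significant iff adjusted p ≤ 0.05
   and |shrunken log2 FC| ≥ 1. Whether the fold-change threshold applies
   to the shrunken estimate or the MLE is configurable; shrunken is the
   default.

## Pre-ranked gene set enrichment

Gene sets (GMT input) are scored on the shrunken-fold-change ranking by
the weighted Kolmogorov–Smirnov running sum (weight exponent $p = 1$;
ties in the metric broken by gene id for determinism). The null is **gene
permutation**: random member sets of the same size scored on the fixed
ranking — appropriate because the input is a pre-ranked list, there is no
sample-level exchangeability left to exploit. NES divides the ES by the
mean |null ES| of matching sign; the permutation p-value uses the add-one
estimator over same-sign permutations. Both the BH-adjusted permutation p
(flagging `enriched` at p ≤ 0.25 and |NES| ≥ 1) and a classic
tail-proportion FDR q from the pooled sign-normalized null are reported,
since the two conventions coexist in practice. An enumeration test checks
the permutation p against the exact distribution over all
$\binom{N}{2}$ placements of a 2-gene set, and the ES is pinned to
`fgsea` on a shared fixture.

## Overrepresentation permutation test

Whether any cell line (or tumor type) is systematically a top- or
bottom-quartile member across analytes is tested by permutation: the
observed statistic is the number of quartile memberships across analytes
(for a type: total quartile slots occupied by its lines), and the null
redraws each analyte's quartile set uniformly and independently. Because
the hit count of a uniform size-$k$ draw within a fixed $m$-unit focal
subset is hypergeometric, the null is sampled directly from that
distribution and summed over analytes — distributionally identical to
drawing the sets, and checked against exhaustive enumeration on a tiny
instance. P-values use the add-one estimator (minimum $1/(B+1)$, never
zero) with BH within each family; defaults are 20,000 permutations for
cell lines and 5,000 for tumor-type groupings. The statistic itself is a
reconstruction — the simplest count consistent with how such results are
reported — and both directions are tested separately.

## The synthetic-data generator

The generator exists so that recovery, calibration and power claims are
testable. It emulates the study design, not any particular dataset:

* **Secretome**: 3 donors × 25 cell lines (+ one control well) × 10
  analytes, 7 quantifiable and 3 constructed to fail the censoring filter.
  Concentrations are log10-normal:
  $c = 10^{\mu_a + \delta_{d,a} + \lambda_a s_{c,a} + \varepsilon}$, with a
  latent standard-normal polarization score $s$ per cell line (analytes
  may share a latent factor via `latent_group`, which is how correlated
  analyte pairs are planted). Log-normality reflects that concentrations
  are positive and non-normal; the latent score enters linearly on the log
  scale so rank-based recovery is monotone by construction.
* **Donor effects are tuned, not merely drawn**: the donor intercepts are
  standardized to sample mean 0 and sample sd equal to the target
  $\sigma_d$, so each dataset realizes its target ICC
  $\sigma_d^2/(\sigma_d^2+\sigma_e^2)$ in the generating effects. With 3–5
  donors, unstandardized draws would make the realized donor variance — and
  therefore any recovery assessment — essentially a draw from a 4-df
  chi-square; tuning removes that irreducible ambiguity. Target ICCs span
  0.096–0.754 across the ten analytes, the donor-repeatability range such
  panels report.
* **Expression**: 2000 genes × 25 lines; 5 planted genes per analyte with
  log2 mean $b_0 + 1.5\, s_{c,a}$, baselines $b_0 \sim N(5, 2)$ (log2),
  negative-binomial counts at dispersion 0.05 scaled to library sizes
  drawn from 0.5–1.5 million. TPM uses unit gene lengths (counts
  proportional) because the rank screen is invariant to per-gene length
  factors. The planted effect of 1.5 log2-units per latent SD makes the
  highest-loading analyte's planted genes recoverable but leaves
  lower-loading analytes genuinely hard — the screen's operating range,
  not a guaranteed win.
* **Fractionation**: balanced donors × lines × 3 media fractions with a
  1000 pg/mL exosome-only effect by default, donor SD 300 and residual SD
  350 pg/mL around a 1500 pg/mL baseline — noise at roughly a quarter of
  the effect, typical for ELISA-scale replicates.
* **Dose–response**: 4 donors × 4 doses (0–5 ng/mL) on the inverse scale,
  $1/y = a + b\,\mathrm{dose} + u + \varepsilon$ with $a = 1/7.42$ and $b$
  set so the mean response at 5 ng/mL is 23.02 pg/mL; responses are kept
  positive by redrawing the residual. Donor and residual SDs default to
  0.003 on the inverse scale, chosen once so that back-transformed
  predicted means are estimable to within ~5% at this design size — the
  regime in which an inverse-transformed mixed model is the right tool.

What the generator does **not** emulate: assay-specific heteroscedasticity,
plate effects, donor-by-treatment interactions, correlated gene–gene
structure beyond the shared latent factors, and length or GC bias in
counts. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated model, not robustness to every
failure mode of real panels.

## Reproducibility and numerical choices

Every stochastic stage takes an explicit seed; `run_pipeline()` derives
per-stage seeds from one master seed and records it in each output header
and the JSON manifest, and rerunning with the same seed reproduces all
artifacts byte for byte. Results tables serialize floats at 10 significant
digits. Test problem sizes are chosen to keep the full suite under a few
minutes on one core: 100 seeds for ICC recovery, 20 for screen recovery
and DE power, 200–1000 permutations for calibration loops, 20,000 where a
closed-form null mean is being matched to within 2%.

## Known limitations

* The DE and enrichment stages reproduce the semantics, thresholds and
  qualitative behaviour of the full DESeq2/ashr and fgsea-style machinery,
  not their numerical output on real data.
* One random-intercept grouping only; no crossed or nested random
  structures, no generalized LMMs.
* Containment df is an approximation; for very unbalanced designs a
  Satterthwaite correction would differ.
* The q-value implementation fixes $\lambda = 0.5$ rather than selecting
  it by spline; with few tests (e.g. 21 analyte pairs) BH is the better
  default and is used there.
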