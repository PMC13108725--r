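# macpolar

Screening tumor cell lines for macrophage-polarization capacity.

Tumor-conditioned media (TCM) experiments apply the secretome of a panel of
cancer cell lines to primary monocyte-derived macrophages from a few blood
donors, then measure the cytokines and chemokines those macrophages secrete.
`macpolar` turns such panels into ranked, statistically validated results:

* **Robust phenotype scoring** — per-analyte modified z-scores
  `0.6745 * (x − median) / MAD`, with lower-limit-of-quantification (LLoQ)
  retention rules, censored-value imputation, donor averaging (mean ± SEM)
  and top/bottom quartile classification of cell lines.
* **Donor variance decomposition** — random-intercept Gaussian mixed models
  fitted by 1-D profile likelihood, intraclass correlation
  ICC = σ²_donor / (σ²_donor + σ²_resid), likelihood-ratio tests,
  Tukey–Kramer post-hoc contrasts, fixed-effect F-tests and Nakagawa R².
* **Transcriptome association** — genome-wide Spearman screens of gene
  expression against polarization scores, with BH-adjusted p-values and
  Storey q-values; pairwise cytokine correlation matrices.
* **Quartile differential expression** — a self-contained median-of-ratios /
  negative-binomial-Wald / empirical-Bayes-shrinkage stage with the standard
  dual threshold (BH-adjusted p ≤ 0.05 and |log2 FC| ≥ 1).
* **Pre-ranked GSEA** — weighted Kolmogorov–Smirnov enrichment scores, NES
  and FDR from a gene-permutation null, GMT input.
* **Overrepresentation permutation tests** — are any cell lines or tumor
  types systematically in the top/bottom quartiles across analytes?
* **Synthetic-data module** — generates the whole study design (donors ×
  cell lines × analytes with log-normal responses and tuned donor ICCs,
  linked NB count matrices with planted genes, fractionation and
  dose–response tables) with known ground truth, so every stage is validated
  by parameter recovery.

## Worked example

```r
library(macpolar)

scenario <- make_default_scenario(seed = 42)   # 3 donors x 25 lines x 10 analytes
sim      <- simulate_cytokine_experiment(scenario)
scores   <- score_polarization(sim$table, sim$lloq_map, control_units = "CTRL")
scores
#> <polar_scores>
#>   analytes retained: 7 of 10
#>   units scored: 26
#>   pooling: pooled
```

Three of the ten simulated analytes fail the 40% censoring rule (here IFNg,
71.8% of observations below its LLoQ) and seven are scored. The strongest
VEGF-stimulating cell lines, averaged over donors:

```r
dplyr::arrange(subset(scores$per_unit, analyte == "VEGF" & !is_control), -mean_z)
#> # A tibble: 25 x 6
#>   unit  analyte mean_z   sem n_donors is_control
#> 1 L12   VEGF     16.6   8.64        3 FALSE
#> 2 L09   VEGF     10.1   7.48        3 FALSE
#> 3 L25   VEGF      7.44  2.90        3 FALSE
```

L12's mean modified z-score of 16.6 means its TCM drove macrophage VEGF
secretion 16.6/0.6745 ≈ 25 MADs above the panel median. How much of the
raw variation is donor identity rather than tumor biology?

```r
d <- subset(sim$table, analyte == "VEGF" & unit != "CTRL")
d$y <- log10(d$concentration)
fit <- fit_random_intercept(d, y ~ unit, group = "donor")
glance(fit)[c("icc", "loglik")]
#>     icc loglik
#> 1 0.580   25.0
lrt_random_intercept(fit)
#>    chi2    df        p p_boundary
#> 1  54.3     1 1.73e-13   8.65e-14
```

The fitted ICC of 0.58 (generator target 0.614) says more than half the
treatment-adjusted variance is donor-level; the likelihood-ratio test
against plain least squares confirms the donor intercept belongs in the
model. Which genes track the VEGF phenotype?

```r
expr   <- simulate_expression_bundle(scenario, sim$truth)
screen <- gene_score_screen(expr$bundle, scores, "VEGF")
head(screen, 3)
#> # A tibble: 3 x 7
#>   gene    rho     n    p_raw p_adj_bh  q_value matrix_used
#> 1 g0005 0.971    25 9.41e-16 1.88e-12 1.88e-12 normalized
#> 2 g0004 0.965    25 6.41e-15 6.41e-12 6.40e-12 normalized
#> 3 g0001 0.959    25 4.08e-14 2.72e-11 2.72e-11 normalized
```

The top three hits (ρ = 0.96–0.97, q < 1e-11) are all genes the generator
planted on the VEGF latent score (`expr$truth$planted_genes`) — the screen
recovers the ground truth. `quartile_de()`, `preranked_gsea()`,
`overrepresentation_test()`, `dose_response_fit()` and
`pairwise_contrasts()` continue the chain, and `run_pipeline(out_dir)`
executes everything and writes CSV artifacts plus a JSON manifest keyed to
one master seed.

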