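# m6apattern

Discovery and scoring of N6-methyladenosine (m6A) regulation patterns in
bulk tumor transcriptomes, and their association with immune context,
progression-free survival (PFS) and immunotherapy response.

## The problem and who this is for

m6A is the most abundant reversible mRNA modification, controlled by writer
methyltransferases (WTAP, KIAA1429, CBLL1, RBM15, RBM15B, ZC3H13, METTL3,
METTL14), eraser demethylases (FTO, ALKBH5) and reader proteins (ELAVL1,
FMR1, HNRNPA2B1, HNRNPC, IGF2BP1-3, LRPPRC, RBMX, YTHDC1-2, YTHDF1-3). In
tumor cohorts the joint expression of this 24-gene panel stratifies patients
into *m6A regulation patterns* with distinct immune microenvironments and
outcomes. This package gives computational oncologists a tested, fully
reproducible implementation of that analysis:

1. **Pattern discovery** — Gaussian-mixture model-based clustering of the
   panel (`fit_model_clusters()`), with covariance-family sweep, BIC
   selection, and a Kruskal-Wallis/Dunn *highest-median-lowest* cluster
   characterization (`characterize_clusters()`).
2. **Immune context** — per-sample signature scoring by ssGSEA
   (`ssgsea_score()`, `score_matrix()`) or ingestion of published
   signature tables (`ingest_signature_table()`).
3. **m6Ascore** — per-pattern differential expression with a moderated t
   (`cluster_degs()`), intersection into the co-expressed gene (CEG) set
   (`intersect_cegs()`), then PCA: for sample *i*,
   `m6Ascore_i = PC1_i + PC2_i`, the sum of the first two principal-
   component projections of standardized CEG expression
   (`compute_m6ascore()`).
4. **Survival** — dichotomization at the maximally selected log-rank
   statistic (`maxstat_cutpoint()`, `dichotomize()`), Kaplan-Meier,
   log-rank and univariate Cox (`km_estimate()`, `logrank_test()`,
   `univariate_cox()`).
5. **Moderator screen** — the resampling multiple co-expression analysis
   (`run_multicoexp()`): 100 draws of 60% of the cohort; per draw the
   Spearman r1 between marker regulators and signature scores plus every
   CEG's median; per (regulator, signature, CEG) triple the across-replicate
   Spearman correlation of medians with r1.
6. **Immunotherapy response** — contingency tests, ROC/AUC with DeLong
   variance and paired DeLong comparison (`contingency_test()`,
   `roc_auc()`, `delong_compare()`).

A synthetic cohort generator with planted ground truth
(`generate_cohort()`, `generate_moderator_scenario()`) emulates the
statistical structure the analysis assumes — three patterns of 157/36/212
samples, marker shifts, cluster-linked CEGs and signatures, proportional-
hazards PFS and score-linked response — so every stage is testable without
external data. `run_pipeline()` executes everything end to end from one
seed.

## Worked example

```r
library(m6apattern)

report <- run_pipeline(config = cohort_config(), seed = 7)
report
#> m6A regulation-pattern analysis report
#>   samples: 405, genes: 614, seed: 7
#>   regulation patterns (K=3, EEI): sizes 212/37/156
#>   CEGs: 61
#>   high vs low m6Ascore: log-rank chi2 152.96 (p 3.92e-35), HR per score unit 0.884
#>   response rate low/high score: 0.80 / 0.25 (chi2 p 4e-13), AUC (low=responder) 0.722
```

Reading the output: the mixture model recovers three patterns (sizes match
the planted 212/36/157 up to label order); 61 genes pass the per-pattern
DEG rule (p < 0.05, |fold change| > 2) in all three patterns and form the
CEG set (the 54 planted CEGs plus signature genes that genuinely track all
three patterns); the m6Ascore built from them separates survival sharply
(hazard ratio < 1: high score, better PFS), while the *low*-score group has
the higher immunotherapy response rate (80% vs 25%) and the score predicts
response with AUC 0.72 when low values are scored as response-positive —
the central contrast between prognosis and ICI benefit.

Pieces compose tidyverse-style:

```r
cohort <- generate_cohort(cohort_config())
fit    <- fit_model_clusters(cohort$expression, seed = 1)
glance(fit)                      # K, family, loglik, BIC
sigs   <- score_matrix(cohort$expression, cohort$gene_sets)
degs   <- lapply(1:3, \(k) cluster_degs(cohort$expression, fit$labels, k))
cegs   <- intersect_cegs(degs)
scores <- compute_m6ascore(cohort$expression[cegs$members, ]) |>
  dichotomize(cohort$clinical)
plot_km(km_estimate(dplyr::inner_join(scores, cohort$clinical,
                                      by = "sample_id"),
                    group_col = "group"))
```

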