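---
title: "Modeling m6A regulation patterns, the m6Ascore, and immune context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling m6A regulation patterns, the m6Ascore, and immune context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6apattern)
```

## The analysis in one paragraph

N6-methyladenosine (m6A) is the most common reversible mRNA modification,
deposited by writer methyltransferases, removed by eraser demethylases and
recognized by reader proteins. In bulk tumor transcriptomes the joint
expression of a 24-gene regulator panel (8 writers, 2 erasers, 14 readers)
stratifies patients into a small number of *m6A regulation patterns* that
differ in immune microenvironment and outcome. `m6apattern` implements that
analysis end to end: Gaussian-mixture model-based clustering of the panel,
Kruskal–Wallis/Dunn characterization of the clusters, per-sample immune
signature scoring by ssGSEA, a moderated-t screen for genes differentially
expressed in every pattern (whose intersection is the co-expressed gene set,
CEG), a per-sample **m6Ascore** defined as the sum of the first two
principal-component projections of CEG expression, survival dichotomization
of the score by the maximally selected log-rank statistic, a resampling
co-expression screen for CEGs that *moderate* regulator–signature
correlations, and evaluation of the score against immunotherapy response.

## Model-based clustering of the regulator panel

`fit_model_clusters()` fits Gaussian mixtures by EM to the per-gene
z-scored panel expression (samples × 24 genes). Six covariance families are
swept — spherical, diagonal and full, each shared or per-cluster — and the
fit minimizing `BIC = -2 log L + npar log n` is returned. EM is started from
two deterministic initializations (k-means with 10 restarts; Ward
agglomeration, the classic model-based-clustering start) plus k-means++
seeded random starts, because the dominant failure mode on realistic effect
sizes is a local optimum that merges the smallest pattern; six starts per
family were sufficient in every seeded experiment we ran. The E-step uses
log-sum-exp, covariances carry a 1e-6 ridge, and a cluster collapsing below
two effective members triggers a restart. The per-iteration log-likelihood
trace is stored so monotone ascent is testable, responsibilities are a
proper distribution per sample, and argmax ties break to the lowest cluster
index for determinism. K is fixed at 3 by default — the three-pattern design
— but is an ordinary argument.

Cluster characterization follows the highest/median/lowest rule: per
feature, a Kruskal–Wallis test, then (if p < 0.05) Dunn pairwise z tests
with tie correction, Holm-adjusted across the three comparisons. A cluster
is "highest" only when its median exceeds every other cluster's and all its
pairwise tests are significant; "lowest" symmetrically; "median" when
significantly between; otherwise "ns". At most one cluster per feature can
be highest, one lowest.

## ssGSEA

`ssgsea_score()` ranks a sample's genes by expression (ties broken by gene
ID so scores are platform-independent) and accumulates the difference
between the weighted in-set ECDF and the unweighted out-of-set ECDF over all
rank positions, weighting in-set steps by `|N - i + 1|^alpha`. `alpha`
defaults to 0.25, the original ssGSEA convention; at `alpha = 0` the score
is a pure rank statistic (invariant under monotone transforms, exactly
negated by rank reversal). Scores are not normalized by default; a min–max
`normalize` flag rescales each signature to [0, 1] across samples.
Precomputed signature tables (e.g. published pan-immune CIBERSORT-derived
scores) can be ingested instead via `ingest_signature_table()`; which source
was used is recorded in the run manifest.

## DEGs, CEGs and the m6Ascore

`cluster_degs()` tests one pattern against the rest per gene with a
moderated t: ordinary pooled-variance statistics with gene variances shrunk
by empirical Bayes, `s2_tilde = (d0 s0^2 + d s^2) / (d0 + d)`, the prior
`(d0, s0^2)` moment-matched on the log-variance scale (digamma/trigamma
inversion). A gene passes at `p < 0.05` and linear fold change above 2
(`|log2 FC| > 1`), both thresholds exposed. P-values are unadjusted to match
that rule; BH adjustment is available but off by default. One-vs-rest is
the default contrast (per-cluster DEG lists) — note that the "rest" pools
the two other patterns, so its variance is a mixture variance; planted
shifts must be large enough to clear both thresholds under that pooling.
The CEG set is the intersection of the per-pattern passing lists.

`compute_m6ascore()` standardizes the CEGs, runs PCA on the sample × CEG
matrix, and scores each sample as the sum of its projections on the first
two components. Because eigenvector sign is arbitrary, each component is
oriented so its largest-magnitude gene loading is positive; the orientation
is recorded. Standardization before PCA is on by default and exposed as a
flag. Zero-variance genes are dropped with a warning; fewer than two
usable CEGs is an error.

`dichotomize()` splits the score at the maximally selected log-rank
statistic: every observed score value that leaves at least
`min_group_frac` (default 0.1) of samples on each side is scored by the
two-group log-rank chi-square, and the argmax (ties to the smaller value)
becomes the cutpoint, low group = score ≤ cutpoint. No multiple-testing
correction of the selected p is attempted; the reported p is labeled
descriptive, because the cutpoint is chosen to maximize exactly that
statistic. A subtlety worth knowing: when all events concentrate in one
tail, the variance-weighted statistic can peak strictly inside that tail
rather than at the visual boundary between event-rich and censored samples
— the exhaustive scan, not intuition, defines the cutpoint.

## Survival machinery

Kaplan–Meier, log-rank and univariate Cox go through the survival package
(`survfit`, `survdiff`, `coxph` with Breslow ties — ties are rare here since
simulated times are continuous); the test suite re-derives each from first
principles (risk-set products, O−E/V sums, golden-section maximization of
the Breslow partial likelihood) and checks agreement. The cutpoint scan uses
an internal vectorized two-group log-rank statistic so that scanning ~400
candidates costs milliseconds; it is validated against a survdiff-based
exhaustive scan.

## The resampling co-expression screen

`run_multicoexp()` implements the three-step procedure: draw 60% of the
cohort without replacement; record the Spearman correlation r1 between each
of the seven marker regulators (METTL14, ZC3H13, IGF2BP1, KIAA1429,
HNRNPA2B1, IGF2BP3, YTHDF1) and each signature score — kept only when its
p < 0.05, the relevance rule — together with every CEG's median expression;
repeat 100 times; then per (regulator, signature, CEG) triple correlate the
medians with the r1 values across replicates. Replicates with a filtered-out
r1 are dropped pairwise, and triples with fewer than 10 contributing
replicates, or a degenerate median vector, are flagged rather than scored.
A `filter_r1 = FALSE` flag retains all r1 values for sensitivity analysis;
no multiplicity correction is applied across triples by default. Note that
median invariance under monotone transforms is exact only when the
subsample size is odd (the median is then an order statistic); at even
sizes the midpoint average can reorder medians marginally.

Small-sample Spearman p-values (n ≤ 8, no ties) come from full permutation
enumeration; beyond that the t approximation is used. Full enumeration to
n = 12 would need 479 million permutations per test, so 8 is where
exactness stops being worth it.

## Response evaluation

Responders are CR/PR versus SD/PD (the standard RECIST collapse;
configurable). Group-by-response tables are tested by chi-square without
continuity correction (textbook statistic, transpose-invariant) or Fisher's
exact test for sparse 2×2 tables. `roc_auc()` computes the trapezoid AUC,
which equals the Mann–Whitney probability with half-weight ties, with
DeLong structural-components variance; `positive_direction = "lower"`
scores the analysis' own direction (low m6Ascore predicts response)
directly. `delong_compare()` tests two correlated AUCs; comparing a score
with itself is a flagged degenerate case returning difference 0 and p = 1.
Confidence intervals move to the logit scale when the AUC is within 0.1 of
the boundary so they stay inside [0, 1].

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code that emulates the
statistical structure the analysis assumes — it is how every stage is
exercised without external downloads. Defaults, chosen once:

- **Design**: three patterns of 157/36/212 samples (405 total); i.i.d.
  Gaussian noise of 0.5 log2 units on every gene.
- **Regulators**: ±1 log2 shifts planting the marker profile — METTL14 and
  ZC3H13 highest in pattern 3 and lowest in pattern 1; KIAA1429 and
  HNRNPA2B1 highest in pattern 2 and lowest in pattern 3; IGF2BP1, IGF2BP3
  and YTHDF1 lowest in pattern 3.
- **CEGs**: 54 genes ordered pattern 2 < 1 < 3, each shifted by 2 log2
  units times a per-gene multiplier in [0.8, 1.2]. The factor 2 is a
  designed consequence of the one-vs-rest DEG rule: the middle pattern's
  contrast is attenuated by (212 − 36)/248 ≈ 0.71, so unit shifts cannot
  clear |log2 FC| > 1.
- **Signatures**: three helper-T-cell sets of 12 genes; Th1 and Th17
  elevated in pattern 3, Th2 elevated and Th17 depressed in pattern 2, at
  1.5 log2 units. The 1.5 is again a rank-interference consequence: ssGSEA
  is rank-based and the strong CEG shifts reshuffle a ~54-gene block of
  ranks per cluster, which unit signature shifts do not survive.
- **Outcome**: the *true score* of a sample is the oracle PCA score of the
  noiseless CEG means (so it takes one value per pattern, ordered
  2 < 1 < 3). PFS is exponential with hazard `h0 exp(-0.7 z)` (z the
  standardized true score — the raw score scales with sqrt(|CEG|), so the
  per-unit coefficient is defined on the z scale), h0 = log(2)/1000 days.
  Censoring is an independent exponential whose rate is solved numerically
  so the marginal censored fraction is 0.3. Response is Bernoulli with
  logit `qlogis(0.3) - 1.0 z`: low score responds, the ICI direction.
- **Clinical extras**: immune subtype C3 frequencies of 69/33/88% per
  pattern, T/N/M stages, Gleason and PSA; a `stage_effect` knob links
  T stage to pattern (0, i.e. independent, by default).

`generate_moderator_scenario()` plants a moderated link for the screen:
signature genes become
`base + loading · R_c · (offset + strength · M_c) + main_effect · M_c + noise`,
with R_c and M_c the centered regulator and moderator. The product term
makes the within-subsample R–signature correlation increase with the
subsample median of M (what the screen detects); the direct `main_effect`
term (default equal to `strength`) keeps the signature elevated under high
moderator within *both* regulator strata — the pattern a median-split
contrast displays — which a pure product cannot do because it flips sign
with the centered regulator. The strong preset (strength 1.5, offset 0.6,
gene noise 0.3) comes from requiring the across-replicate spread of the
subsample median of M (sd ≈ 1.25 sd(M)/√(0.6 n)) to move r1 by more than
r1's own sampling noise (≈ 1/√(0.6 n)).

What the generator does **not** emulate: batch effects, heavy-tailed or
count-level noise, correlated background genes, gene-gene co-expression
beyond the planted structure, informative censoring, or cohort
heterogeneity between discovery and immunotherapy populations. Tests
passing on these cohorts therefore certify the *procedures* — their
numerics, calibration and direction recovery — not robustness of the
biology to real-data pathologies.

## Numerical and design choices

- BIC is reported in the "smaller is better" convention
  (`-2 log L + npar log n`).
- Duplicate gene rows collapse by mean on load; duplicate samples error.
  Rows with missing values are dropped and counted. Expression is assumed
  log2; `log2_transform` applies `log2(x + 1)` for counts.
- Cohort joins are strictly by sample ID; every loader and the pipeline
  report the realized post-join cohort size, since public cohorts routinely
  lose samples to incomplete annotation.
- One global pipeline seed derives per-stage seeds
  (`seed + 1000 × stage`), so a rerun is bit-identical and individual
  stages are independently reproducible.
- Default problem sizes (405-sample cohorts, 100 screen replicates, 50
  consensus resamples, 100-seed replication loops in the tests) keep a full
  pipeline run under ~10 s and the whole test suite in minutes on one CPU.

## Known limitations

- The maxstat p-value is selection-biased and deliberately uncorrected
  (no Lausen-type adjustment), matching descriptive use of the cutpoint.
- The co-expression screen is correlational; no causal mediation model is
  fitted, and the pairwise-drop treatment of filtered replicates is one of
  several defensible conventions (the retain-all alternative is a flag).
- The screen's p-values are anti-conservative under the null: medians and
  r1 are computed from the same overlapping subsamples of one fixed
  cohort, which induces a spurious per-cohort median-r1 association of
  order 1/sqrt(n) and makes the replicate-level correlation test reject at
  roughly 13% rather than 5% at nominal alpha = 0.05 (with independent
  replicates the same test is calibrated; our suite verifies both
  measurements). Treat reported hits as a screen to rank candidates, not
  as calibrated inference.
- One-vs-rest is the default DEG contrast; pairwise-contrast DEG lists are
  a plausible alternative reading and can be assembled from
  `cluster_degs()` calls on subsets.
- `K = 3` is a design default, not an inference; no automatic K selection
  by consensus CDF is performed.
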