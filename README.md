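# cdgrs — case-control genetic risk scores for SNP panels

`cdgrs` is an R package for the complete statistical pipeline of a
small-panel case-control genetic association study, built around the
published 22-SNP Crohn's disease susceptibility panel genotyped in 369
Ashkenazi Jewish cases and 503 controls. It is aimed at statistical
geneticists and epidemiologists who want each stage of such a study —
quality control, association, risk-score construction, classification
evaluation — as tested, reusable functions rather than a one-off SAS/Excel
workflow, together with a cohort simulator so the whole pipeline runs and
is testable without access to the original genotypes.

## What it computes

* **Genotype QC** — Hardy-Weinberg equilibrium χ² tests (controls by
  default), and pairwise linkage disequilibrium from unphased genotypes by
  EM over the double-heterozygote phase ambiguity, reporting Lewontin's
  *D′* = *D*/*D*<sub>max</sub> and *r²* = *D²*/(p<sub>A</sub>q<sub>A</sub>p<sub>B</sub>q<sub>B</sub>).
* **Association** — allelic odds ratios on 2×2 allele-count tables with
  Wald intervals, OR = ad/bc, SE(ln OR) = √(1/a+1/b+1/c+1/d), with flagged
  Haldane-Anscombe correction for zero cells; carriage (≥1 risk allele) and
  compound heterozygote/homozygote (≥2 risk alleles) tests; multivariate
  logistic regression by IRLS with step-halving, genotype-indicator and
  log-additive codings, and separation flagged rather than fatal; analytic
  and Monte-Carlo power for the allelic test.
* **Risk scores** — the allele-count score Σ c<sub>i</sub> and the weighted
  score Σ w<sub>i</sub>c<sub>i</sub> (default weights: multivariate
  log-additive ORs, protective SNPs flipped to their major allele with
  reciprocal weights); inclusive-cutoff classification metrics
  (sensitivity, specificity, PPV, NPV, accuracy, OR per cutoff), ROC
  curves with tie-aware trapezoidal AUC, and score distributions.
* **Synthetic cohorts** — a retrospectively ascertained simulator: HWE
  source population (optional pairwise LD at a target *D′*), disease from a
  log-additive logistic model with the intercept calibrated to a target
  prevalence, rejection sampling to fixed case/control quotas.
* **Orchestration** — `run_pipeline()` writes a deterministic TSV/JSON
  report bundle; a thin CLI lives in `inst/scripts/grs.R`.

## Worked example

```r
library(cdgrs)

sim <- simulate_reference_cohort(seed = 42)   # 22 SNPs, 369 cases / 503 controls
gm <- sim$genotypes; ph <- sim$phenotypes

allelic_test_snp(gm, ph, "rs2066847")
#> rs2066847: OR = 4.27 (2.51-7.24), p = 7.88e-08

carriage_test(gm, ph, nod2_coding_panel(), label = "NOD2 carriage")
#> NOD2 carriage: [carriage] OR = 3.24 (2.35-4.48), p = 9.81e-13

cs <- count_score(gm, significant_panel())
st <- ph$status[match(cs$sample_id, ph$sample_id)]
threshold_sweep(cs$score[st == 1], cs$score[st == 0], cutoffs = 7)
#>   cutoff   or sensitivity specificity   ppv   npv accuracy
#> 1      7 2.92       24.39       90.06 64.29 61.89    62.27

roc(cs$score[st == 1], cs$score[st == 0])$auc
#> [1] 0.688
```

The first call simulates a cohort with the packaged panel's control
frequencies and univariate ORs; the per-SNP test then recovers an effect
near the generating value (rs2066847, OR 4.27 here against a generating
5.18 — a single-cohort draw, not a bias). The sweep row reads: calling
"disease" at a count score ≥ 7 catches 24% of cases while keeping 90% of
controls negative, a 2.9-fold odds contrast in this simulated cohort; the
AUC of 0.69 summarizes the score over all cutoffs.

Independently of any simulation, the published cutoff table can be
recomputed from its printed counts alone:

```r
rt <- recompute_threshold_table()
subset(rt, score_type == "count" & cutoff == 7)
#>   cutoff   or ci_low ci_high sensitivity specificity accuracy
#> 5      7 4.86   3.27    7.22          29       92.25    65.48
subset(rt, !or_consistent)$cutoff   # printed ORs the counts cannot produce
#> [1]  9 10 11
```

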