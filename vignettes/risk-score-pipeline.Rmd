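---
title: "Case-control genetic risk scores: models, simulator and design notes"
author: "cdgrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control genetic risk scores: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdgrs)
```

## Scope

`cdgrs` implements the complete statistical pipeline of a small-panel
case-control association study, modelled on a published 22-SNP Crohn's
disease panel genotyped in 369 Ashkenazi Jewish cases and 503 controls:
genotype QC (Hardy-Weinberg equilibrium, pairwise LD), univariate and
multivariate odds-ratio estimation, two genetic risk scores with threshold
classification and ROC evaluation, analytic power, and a synthetic-cohort
simulator that emulates the study's data-generating assumptions so that
every stage is testable without the (undeposited) raw genotypes.

## Data model

Genotypes are held as risk-oriented dosages: 0 for common-allele
homozygotes, 1 for heterozygotes, 2 for risk-allele homozygotes. For
protective variants (in the packaged panel the two IL23R SNPs rs11209026
and rs7517847) the *major* allele is declared the risk allele
(`is_flipped = TRUE`), so every panel allele points in the risk direction
and both risk scores are monotone in risk. Flipping maps a dosage $c$ to
$2-c$, frequencies to $1-p$, and odds ratios to their reciprocals; applying
it twice is the identity.

Missing calls are excluded pairwise from frequencies and 2x2 tables. In
score computation they are instead mean-imputed as twice the pooled
risk-allele frequency (flagged per sample), which keeps the evaluated group
sizes fixed — the convention needed for cutoff tables whose denominators are
the full 369/503.

## Statistical methods

**HWE.** For genotype counts $(n_{AA}, n_{Aa}, n_{aa})$ the allele
frequency $\hat p$ is estimated by counting, expected counts are
$n(\hat p^2, 2\hat p\hat q, \hat q^2)$, and the Pearson statistic is
referred to $\chi^2_1$. Monomorphic input returns $\chi^2 = 0,\,p = 1$.
The scan defaults to controls only: deviation among cases can be a genuine
disease signal rather than a genotyping failure. (Whether the original
study's LD/HWE supplement used controls or pooled samples is not stated;
controls-only is this package's documented default, with `stratum =
"pooled"` available.)

**LD.** Two-locus haplotype frequencies are maximized by EM from unphased
genotypes: all cells of the 3x3 genotype cross-table determine their
haplotypes except the double heterozygote, which is split each E-step
according to the current estimate
$\rho = p_{AB}p_{ab} / (p_{AB}p_{ab} + p_{Ab}p_{aB})$ — the standard EM,
not a fixed 50/50 split, because only that yields the MLE. Initialization
is at linkage equilibrium; convergence when the largest frequency change
drops below $10^{-10}$ (at most 1000 iterations). Then
$D = p_{AB} - p_Ap_B$, $D' = D/D_{\max}$ with
$D_{\max} = \min(p_Aq_B, q_Ap_B)$ for $D>0$ (mirrored for $D<0$), and
$r^2 = D^2/(p_Aq_Ap_Bq_B)$. If $D_{\max} = 0$ (a frequency at the boundary)
$D'$ is reported as 0 with a warning rather than 0/0. The observed-data
log-likelihood is tracked per iteration and asserted non-decreasing in the
tests; a grid search over $p_{AB}$ at $10^{-5}$ resolution serves as an
independent oracle.

**2x2 odds ratios.** Allelic tests treat alleles as observations ($2n$
denominators), matching the study's "allelic odds ratio" convention — this
choice is confirmed by the printed interval for the most extreme cutoff row,
which the Wald construction reproduces to two decimals. With
$\mathrm{SE}(\ln\mathrm{OR}) = \sqrt{1/a+1/b+1/c+1/d}$, the 95% CI is
$\exp(\ln\mathrm{OR} \pm 1.96\,\mathrm{SE})$ and the p-value is two-sided
normal. If any cell is zero, 0.5 is added to all four cells
(Haldane-Anscombe) and the result is flagged — finite flagged estimates
stand in for the study's "ND" cells. Carriage (at least one risk allele
across a SNP set) and compound heterozygosity/homozygosity (two or more risk
alleles in total) reduce to 2x2 tables over samples.

**Logistic regression.** `logistic_fit()` is a Newton/IRLS maximizer of the
Bernoulli log-likelihood with step-halving, so the likelihood trace is
non-decreasing. Convergence requires every score-equation component below
$10^{-8}$; Wald SEs come from the inverse observed information. A
coefficient walking past $\pm 15$ flags probable separation: the fit is
returned unconverged with a warning instead of erroring, mirroring
inestimable genotype cells. Three codings are built from the dosage matrix:
per-SNP indicator pairs (1 copy, 2 copies), and the log-additive linear
dosage whose exponentiated coefficient is the per-allele OR. In the
genotype coding, empty or aliased cells (no 2-copy carriers, or no
non-carriers) are dropped and reported as inestimable. The study does not
describe how its multivariate model was reduced to seven SNPs;
`backward_prune()` offers a conventional backward elimination at
$p \ge 0.05$, labelled as this package's own, non-canonical choice.

**Power.** The analytic allelic power uses the two-proportion normal
approximation with the case frequency derived on the odds scale,
$p_1 = \mathrm{OR}\,p_0/(1-p_0+\mathrm{OR}\,p_0)$:
$\mathrm{power} = \Phi\!\left(|p_1-p_0|/\mathrm{SE}_{\mathrm{alt}} -
z_{1-\alpha/2}\right)$,
$\mathrm{SE}_{\mathrm{alt}} = \sqrt{p_1q_1/2n_{\mathrm{case}} +
p_0q_0/2n_{\mathrm{control}}}$. At $\mathrm{OR}=1$ this one-tailed formula
returns $\alpha/2$, not $\alpha$ — the price of ignoring the opposite
rejection tail, negligible under any real alternative. A Monte-Carlo mode
draws stratum genotype counts from the calibrated retrospective model and
counts Wald rejections. At the study's $n = 369/503$ and $\alpha = 0.05$, a
control risk-allele frequency of 0.59 (the ATG16L1 frequency under
discussion in the source study, which did not print its assumed value)
reproduces the quoted 80% detectability of $\mathrm{OR} \ge 1.32$; the
frequency is an exposed parameter, not an asserted study input.

**Risk scores and evaluation.** The count score sums panel dosages (range
$0..2k$); the weighted score sums weight times dosage, with the packaged
default weights equal to the multivariate log-additive ORs — the literal
"multiplied ORs by 0, 1, or 2" construction — with protective SNPs flipped
and their weight the reciprocal of the printed OR. Log-OR weights (the
regression-coefficient convention the study cites) can be supplied instead;
because the published weight set cannot be uniquely reconstructed from the
text, no claim is made to reproduce the published weighted-score
distribution bin for bin. Cutoffs are inclusive ("score $\ge t$").
Sensitivity, specificity, PPV, NPV and accuracy are percentages with
accuracy the prevalence-weighted average of sensitivity and specificity,
i.e. exactly the fraction classified correctly. The ROC is traced over all
distinct cutoffs and the trapezoidal AUC equals the Mann-Whitney
probability with ties counted one half (asserted against exhaustive pair
counting).

## The synthetic-cohort simulator

The simulator is prospective-logistic with retrospective ascertainment:
individuals are drawn from a source population with HWE genotypes
(optionally two-SNP LD blocks drawn as two independent haplotypes from
[make_haplotype_pair()]), disease is assigned
$\mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 + \sum_i \ln(\mathrm{OR}_i)
c_i))$, and sampling continues until the case and control quotas are filled
— the design being emulated, and deliberately distinct from directly
sampling stratum genotype frequencies, so that the analytic Bayes inversion
`expected_genotype_freq_in_stratum()` remains an independent oracle for it.

$\beta_0$ is calibrated by bisection so that the population expectation of
the penetrance equals the target prevalence, to within $10^{-8}$. The
expectation is exact (full enumeration of the joint dosage support) while
the support is small; for larger panels such as the 22-SNP reference
configuration the distribution of the linear predictor is convolved on a
fine grid (step $10^{-3}$) with linear probability splitting, whose error
in the expectation is second-order in the step and far below the bisection
tolerance in practice.

Defaults are the study conditions: 369 cases, 503 controls, the packaged
control risk-allele frequencies as population frequencies, and the
univariate allelic ORs as per-allele effects. Prevalence defaults to 0.005
— Crohn's-disease-like; the study never states the value behind its power
remark, so it is a parameter, and the rare-disease regime keeps OR close to
RR. A sampling cap (default 20 times the expected draws) turns impossible
quota/prevalence combinations into a diagnostic error.

One master seed (`set.seed` at entry to `simulate_cohort()`) makes a
configuration bit-reproducible within this implementation; across
implementations only distributional reproducibility is meaningful. LD
beyond pairs (e.g. the study's three-SNP IRGM block at $r^2 > 0.95$) would
be modelled as chained pairs; full multi-locus haplotype simulation is out
of scope.

What the simulator does *not* emulate: population structure and
relatedness, genotyping error, informative missingness, effect-size
attenuation from using marginal (univariate) ORs jointly in the 22-SNP
reference configuration, and any LD unless requested. Consequently,
passing parameter-recovery and calibration tests shows the estimators are
correct under the stated model, not that the model captures every feature
of the real cohort.

## Published-table reproduction and its limits

`recompute_threshold_table()` rebuilds every metric of the published cutoff
table from its printed counts alone. All count-score rows ($\ge 3..\ge 8$)
and weighted rows ($\ge 2..\ge 8$) reproduce the printed OR to 0.01 and the
printed percentages to 0.1, with two documented exceptions that the counts
themselves contradict: the count $\ge 6$ row prints accuracy 64.5 while its
counts imply 64.8, and the printed ORs of the weighted $\ge 9,\ge 10,
\ge 11$ rows (7.69, 9.45, 14.2) are not the cross-products of their printed
counts (7.30, 5.96, 6.32). The recomputation flags these rows; the package
reproduces the internally consistent ones and makes no attempt to guess the
computation behind the others. Univariate ORs, multivariate coefficients,
the score-distribution figures and the printed AUCs (70%/71%) depend on the
unavailable individual-level genotypes and are covered by property-based
checks on simulated cohorts instead of exact reproduction.

One annotation oddity is preserved as-is: the packaged panel lists
rs1373692 under PTGER4 with the label "p.T300A" exactly as printed, even
though T300A conventionally denotes the ATG16L1 coding change; the SNP is
treated purely as an identifier with a declared risk allele.

## Numerical choices

* EM: LE initialization, tolerance $10^{-10}$ on frequencies, 1000
  iteration cap; boundary $D_{\max}=0$ yields $D'=0$ with a warning.
* Intercept bisection: residual $10^{-8}$ on prevalence, interval widening
  before failure; exact enumeration up to $2\times10^5$ support points,
  else grid convolution at step $10^{-3}$.
* IRLS: score tolerance $10^{-8}$, 100 iteration cap, step-halving floor
  $10^{-10}$, separation threshold $|\beta| > 15$.
* Haldane correction: 0.5 to all four cells, only when a cell is zero,
  always flagged.
* Ordering: input sample/variant order is preserved everywhere; no sorting.

## Problem sizes used by the test suite

The property-based checks run at sizes chosen to balance Monte-Carlo
resolution against a quick default test run: parameter recovery uses 200
simulated cohorts at the full study size (369/503, prevalence 0.005);
null calibration uses 1000 replicates of 150/200 cohorts at prevalence 0.2
(the "small-cohort" null regime, where quota filling is cheap and the
allelic test's nominal level is the property under test); LD round-trips
use cohorts of 3000–8000; stratum-frequency cross-checks use 2000/2000.

## Known limitations

* The weighted score's published weight set and protective-allele
  convention are not uniquely recoverable; the reciprocal-OR flip default
  implies a score scale shifted relative to the published histograms.
* No exact (mid-p or Fisher) tests, no covariate adjustment beyond
  genotypes, no haplotype association, no imputation/phasing, no
  multiallelic sites or sex chromosomes.
* The score models are developed and evaluated on the same data by design,
  as in the source study; no cross-validation or external validation is
  provided.
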