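---
title: "Methods: polygenic scoring and kappa-weighted ROC trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scoring and kappa-weighted ROC trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgenrisk)
```

This vignette is the package's own account of the statistical methods it
implements, the choices made where the methodology was genuinely open,
and what its synthetic-data tests do and do not establish.

## The analysis model

The package targets small candidate-marker case/control studies of
clinically heterogeneous Alzheimer's disease: a few hundred subjects, a
few dozen biallelic markers genotyped as additive minor-allele doses
(0/1/2 with missing calls), cases split into amnestic (AmnAD) and
atypical (AtAD) presentations, and a two-stage discovery/validation
design. Three statistical layers sit on top of that data model.

**Association.** Each marker is tested marginally with a logistic
regression `status ~ dose` under the additive model; no covariates are
included, matching the convention of small replication scans. The
reported statistic is the Wald z (maximum-likelihood slope over its
observed-information standard error) with a two-sided normal-tail
p-value; on a binary dose this reduces exactly to the 2×2 log-odds-ratio
with Woolf's standard error, which the test suite uses as a closed-form
oracle. Missing doses are handled per marker by complete-case analysis.
Complete separation is flagged (p reported missing) rather than
silently returning a divergent estimate.

**Risk scoring.** Ranked findings are pruned greedily in rank order:
a marker survives iff its squared dose correlation (composite LD,
computed over pairwise-complete samples) with every already-retained
marker is ≤ 0.8. This formalises "keep the most strongly associated
member of each linked set" deterministically. Each retained marker is
oriented so that the counted allele confers risk — minor allele when
OR ≥ 1 (the boundary keeps the minor allele), major otherwise — and
nested sets A, B, C, … are built by adding one marker at a time in rank
order. A sample's score for a set is the weighted mean risk-allele
fraction, `Σ w·d′ / (2m)`; missing doses are imputed at twice the
in-sample risk-allele frequency, mirroring the default of the classic
SNP-scoring tool. Unit weights are the default because the flipping
rule is only meaningful for unweighted allele counting; |log OR|
weights are available (`weights = "log_or"`) but are an extrapolation,
not a claim about the emulated study.

**Evaluation and the stopping rule.** Scores are assessed by empirical
ROC curves and the Mann–Whitney AUC (ties count one half), with
standard errors and paired comparisons by DeLong's
structural-components method — implemented here directly, and
cross-checked in the tests against pROC, which is never used as the
implementation. The optimal set is the first one followed by **two
consecutive AUC decreases**, falling back to the index of the maximum
when the rule never fires. The alternative literal reading "AUC_i
exceeds both of its two successors" is available via
`select_optimal_set(..., rule = "literal")`; on the published per-set
increment ladder the two readings disagree (the literal rule stops four
sets earlier at the first local peak), and the consecutive-decreases
reading is the one consistent with the published selection of the
17-marker set, so it is the default. Selection always uses the
full-precision AUC sequence; two-decimal rounding makes the rule
ambiguous. In validation the selected set's scoring file is applied
*unchanged* — ranks, orientations and weights are never re-estimated —
and compared against the single-marker baseline set A with the paired
DeLong test. Whether the emulated study's per-set comparisons were
paired is unknown; paired is assumed because both scores exist for the
same subjects.

**Decision trees.** Recursive partitioning over sex (0 = male,
1 = female), age in years, the derived APOE ε4 dose and all QC-passing
marker doses. Candidate rules are `value ≥ cut` with cuts {1, 2} for
doses, {1} for binaries, and every distinct observed value but the
minimum for continuous predictors (observed values, not integer grids —
the emulated software's behaviour is unknown and observed values add no
tuning surface). At a node, the side with the higher case fraction is
designated test-positive and the split maximising
`r·Se + (1−r)·Sp` wins, with r = 0.5 by default so sensitivity and
specificity are balanced. A Kraemer weighted-kappa criterion
(`criterion = "kraemer_kappa"`) is provided because the referenced
software family descends from that methodology; it is
`κ(r) = P·P′·(Se+Sp−1) / (r·P·Q′ + (1−r)·P′·Q)` with P the node
prevalence and Q the positive rate, and reduces to Cohen's kappa at
r = 0.5 (a property the tests assert to 1e-12). Growth stops when a
child would fall below `min_subgroup = 10`, when the winning split's
multiple-testing-corrected Pearson χ² (1 df, no continuity correction)
exceeds α = 0.01, when the path reaches `max_path_splits`, or when a
node is pure.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_call_rate` | 0.80 (exclusive) | fraction | marker inclusion rule of the emulated design |
| `min_maf` | 0.01 (inclusive) | fraction | idem |
| `min_hwe_p` | 0.001 (exclusive) | probability | idem; strict/inclusive boundaries follow the stated inequalities |
| LD `threshold` | 0.8 | r² | pruning cutoff of the emulated design |
| `max_sets` | 26 | sets | one per letter A–Z |
| `kappa_weight` | 0.5 | — | equal weighting of sensitivity and specificity |
| `min_subgroup` | 10 | subjects | smallest admissible child |
| `alpha` | 0.01 | probability | χ² significance floor after correction |
| `max_path_splits` | 4 | splits | see below |
| `correction` | per predictor | — | see below |

Two of these were genuinely open. The depth cap: the stopping rule is
described as firing at a "three-way interaction", yet the published
all-AD tree chains four successive split variables; the default is
therefore 4, with 3 available to match the narrower reading. The
multiple-testing correction: "corrected" is not specified, so the
default multiplies the χ² p by the number of predictors searched at the
node (the coarser, more conservative-per-predictor family), with a
per-cut Bonferroni (`correction = "bonferroni_cuts"`) selectable.

## Hardy–Weinberg testing population

The exact test itself (Levene–Haldane conditional two-sided, summing
heterozygote configurations no more probable than the observed one) is
computed by default over all supplied samples, since the emulated
design does not state otherwise. The *pipelines*, however, assess HWE
in controls only (`hwe_in = "controls"`): a marker with a real effect
departs from HWE in the pooled case/control sample in proportion to its
effect, and pooled testing can therefore delete exactly the markers the
study is about — in simulation the planted APOE marker is lost this way
in a few percent of cohorts. Controls-only is the standard case/control
practice; `hwe_in = "all"` restores the naive behaviour.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws controls at HWE with configured population
MAFs and draws cases of each subtype with genotype probabilities tilted
by `exp(dose × log OR)` and renormalised — retrospective (case-control)
sampling under the additive logit model, which matches the study design
and avoids modelling prevalence. Calibrations baked into the defaults:

* group sizes 283 / 126 / 39 (controls / AmnAD / AtAD), with
  per-stage presets (133/42/17 discovery, 150/84/22 validation) in
  `study_design_counts()`;
* a composite APOE ε4 marker with control allele frequency 0.119,
  the value implied by a 22.3 % control carrier rate under HWE (the
  published cohort MAF of 0.20 is case-enriched and would overstate the
  control rate);
* one strong planted driver per subtype — per-allele OR 4.3 for ε4 in
  AmnAD, and the same strength for HFE rs1799945 in AtAD. The pooled
  all-AD estimate for HFE (OR 2.83) is diluted by the roughly 70 %
  amnestic share of cases and would understate the subtype-specific
  effect that makes HFE the leading AtAD differentiator;
* ages truncated-normal on 65–101 years and 2 % missing genotypes.

Age and sex are simulated but **not causal by default**: all groups
share one age/sex distribution, so planted genetic structure alone
drives case status and recovery tests are interpretable. Passing
`demographics = study_demographics()` gives each group its
study-calibrated profile (e.g. amnestic cases 79.2 ± 8.5 years, 33.3 %
female atypical cases), which makes age a genuinely informative tree
predictor — as in the real cohort — at the cost of confounding the
genetic recovery checks.

The simulator does not model genome-wide LD (only explicit proxy
markers via `plant_ld_proxy()`, which resample from the parent's
marginal with probability 1 − fidelity), haplotype phase, genotyping
batch effects, or population structure. Consequently, passing tests
show that the *pipeline* recovers planted structure under its own
assumptions; they say nothing about robustness to stratification or
assay artefacts in real data.

## Numerical choices and degenerate inputs

* HWE tail sums use a `1e-10` relative tolerance when comparing log
  probabilities, guarding against ties at the observed configuration.
* Logistic fits run IRLS to a `1e-12` deviance tolerance so slopes and
  standard errors agree with closed forms to about `1e-6`; separation is
  detected from the fitted-probability warning (or an SE above 100) and
  flagged.
* Ranking ties break by |z| descending then marker id; split ties break
  by predictor manifest order then lower cut; the tie at OR = 1 keeps
  the minor allele; an equal case fraction on both split sides
  designates the ≥ side positive. All downstream results are therefore
  deterministic and permutation-invariant.
* Samples missing a split predictor are excluded from that node's
  search and follow the larger child (ties to the positive side), so
  child counts always sum to the parent.
* Degenerate inputs (constant doses, single-class nodes, empty marker
  sets, zero-margin 2×2 tables) raise typed errors or flagged rows as
  documented, never silent numbers.
* Paired DeLong on identical score vectors has zero variance of the
  difference and returns z = 0, p = 1 by convention.

## Problem sizes in the test suite

The suite exercises the simulator at the study's own scale (448
subjects, 75 markers) for the end-to-end checks: 100-seed loops for
parameter recovery (planted OR 4.3, 185 cases / 283 controls),
subtype-architecture recovery at the tree root, and the
discovery-versus-validation overfitting direction; oracle-equivalence
checks run on 30–120-row fixtures where brute force is exact. Marginal
calibration uses 5 000 controls. These sizes were chosen so every
stochastic assertion has comfortable Monte-Carlo margins while the
whole suite stays inside a few minutes.

## Known limitations

* With 39 atypical cases, the corrected-χ² stopping rule at α = 0.01
  over ~77 predictors is underpowered for the planted AtAD driver: in
  repeated simulation a noticeable minority of cohorts yield a
  single-leaf atypical tree even though the driver is the top-quality
  split in essentially all of them. This is a property of the design
  being emulated, not of the implementation, and the package reports it
  honestly rather than weakening the gate.
* Composite (dose-correlation) LD slightly differs from haplotype-EM
  r²; at the 0.8 cutoff used for pruning the difference is immaterial,
  but the pruning is not guaranteed identical to phase-aware tools.
* Node metrics treat node *membership* as the test
  (PVP = cases/node size, Se = node cases/all cases, and so on). The
  emulated software may have used a cumulative-classifier
  operationalisation for its reported sensitivities; both readings are
  computable from the exported counts, and neither is asserted to be
  the original definition.
* Two published totals for the validation stage (subtyped counts
  summing 256 versus a reported 276 participants) cannot both be
  reproduced by one simulated cohort; the design-count table records
  both and composition percentages use the reported stage totals.
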