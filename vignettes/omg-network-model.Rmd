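---
title: "A discrete Bayesian network for suspected ocular myasthenia gravis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete Bayesian network for suspected ocular myasthenia gravis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omgnet)
```

## The clinical problem

Ocular myasthenia gravis (OMG) presents with fatigable ptosis and/or
diplopia and mimics many other ocular motility disorders.  No single test
settles the diagnosis: acetylcholine receptor (AChR) antibody serology is
specific but has limited and strongly age-dependent sensitivity, while
edrophonium testing, repetitive nerve stimulation (RNS) and single-fiber
EMG (sfEMG) are accurate but often unavailable or contraindicated.  In
practice a clinician therefore holds an *incomplete* subset of test
results and wants the probability of OMG given exactly those results.

`omgnet` models this situation with a discrete Bayesian network over
twelve categorical variables: age (three bins), sex, the OMG diagnosis,
and nine signs or tests (diplopia, ptosis, sustained upgaze, ice pack
test, AChR antibodies, Besinger/QMG severity bin, edrophonium, RNS,
sfEMG).  Because a Bayesian network represents the full joint
distribution, conditioning on *any* subset of observed variables yields a
valid posterior probability of OMG — missing examinations are simply
marginalised out.

## Model

Each variable $X$ carries a conditional probability table (CPT)
$p(X \mid \mathrm{pa}(X))$ along a fixed directed acyclic graph: age and
sex are roots, OMG depends on sex, the AChR result depends on OMG *and*
age (its sensitivity roughly doubles between patients under and over 50),
and every other sign or test depends on OMG alone.  The graph is declared
in a plain-text YAML file (`inst/extdata/omg_network.yaml`) and can be
replaced wholesale; nothing in the package is hard-wired to this
structure.  The graph is fixed by design — structure learning is out of
scope, matching the model's emphasis on medically interpretable,
auditable relationships.

### Dirichlet posteriors

Every CPT row (a probability vector over the child's $k$ states for one
parent configuration) receives an independent symmetric
$\mathrm{Dirichlet}(\alpha_0, \dots, \alpha_0)$ prior with
$\alpha_0 = 1$ per state, updated conjugately by the observed counts:
$\alpha_i = \alpha_0 + n_i$.  The choice $\alpha_0 = 1$ (a uniform prior
on each row) reproduces the published credible intervals of the source
cohort; e.g. counts of 29 positive / 2 negative edrophonium tests among
OMG-positive patients give a $\mathrm{Beta}(30, 3)$ marginal with median
91.7% and 95% interval (79.2, 98.0)%.  `prior_strength` is exposed in
`fit_network()` for sensitivity analyses.

Counting uses **per-table complete cases**: a record contributes to the
CPT of $X$ iff $X$ and all parents of $X$ are observed in that record.
This matters with clinical data, where each examination is missing in a
different subset of patients — the per-table eligible case counts (71 of
89 for edrophonium, 51 for the ice test, and so on) would be destroyed by
whole-record listwise deletion.

### Credible summaries

The marginal posterior of one CPT entry is
$\mathrm{Beta}(\alpha_i,\ \alpha_\cdot - \alpha_i)$, so
`cpd_summary()` reports *exact* equal-tailed quantiles
$(q_{0.025}, \mathrm{median}, q_{0.975})$ via `qbeta` — no sampling.
Published CPD tables of this kind are often produced by Monte-Carlo
draws from the posterior instead; with $10^4$ draws the sampled quantiles
of these Beta distributions jitter by up to roughly $\pm0.3$ percentage
points around the exact values, which is worth remembering when comparing
any printed table against exact quantiles digit by digit.  Within this
package the exact route is canonical, and the sampling route
(`sample_parameters()`) is tested for convergence against it.

### Prediction under partial evidence

`predict()` propagates *parameter* uncertainty into the prediction:

1. draw `n_samples` full parameter sets from the Dirichlet posteriors
   (each CPT row independently — the exact conjugate posterior);
2. for each draw compute $P(\mathrm{OMG}^+ \mid \mathrm{evidence})$ by
   exact enumeration;
3. report the empirical median and the 0.025/0.975 quantiles, and
   classify positive when the median strictly exceeds 50%.

Enumeration first prunes unobserved *barren* variables (non-query,
non-evidence variables with no retained children), whose CPTs sum to
one; what remains is the ancestral set of the query and evidence.  For
this network that leaves at most a few dozen joint configurations, so
exact inference costs microseconds per draw and the algorithm stays fully
transparent — there is no approximate message passing anywhere.
A strictly positive prior makes all sampled probabilities positive, so
zero-probability evidence can only arise with user-supplied degenerate
parameters; that case raises an explicit error rather than renormalising
silently.

Defaults: `n_samples = 10000` and `seed = 20160101`.  At $10^4$ draws the
interval endpoints are stable to about $\pm 0.005$; the median is far
more stable, and the ties rule (median exactly 0.5 classifies negative)
follows the strict ">50%" positivity convention.

## The packaged training fixture

The published per-variable counts of the 89-patient prospective training
cohort (39 OMG-positive) ship as `omg_training_fixture()`: counts per OMG
stratum, missing-examination counts per stratum, and a provenance flag
per variable.  One subtlety: the AChR-by-age joint split is not published.
The packaged split (6/10, 12/13, 15/16 positives among OMG-positive
patients across the three age bins; 0/15, 0/17, 2/18 among OMG-negative)
is the unique integer solution consistent with all published margins and
the reported 27/29 over-50 sensitivity, and is flagged `"derived"`.

`expand_fixture()` turns the counts into an 89-record data set whose
per-table counts reproduce the fixture *exactly*.  Because cross-test
joints within an OMG stratum are not identified by the published margins,
any such expansion is one admissible reconstruction: single-predictor
summaries computed from it are exact, while multi-predictor summaries
depend on the unpublished joint and are illustrative only.  Passing a
seed permutes the within-stratum assignment, which changes none of the
per-table counts — a property the test suite checks.

## Validation machinery

`evaluate_predictors()` mirrors the published internal validation: keep
records complete for the predictor set and the outcome, score each by the
median predicted OMG probability given only those predictors, classify at
the strict 50% threshold, and report the misclassification rate together
with the rank-based AUC (mid-ranks, i.e. ties count one half — the
Mann-Whitney convention).  On the training fixture this reproduces the
published single-predictor rows: 8 of 89 misclassified by AChR status
alone, 6 of 71 by edrophonium alone.

`cross_validate()` performs seeded k-fold cross-validation (default
k = 10): unstratified random folds as equal as possible, refit on the
remaining folds with the same prior, evaluation on the held-out fold,
and unweighted fold averages.  Folds containing a single outcome class
leave the AUC undefined; they are excluded from the AUC mean and counted
in `auc_folds_skipped`, while still contributing to the error mean.
`sens_spec()` computes per-test sensitivity and specificity from the
records with both the test and the outcome observed, returning the raw
2x2 counts alongside.

## Synthetic cohorts

`generate_cohort()` draws records by ancestral sampling in topological
order from plug-in (posterior-mean) or user-supplied parameters, then
masks each variable independently at configurable rates
(missing-completely-at-random); `omg_training_missing_rates()` reproduces
the training data's missing-examination fractions.  The outcome is never
masked.  MCAR is a deliberate simplification: in the real cohort,
missingness is plausibly informative (edrophonium was skipped on
contraindication or after positive serology), but no mechanism is
quantified, so an honest generator exposes the rates and assumes no more.
Consequently, passing recovery and cross-validation tests on synthetic
data demonstrate correctness of the fitting and scoring machinery under
MCAR — they do not certify behaviour under informative missingness or
referral bias, which also shape the real training data.

## Numerical and design choices

* Exact Beta quantiles for single-entry summaries; Monte-Carlo only for
  compound queries, where the posterior of
  $P(\mathrm{OMG} \mid \mathrm{evidence})$ has no closed form.
* Age bins use right-closed intervals $(0,50], (50,70], (70,120]$ and the
  severity score $[-1,1], (1,4], (4,8], (8,24]$; the published bin labels
  overlap at the boundaries, so the closure convention is this package's
  choice and is documented at the binning functions.
* The Besinger and QMG severity scores are treated as one variable (the
  validation cohorts measured QMG instead of Besinger).
* Problem sizes in the test suite — $10^4$ synthetic records for
  parameter recovery (binomial tolerance $\pm 0.03$), $10^5$ posterior
  draws for quantile convergence (tolerance $\pm 0.005$), 890 records for
  the cross-validation-versus-Bayes-error check (tolerance $\pm 3$
  percentage points) — were chosen so that each tolerance sits at three
  or more standard errors of the corresponding estimator.
* All randomness is seed-controlled, and seeded entry points restore the
  caller's RNG state.

## Known limitations

* The training cohort is small (n = 89, single tertiary center, likely
  referral bias); the credible intervals express exactly this. The model
  is a decision aid, not a diagnostic oracle.
* The DAG is asserted, not learned; variables absent from the published
  tables (dysarthria, dyspnea, dysphagia) are not modelled.
* External validation cohorts are available only as aggregate counts, so
  the package makes no claim to reproduce record-level external
  validation results.
* Multi-predictor training-set metrics depend on unpublished cross-test
  joints and are reproducible only on synthetic or user-supplied
  record-level data.
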