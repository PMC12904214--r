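# omgnet

A discrete Bayesian network for estimating the probability of **ocular
myasthenia gravis (OMG)** in patients presenting with ptosis and/or
diplopia, from any subset of routine clinical variables: age, sex,
diplopia, ptosis, sustained upgaze test, ice pack test, acetylcholine
receptor (AChR) antibodies, Besinger/QMG severity score, edrophonium
test, repetitive nerve stimulation (RNS) and single-fiber EMG (sfEMG).

OMG is a great mimicker, and its single most accessible biomarker — AChR
serology — misses a large fraction of cases, especially in younger
patients. The package is aimed at neuro-ophthalmologists, neurologists
and biostatisticians who want an interpretable diagnostic aid that still
works when most examinations are missing, plus the machinery to refit
and validate it on their own cohorts.

## Model

The joint distribution factorizes along a fixed DAG,

p(age, sex, omg, tests) = p(age) p(sex) p(omg | sex) p(achr | omg, age) ∏ p(testᵢ | omg),

with each conditional probability table (CPT) row carrying an independent
symmetric Dirichlet(1) prior updated conjugately by per-table
complete-case counts: α = 1 + n. Single CPT entries are summarised by
*exact* Beta quantiles (0.025, median, 0.975). Predictions under partial
evidence propagate parameter uncertainty: `predict()` draws parameter
sets from the Dirichlet posteriors, computes P(OMG⁺ | evidence) for each
draw by exact enumeration over the (pruned, tiny) joint, and reports the
median with an equal-tailed 95% credible interval; a case is classified
positive when the median exceeds 50%. Validation follows the clinical
convention: misclassification rate and rank-based AUC per predictor set,
on the training data or by seeded 10-fold cross-validation.

The published per-variable counts of the 89-patient training cohort
(39 OMG-positive) ship as a fixture, together with an expander that
produces record sets matching those counts exactly and a synthetic
cohort generator with configurable missingness.

## Worked example

```r
library(omgnet)

fit <- fit_network(omg_training_counts())

# How sensitive is AChR serology in a young OMG patient?
round(100 * cpd_summary(fit, "achr", "positive",
                        c(omg = "positive", age = "18-50")), 1)
#>   q025 median   q975
#>   30.8   58.8   83.3

# Seronegative patient with a positive ice pack test:
predict(fit, c(achr = "negative", ice = "positive"))
#> OMG probability given evidence: achr=negative, ice=positive
#>   median 25.4%  (95% CI 11.3% - 46.3%)
#>   classification: negative (10000 posterior draws, seed 20160101)

# Older seropositive man:
predict(fit, c(sex = "male", age = "70+", achr = "positive"))
#> OMG probability given evidence: sex=male, age=70+, achr=positive
#>   median 89.2%  (95% CI 73.1% - 97.4%)
#>   classification: positive (10000 posterior draws, seed 20160101)

# Training-set validation of serology as sole predictor:
evaluate_predictors(fit, omg_training_records(), "achr")
#> Predictor set: { achr }
#>   cases: 89   error rate: 8.99%   AUC: 0.903
```

The first block reads: given a final OMG diagnosis and age 18–50, the
posterior probability of a positive AChR test has median 58.8% with 95%
credible interval (30.8, 83.3)% — the serology's age-dependent
sensitivity, learned from 10 young OMG-positive patients, hence the wide
interval. The prediction blocks show the central clinical use: the
probability of OMG given exactly the tests at hand, with the credible
interval conveying how much the small cohort actually pins it down. The
validation block scores all 89 training records by AChR status alone:
8 of 89 are misclassified at the 50% threshold.

A command-line interface wrapping the same functions (subcommands `fit`,
`predict`, `validate`, `simulate`, `summarize`) is installed at
`inst/cli/omgnet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "omgnet.R", package = "omgnet"))')" \
  predict sex=male achr=positive
```

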