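# vavalidate

Validation framework for computer-coded verbal autopsy (CCVA) algorithms.

Where deaths occur outside medical care, the probable cause of death is often
inferred from a **verbal autopsy** (VA): a structured interview with relatives
about the symptoms the deceased experienced. Algorithms that assign causes
from these symptom endorsements need rigorous validation against
gold-standard data, both at the **individual level** (did the algorithm get
each death right?) and at the **population level** (did it recover the cause
distribution, the input to health policy?). `vavalidate` implements the
standard chance-corrected validation protocol used for this purpose, and a
synthetic gold-standard data generator so the whole pipeline can be run and
tested without access to restricted mortality data.

## The metrics

For cause $j$ out of $N$ causes, with one-vs-rest true positives $TP_j$ and
false negatives $FN_j$, **chance-corrected concordance** rescales sensitivity
so that 0 is random guessing and 1 is perfect detection:

$$CCC_j = \frac{\frac{TP_j}{TP_j + FN_j} - \frac{1}{N}}{1 - \frac{1}{N}}$$

Population-level performance compares the true and predicted cause-specific
mortality fractions (CSMF):

$$\mathrm{CSMF\ accuracy} = 1 - \frac{\sum_{j=1}^{N} |CSMF_j^{true} - CSMF_j^{pred}|}{2\left(1 - \min_j CSMF_j^{true}\right)}$$

and is corrected for chance (random allocation against Dirichlet-distributed
true fractions attains about $1 - e^{-1} \approx 0.632$):

$$\mathrm{CCCSMF\ accuracy} = \frac{\mathrm{CSMF\ accuracy} - (1 - e^{-1})}{1 - (1 - e^{-1})}$$

## The protocol

1. Partition the gold-standard data uniformly at random into a 75% train
   fold and a 25% test fold; repeat 500 times (`make_splits()`).
2. Resample each test fold, with replacement, to a cause composition drawn
   from a flat Dirichlet (`draw_dirichlet_csmf()`, `resample_to_csmf()`), so
   train and test cause compositions are uncorrelated and a classifier
   cannot score well by parroting the training distribution.
3. For each split, estimate a **probbase** — the matrix of symptom
   endorsement probabilities conditional on cause — from the train fold
   (`estimate_probbase()`), or use a fixed expert-derived one.
4. Predict causes on the resampled test fold with a reference classifier
   (`predict_va()`: naive Bayes over endorsed and non-endorsed symptoms,
   an endorsed-only variant, or a uniform random baseline).
5. Score each split (`metric_report()`) and aggregate to medians with 95%
   uncertainty intervals across splits (`run_validation()`,
   `aggregate_metrics()`, `compare_runs()`).

## Worked example

```r
library(vavalidate)

cfg     <- phmrc_like_preset("neonate", n_records = 600, seed = 42)
pb_true <- generate_probbase(cfg)
ds      <- generate_dataset(pb_true, cfg)
ds
#> <va_dataset> 600 records, 6 causes (neonate), 110 symptoms, 6 site(s)

summary <- run_validation(ds, experiment_config("trained", n_splits = 50, seed = 43))
summary
#> <experiment_summary> trained mode, 50 splits (0 failed)
#>   ccc_overall_mean     median   88.4%  (UI   76.7%,   95.9%)
#>   ccc_overall_median   median   90.4%  (UI   77.5%,   99.6%)
#>   csmf_accuracy        median   93.7%  (UI   86.5%,   97.3%)
#>   cccsmf_accuracy      median   83.0%  (UI   63.2%,   92.6%)
#>   sensitivity_median   median   92.0%  (UI   81.3%,   99.7%)
#>   specificity_median   median   98.5%  (UI   96.5%,  100.0%)
```

The neonate-like preset simulates 600 deaths over 6 causes and 110 symptoms
with mild reporting noise and missingness. Training a probbase per split and
classifying with the full Bayes scorer recovers a median overall CCC of
88.4% (individual level) and a median CCCSMF accuracy of 83.0% (population
level) across 50 splits; on real VA data, where symptom profiles separate
causes far less cleanly, published values for these metrics are much lower.
`summary$ccc_by_cause` gives the per-cause CCC medians and intervals, and
`summary$reports[[i]]$confusion$misclass` the misclassification matrix of
any single split.

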