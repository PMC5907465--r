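---
title: "Chance-corrected validation of verbal-autopsy cause assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance-corrected validation of verbal-autopsy cause assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vavalidate)
```

## The problem

Computer-coded verbal autopsy (CCVA) algorithms assign a cause of death from
the ternary symptom responses (yes / no / don't know) of a structured
interview with the deceased's relatives. Validating such an algorithm
requires gold-standard data — deaths whose cause was established clinically —
and metrics that separate real diagnostic signal from what any guesser would
achieve. This package implements that validation machinery: the metrics, the
repeated-split design, empirical probbase training, reference classifiers,
and a synthetic data generator that emulates the structure of multi-site
gold-standard databases (on the order of 34 adult / 21 child / 6 neonate
causes and 100–200 symptoms per age module).

## Metrics and their chance anchors

**Individual level.** Chance-corrected concordance for cause $j$ is
per-cause sensitivity rescaled by the $1/N$ a uniform guesser attains:
$CCC_j = (TP_j/(TP_j+FN_j) - 1/N)/(1 - 1/N)$. It is 1 for perfect
detection, 0 at chance, and bounded below by $-1/(N-1)$ (sensitivity zero).
Causes without true cases in a test set have undefined $CCC_j$; they are
excluded from aggregation rather than imputed, which avoids 0/0 and matches
the one-vs-rest convention. The overall statistic is the mean of the defined
per-cause values by default; the median is available through
`overall_ccc(method = "median")`, since both aggregations appear in the
validation literature and neither is canonical.

**Population level.** CSMF accuracy is one minus the L1 distance between
true and predicted cause fractions, normalised by the largest error possible
given the true fractions, so it lies in $[0, 1]$. Random allocation does not
score 0 on it: against Dirichlet-distributed true fractions it attains about
$1 - e^{-1}$. CCCSMF accuracy is the affine rescaling that moves that
chance level to 0 while keeping 1 perfect; negative values mean worse than
chance, which genuinely occurs for badly mis-specified classifiers (see
below).

## The split design

Each of the (by default 500) repetitions partitions the data uniformly at
random into 75% train / 25% test. The test fold is then resampled with
replacement to a cause composition drawn from a flat Dirichlet
($\alpha = 1$ componentwise; the "uninformative" choice — $\alpha$ is
configurable since the literature does not pin a value). The point of the
resampling is decorrelation: the test-set cause composition becomes
independent of the training data, so an algorithm cannot earn
population-level credit by reproducing the training CSMF. The package
asserts this property directly: across 200 splits the per-cause correlation
between train-fold CSMF and resampled-test CSMF stays within sampling noise
of zero (|r| < 0.15; the sampling s.d. of a correlation over 200
independent splits is ~0.07).

Choices the design leaves open, resolved here as follows:

* **Resampled test size** equals the 25% fold size (or the full dataset in
  the no-training mode). Nothing in the protocol fixes it; matching the
  fold size keeps per-split metric variance comparable to the unresampled
  design.
* **Causes with no records in the pool** have their target mass
  renormalised over the available causes (and the event is flagged);
  otherwise the multinomial draw would be infeasible whenever a rare cause
  misses a fold.
* **Splits are simple random**, not cause-stratified.
* **Seeding**: each split derives its own seed from the master seed, so any
  single split is reproducible in isolation, and generation never perturbs
  the caller's RNG stream.
* **Uncertainty intervals** are the 2.5th/97.5th percentiles of the
  per-split values with linear interpolation (`quantile` type 7). Failed
  splits are skipped and counted rather than fatal; more than 50% failures
  aborts the run.

## Probbase estimation and reference classifiers

The *probbase* $P[j, s]$ — the probability that symptom $s$ is endorsed
given cause $j$ — is the common currency of the InterVA family of
algorithms. `estimate_probbase()` computes the empirical version from a
training fold with pseudo-count smoothing:
$(y_{js} + c)/(n_{js} + 2c)$ with $c = 0.5$ by default (a Jeffreys-style
choice), where missing responses count neither as endorsed nor as observed.
Smoothing keeps every entry strictly inside $(0, 1)$, so the log-likelihood
scores below are always finite. A cause absent from a training fold gets a
flat 0.5 row and is flagged.

The reference classifiers are deliberately simple, deterministic
plug-in scorers — the package validates *protocols*, and MCMC-based
cause-assignment samplers are out of its scope (an external algorithm's
predictions can be scored by passing its labels straight to
`metric_report()`):

* `bayes_full`: naive Bayes over both endorsed and non-endorsed symptoms,
  $\log \pi_j + \sum_s x_s \log P_{js} + (1 - x_s)\log(1 - P_{js})$,
  with missing symptoms skipped (default) or treated as absent.
* `bayes_endorsed_only`: drops the $(1 - x_s)$ term, mimicking scorers
  that use only endorsed symptoms. When absences are informative — e.g.
  high background endorsement with cause-specific signature symptoms —
  `bayes_full` dominates it, and the test suite asserts that contrast.
* `random`: uniform random assignment, the chance baseline that the
  chance-corrected metrics should score at zero.

Posteriors come from a max-stabilised softmax of the log scores; ties break
to the lowest cause index for reproducibility. The prior is the smoothed
training-fold CSMF by default, $(n_j + c)/(n + Nc)$ — the smoothing keeps
causes missing from a fold predictable at all — with a uniform option.

## The synthetic generator

`generator_config()` defines the generating process: each cause owns
`signature_size` dedicated symptoms endorsed with probability
`signature_strength`; all other symptoms are background noise at
`background_rate`. A record draws its cause from `csmf_true`, draws
symptoms Bernoulli from the probbase row, then each response flips with
probability `noise_eps` (a symmetric misreporting model — the simplest
mechanism with a single degradation dial) and is blanked to missing with
probability `missing_rate` (missing completely at random). Sites are
uniform labels with no distributional effect unless `site_effect` is set,
since sites enter the real studies only descriptively.

Defaults: `signature_strength = 0.85`, `background_rate = 0.05`,
`signature_size = 3`, `noise_eps = 0.05`, `missing_rate = 0.1`,
`hce_fraction = 0.15`, `n_sites = 6`, uniform `csmf_true`. These are chosen
once as a plausibly noisy regime — clear but imperfect symptom signal,
don't-know rates near what VA instruments show — and the presets
(`phmrc_like_preset()`) add the real studies' module structure: 34/21/6
causes, 171/86/110 symptoms, record counts near 7800/2100/2600.

What the generator does *not* emulate: real marginal endorsement rates,
instrument skip logic, correlated symptoms within a record beyond the
shared cause, informative missingness, or site-level confounding. Passing
tests therefore demonstrate that the pipeline is correct and calibrated,
not that any classifier would reach similar accuracy on field data —
synthetic signatures separate causes far more cleanly than real symptoms
do.

## Calibration and limiting behaviour

The test suite and `scripts/acceptance.R` verify, end to end:

* exact worked values of every metric, and equality with a brute-force
  record-by-record reference on random instances;
* chance calibration — a uniform random classifier over 34 causes on 500
  Dirichlet-composed test sets of 1,000 records averages CSMF accuracy
  $\approx 1 - e^{-1}$ with both chance-corrected metrics centred at 0;
* the separable limit — with signature strength 1 and no noise, the full
  50-split pipeline scores exactly 100% on CCC, CSMF accuracy and CCCSMF;
* probbase recovery — estimation RMSE against the generating truth falls
  as training size grows (about 0.04 at 50 records/cause, under 0.02 at
  200);
* the trained-vs-mis-specified contrast — a fixed probbase whose signature
  blocks are rotated to the wrong causes scores a clearly *negative*
  median CCCSMF (worse than chance at the population level, even though
  such a classifier can remain above chance individually), while training
  on the same data scores strongly positive. This reproduces, at sign
  level, the qualitative phenomenon that motivates empirical training over
  mis-matched default probbases.

Problem sizes in the tests (hundreds to a few thousand records, 8–200
splits) are scaled-down versions of the 12,530-record, 500-split design,
chosen so the whole suite runs in seconds while every assertion still has
the statistical room it needs.

## Known limitations

* Reference classifiers are plug-in scorers, not re-implementations of any
  published CCVA algorithm; published accuracy tables for those algorithms
  are not reproducible from this package alone.
* Only top-cause predictions feed the CSMF; partial/ranked assignment and
  posterior-averaged CSMFs are out of scope.
* The HCE flag is the only symptom metadata the masking understands;
  arbitrary symptom subsets are expressed by building a reduced
  `symptom_dictionary` instead.
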