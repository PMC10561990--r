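---
title: "Stacked generalization with stackle: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked generalization with stackle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackle)
```

## The procedure

Stacked generalization combines a roster of L supervised base learners by
training a second-stage *meta-learner* on their cross-validated
predictions. `stackle` implements the variant in which every fold model is
kept and averaged at prediction time, rather than refitting each base
learner on the full training set:

**Training.**

1. Partition the n training samples into `nfold` disjoint folds
   (`assign_folds()`; sizes differ by at most one).
2. For each base learner l and fold f, fit the learner on all samples
   *not* in f. This yields an `nfold` × L grid of fold models.
3. Predict each held-out fold with the model trained without it. Cell
   (i, l) of the resulting n × L *meta-feature table* is an out-of-fold
   prediction: the model that produced it never saw sample i. This is the
   leakage guarantee that makes the meta-features honest estimates of each
   learner's generalization behaviour.
4. Train the meta-learner on the meta-feature table against Y. Two modes:
   - **pooled** (default): one meta-fit on all n rows;
   - **per-fold** (`train_each_fold = TRUE`): `nfold` meta-fits, fit f
     using only the rows of fold f.

**Prediction.** New samples are fed to *all* `nfold` × L fold models; the
`nfold` predictions of each learner are averaged (regression) or reduced
to the most frequent category (classification), giving an m × L table;
that table, encoded exactly as at training time, is fed to the
meta-model(s). In per-fold mode the `nfold` meta predictions are averaged
(regression) or majority-voted (classification).

A base learner is a *method plus one complete hyperparameter setting*:
each row of a `method_spec()` table is one ensemble member, so a method
with G rows contributes G base learners, and `cartesian_grid()` is the
explicit helper that turns per-parameter value lists into all
combinations. Keeping rows-as-settings and product-building separate means
the ensemble size L is always visible in the configuration — conflating
them would change L silently.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `nfold` | 5 | CV folds; also the number of fold models kept per learner. More folds = more training data per fold model and more models to average, at linear cost. |
| `train_each_fold` | `FALSE` | Pooled vs per-fold meta-training. Pooled uses all n rows for one fit; per-fold trains `nfold` smaller meta-models whose predictions are averaged. |
| `which_to_use` | all learners | Column subset of the meta-feature table visible to the meta-learner. |
| `cores` | 1 | Fork-based parallelism over the `nfold` × L independent cells. |
| `seed` | 1 | Controls fold assignment and every fit (below). |

## Numerical and reproducibility choices

- **Per-cell seeding.** Cell (f, l) derives its seed deterministically
  from the global seed, f, and l, and each adapter is handed that seed.
  Parallel (`cores > 1`) and serial runs are therefore bit-identical; the
  suite asserts this.
- **Feature alignment by name.** Prediction reorders `newX` columns to
  the training order and rejects missing/extra columns: silent positional
  misalignment is the classic stacking bug.
- **Classification encoding.** Meta-features are predicted class *labels*
  (not probabilities). Each label column is expanded to indicators over
  the response's level set, frozen at training time, with the first level
  as dropped reference. Labels outside the frozen set encode as all-zero
  with a warning. Modal-category ties break to the lexicographically
  smallest label — deterministic and documented.
- **Failure policy.** A cell whose fit errors is recorded and skipped;
  training continues (a 48-learner grid should survive one fragile
  method). A learner whose cells all fail is dropped with a warning; a
  learner with partially failed cells cannot give a complete meta-feature
  column and is excluded from the meta design, again with a warning.
- **Degenerate inputs.** Constant meta-feature columns are legal (the
  linear meta-learner then reduces to the training mean); per-fold mode
  with a within-fold-constant column makes the meta design rank-deficient,
  which the linear backend tolerates but is worth avoiding.

## The synthetic test bed

`simulate_regression(n, p, n_causal, snr, seed)` draws X from independent
standard normals, sets the signal to the sum of the first `n_causal`
features plus the products of neighboring causal pairs (all unit
coefficients), and adds Gaussian noise with
`noise_sd = sd(signal)/sqrt(snr)`:

- `snr` is interpreted as var(signal)/var(noise) — the only reading with
  a checkable invariant; with the realized-signal scaling the ratio is
  exact by construction, and the realized noise agrees within Monte-Carlo
  error.
- With additive independent noise, cor(signal, Y) = sqrt(snr/(1+snr));
  at the default `snr = 4` this is sqrt(0.8) ≈ 0.894, the ceiling any
  predictor can approach on this generator.
- Interactions are restricted to neighbors *within the causal block*
  (19 pairs at the defaults n_causal = 20): variables outside the block
  are declared non-causal, so giving them interaction effects would
  contradict their zero coefficients. The alternative reading (all p−1
  neighboring pairs) is one code change away in `latent_signal()`.

`simulate_classification()` bins the same latent response at quantiles
into ordered categories with deliberately unequal default bin
probabilities (proportional to 1:K), so minor classes exist — the regime
where classifiers that ignore rare categories are punished.

What the generator does *not* emulate: correlated features (linkage
disequilibrium in genotype matrices), heavy-tailed noise, missing values,
and categorical predictors. Passing tests on this generator demonstrate
the machinery's correctness and the ensemble's behaviour under a known
signal, not performance on real genomic or clinical data.

## Benchmark design

`run_benchmark()` compares the full stacking pipeline against each base
method run standalone, on identical simulated train/test pairs per
replicate. A standalone comparator with a multi-row grid selects its
hyperparameter row by out-of-fold CV accuracy on the training set, then
refits that row on the full training data — the ordinary single-model
workflow a practitioner would run through a tuning wrapper. Using CV
rather than test-set selection keeps the comparator honest; using a
single final fit (not fold-averaging) preserves the contrast with
stacking.

The built-in `default_regression_scenario()` is a reduced version of the
simulation design above: 400 training and 400 test samples, p = 100,
20 causal features, snr = 4, 5-fold CV, five method families (random
forest, gradient boosting, radial SVM, elastic net, PLS) on small grids —
12 base learners — with an elastic-net meta-learner. These sizes were
chosen once as the package's standard test bed: large enough that the
interaction signal is learnable and method rankings are stable, small
enough to run the 10-replicate benchmark on a single CPU in minutes. The
package's checks assert the distributional property the ensemble is
expected to show here — stacking's mean test correlation at least the
average of the standalone methods' means, and within 0.05 of the best
single method in most replicates — not a fixed accuracy value.

## Design questions that were genuinely open

- **Per-fold meta-training rows.** "Trained using the predicted values of
  each fold separately" is implemented literally: meta-fit f uses fold
  f's own out-of-fold rows, so each training row enters exactly one
  meta-fit (a partition, asserted in tests). The complement reading
  (fit f on all folds but f) would correlate the `nfold` meta-fits and
  blur the contrast with pooled mode.
- **Fold stratification.** Folds are simple random by default; for
  classification, `stratify = TRUE` deals samples within class so class
  frequencies are preserved per fold while overall sizes still differ by
  at most one. Unstratified is the default because the pooled behaviour
  of the procedure is defined without reference to class balance.
- **Per-fold classification aggregation.** Averaging is undefined for
  labels, so per-fold meta predictions are majority-voted with the same
  lexicographic tie-break as the per-learner aggregation.

## Limitations

- Base learners are adapters over established estimator packages; the
  registry passes hyperparameter names through verbatim, so an invalid
  name surfaces as that package's error (recorded per cell by the failure
  policy rather than aborting the run).
- Meta-learners needing at least two design columns (the elastic net
  backend) cannot sit on a single base learner; use the `linear`
  meta-learner there.
- No repeated/nested CV, no prediction intervals, no probability-based
  classification meta-features, no automatic hyperparameter search —
  grids are fixed a priori by design.
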