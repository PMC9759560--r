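---
title: "Ensemble encoding models for novel individuals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble encoding models for novel individuals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visens)
```

## The problem

Visual encoding models predict a brain region's response to a stimulus.
Accurate per-subject models need very large stimulus–response datasets
(tens of thousands of image–response pairs), which only densely-sampled
fMRI studies of a handful of individuals can provide. `visens` implements
an ensemble strategy for the opposite situation: a *novel* subject from
whom only a few hundred image–response pairs can be collected. The novel
subject's predicted response to stimulus $S$ is modeled as a linear
combination of the predictions of reference subjects' densely-trained
encoding models,

$$
\mathrm{LE}_i(S) \;=\; \beta_{i,0} \;+\; \sum_{j \in N_{\bar{i}}} \beta_{i,j}\,\hat r_j(S),
$$

where $\hat r_j(S)$ is reference subject $j$'s model prediction,
$N_{\bar i}$ indexes the reference subjects (excluding $i$ itself for
in-cohort, leave-one-out use), and the coefficients are fitted by ordinary
least squares against subject $i$'s *single-trial* measured responses on a
random sample of training stimuli. Two baselines bracket it: the *average
ensemble* (unweighted mean of reference predictions; needs no data from
the new subject) and per-subject *readout models* trained directly on the
new subject's data, either from random initialization ("scratch") or
warm-started at the group average of the reference readouts ("finetuned").

Models are judged on two axes:

* **prediction accuracy** — Pearson correlation between predicted and
  measured responses over a shared test set; and
* **prediction consistency** — whether a model *preserves inter-individual
  differences*: the correlation, across all subject pairs and regions,
  between the pairwise inter-subject correlation (ISC) of predictions and
  the ISC of measurements.

The average ensemble is the cautionary tale motivating the second axis:
its leave-one-out predictions are nearly identical across query subjects,
so its ISC-predictions are all 1 or near 1 and its consistency is
reported as undefined — accurate, but not personalized.

## What is modeled, and what is not

Real encoding models in this setting extract image features with a deep
convolutional network and map them to a region's mean response through a
linear readout. The feature extractor is far outside desk scale, so in
`visens` features are abstract fixed vectors: every stimulus carries a
$d$-dimensional feature vector and a readout is just weights plus bias.
The readout-training logic is preserved: mini-batch gradient descent on
mean squared error (batch size 32), validation-based early stopping on
the Pearson correlation between predictions and repeat-averaged
validation responses, and the two initialization modes. This is the one
intentional structural deviation, and it means results here say nothing
about feature learning — only about the ensemble, training-size, and
evaluation machinery.

Likewise out of scope: image synthesis (the generator loop that produces
activation-maximizing stimuli), voxel-level modeling, and fMRI
preprocessing. Responses enter the package already aggregated to one
scalar per (subject, region, stimulus, repeat).

## Data model and splits

A cohort holds a stimulus set (features, optional `animal_face` /
`human_face` / `other` labels, a shared flag) and a long table of
single-trial responses. Splits follow the repeat-handling rules of
densely-sampled designs:

* **training** points are single trials — responses to the same stimulus
  are never averaged;
* **validation** and **test** responses are the mean of *exactly two*
  repeats; when a stimulus was seen three times, two of the three trials
  are chosen at random (seeded). Averaging always exactly two keeps the
  signal-to-noise ratio of averaged responses consistent across stimuli
  and subjects;
* **test** stimuli are drawn from the shared set and are identical across
  subjects, so pairwise ISCs are computed over a common stimulus set.

Whether the two-of-three selection should be seeded is not specified
anywhere we know of; we seed it, which makes splits exactly reproducible.

## The synthetic cohort generator

Every pipeline stage is testable against a Gaussian linear generative
model with the two axes the analyses rest on — a shared stimulus-driven
signal and subject-idiosyncratic structure:

* features $f(S) \sim \mathcal N(0, I_d)$, i.i.d. across stimuli;
* per region, a shared readout $w_g$ with $\lVert w_g\rVert = \sigma_g$
  (direction uniform on the sphere) and per-subject offsets
  $u_j \sim \mathcal N(0, \sigma_u^2/d\, I_d)$;
* noiseless signal $r_j(S) = (w_g + u_j)\cdot f(S)$; each repeat measures
  $r_j(S) + \varepsilon$, $\varepsilon \sim \mathcal N(0,
  \sigma_\varepsilon^2)$ (a Student-t option provides heavier tails);
* optionally, the last subject's signal is a *known* mixture
  $\beta_0^* + \sum_j \beta_j^* r_j(S)$ of the others', giving ground
  truth for coefficient-recovery tests.

Fixing $\lVert w_g \rVert$ exactly (rather than drawing it Gaussian)
makes every region carry the same shared-signal variance. With Gaussian
draws at small $d$, regions differ substantially in realized
signal-to-noise, and because consistency pools subject pairs across
regions, that region-level variation couples ISC-prediction to
ISC-measurement for *any* model — including the average ensemble, whose
consistency should be a degenerate lower bound. The fixed-norm choice
removes this artifact at the source.

### Default parameters

The defaults (`synthetic_config()`) are the study conditions for all
default-scale results: 8 subjects, 4 regions, 1000 stimuli of which 250
are shared (the remainder assigned round-robin as subject-exclusive), 3
repeats, $d = 12$, $\sigma_g = 1$, $\sigma_u = 0.2$,
$\sigma_\varepsilon = 0.6$. Two considerations fix the less obvious
numbers:

* $\sigma_u/\sigma_g = 0.2$ keeps subjects similar enough that reference
  models transfer (the regime in which an ensemble of other subjects'
  models can match a subject's own densely-trained model), yet the
  pairwise idiosyncratic overlaps $u_i \cdot u_k$ — the *pattern* of
  inter-individual differences — remain detectable above the sampling
  noise of ISCs computed over a 100-stimulus test set.
* $d = 12$ is deliberately small relative to the 7 reference subjects of
  a leave-one-out ensemble: the span of the reference readouts can then
  represent roughly $7/12$ of a query's idiosyncratic component, which is
  what lets consistency *grow* with ensemble size. With $d \gg$ the
  number of references, idiosyncratic structure is unrepresentable and
  consistency degenerates to noise.

Each generator concern (features, labels, readouts, noise) draws from its
own named RNG stream derived from the seed, so changing the number of
repeats does not perturb the features.

What the generator does **not** emulate: naturalistic image statistics,
hemodynamics and preprocessing artifacts, voxel-level structure,
heterogeneous repeat counts, and — because the measurement noise is
homoscedastic Gaussian by default — heavy-tailed trial-to-trial
variability. Passing tests therefore demonstrate correctness and the
qualitative phenomena of the method under a clean generative model, not
performance claims about any real dataset.

## Estimation and numerical choices

* **Ensemble OLS.** The design matrix (intercept plus one column per
  reference prediction) is solved by SVD-based minimum-norm least
  squares. Full-rank designs give exactly the normal-equations solution;
  rank-deficient designs (duplicated or constant reference predictors are
  plausible) produce the minimum-norm solution with a warning rather than
  an error. No standardization is applied — reference predictions share
  units by construction — and no regularization is used; with 7
  references and training sizes of 10–50 the fit can be unstable, which
  is visible in the coefficient-recovery error at `n_train = 30`.
* **Readout training.** Plain mini-batch gradient descent by default
  (an AdamW-style adaptive option is available behind the same config);
  learning rate 0.05, batch size 32, at most 300 epochs, patience 10
  validation checks, validation evaluated every epoch *and at epoch 0*,
  so a perfect warm start is never destroyed by training. The weights at
  the best validation correlation are returned. Zero-variance validation
  responses make the correlation undefined; training then falls back to
  the fixed epoch budget and the trace records `NA`.
* **Random initialization** is $w \sim \mathcal N(0, 1/d)$, bias 0.
* **Consistency inference.** ISC upper triangles are pooled across
  regions (per-region mode is available), giving
  $\text{regions} \times k(k-1)/2$ points for $k$ subjects. The
  permutation test permutes the ISC-measurement vector against the fixed
  ISC-prediction vector; the one-tailed p-value uses the add-one
  estimator $(1 + \#\{r_\text{perm} \ge r_\text{obs}\})/(1 + B)$ with
  $B = 10{,}000$ by default, then a caller-supplied Bonferroni factor.
  (For 8 subjects the pair count is $8 \times 7/2 = 28$ per region; an
  often-quoted "$(7\times 8)/2 = 23$" is arithmetically inconsistent and
  we do not reproduce it.)
* **Degenerate consistency.** A pooled ISC vector with standard
  deviation below `degenerate_tol = 0.002` is treated as constant and
  the consistency flagged undefined instead of returning a number.
  Rationale: Pearson correlation is scale-free, so a vector of
  ISC-predictions that are "all 1 or near 1" (leave-one-out average
  ensembles produce spreads around $3\times 10^{-4}$) would otherwise
  yield a spurious finite-sample correlation through the shared test
  stimuli; models that retain subject structure produce spreads an order
  of magnitude above the threshold ($\gtrsim 10^{-2}$).
* **Noise ceilings.** Across-subject: correlation between a subject's
  averaged test responses and the mean of the other subjects'. Within-
  subject, two styles: three repeats (average of two vs the third; the
  two lowest repeat indices are averaged, deterministically) or two
  repeats (first vs second). Under the generator these have closed
  forms, e.g. two-repeat within-subject NC
  $\rho = (\sigma_g^2+\sigma_u^2)/(\sigma_g^2+\sigma_u^2+\sigma_\varepsilon^2)$,
  used as independent oracles in the tests.
* **Classical tests.** Wilcoxon matched-pairs signed-rank (exact
  distribution for $n \le 25$ without ties or zeros — at 8 subjects the
  exact null is the right one), Friedman over model columns with
  Benjamini–Hochberg-adjusted pairwise signed-rank post hocs, and
  Welch's unequal-variance t. These call the standard R implementations;
  the test suite verifies them against exhaustive sign-flip enumeration,
  the rank formula, and the hand-worked step-up procedure. A fully tied
  Friedman table (tie-corrected statistic 0/0) is reported as statistic
  0, p 1.
* **Ties in top-k rankings** are broken by lexicographic stimulus id, so
  rankings are total and reproducible. The preference ratio over a top-k
  set is $(n_\text{animal} - n_\text{human})/(n_\text{animal} +
  n_\text{human})$ — the denominator is the labeled count, not $k$ — and
  a top-k set containing neither label is dropped with a warning.

## Problem sizes

Default-scale analyses use the 8-subject, 4-region cohort with a
100-stimulus shared test set and 50 validation stimuli per subject;
ensembles are fitted on 300 single-trial samples (for a dense reference
set of 20,000 pairs that is a 1.5% fraction). Monte-Carlo properties are
evaluated over 20 seeds (ordering and consistency-trend results), 50
seeds (noise-ceiling closed forms, against configs with $d = 100$ and
1000 stimuli so the seed average pins down the expectation), and 1000
replicates of 1000 permutations each for the calibration of the
permutation test. These sizes were chosen so the full suite documents
the method's behavior while remaining comfortably runnable on a laptop.

## Worked example

```{r example}
cfg <- synthetic_config(seed = 42)
gen <- generate_cohort(cfg)
sp <- build_split(gen$cohort, n_val = 50, n_test = 100, seed = 7)

refs <- oracle_readouts(gen$ground_truth, "FFA1")
ens <- build_loo_ensembles(refs, sp, "FFA1", n_train = 300, seed = 7)
te <- test_data(sp, "FFA1")

acc <- sapply(gen$cohort$subject_ids, function(s) {
  c(reference = prediction_accuracy(predict(refs[[s]], te$x), te$y[, s]),
    ensemble = prediction_accuracy(predict(ens[[s]], refs, te$x), te$y[, s]))
})
round(rowMeans(acc), 3)
```

The linear ensemble, fitted on 300 single trials of each held-out
subject, sits within a few hundredths of the densely-trained reference
readouts' accuracy.

## Known limitations

* The generator is linear-Gaussian; none of the conclusions transfer
  automatically to real fMRI noise structure or to learned nonlinear
  features.
* Unregularized OLS with 7 references is noisy below ~50 training
  samples; a ridge variant would stabilize it but is deliberately not the
  default, to keep the fitted object the plain OLS ensemble.
* The consistency degeneracy threshold is a convention; analyses near the
  boundary (ISC spreads of order $10^{-3}$) should use
  `degenerate_tol` explicitly and report it.
* Within-subject noise ceilings assume the chosen repeats are exchangeable;
  the deterministic "two lowest indices" rule matters only if repeats
  drift systematically, which the generator does not emulate.
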