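---
title: "Simulating meaning-space dimensionality with a deep belief network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating meaning-space dimensionality with a deep belief network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model in brief

`harmonium` implements a simulation framework from computational
psychiatry that operationalises a dimensional account of psychopathology
— the idea that rigid, poorly modulable meaning-making corresponds to a
representational space dominated by a few invariant "primary" dimensions,
with little weight on context-sensitive "secondary" dimensions. The
simulation translates those constructs into measurable properties of a
neural network:

* a **cognitive process** is simulated by a letter-classification task;
* the **position on a normality–psychopathology continuum** is simulated
  by the classification performance of a trained network;
* the **dimensionality of the phase space of meaning** is simulated by
  the PCA eigenspectrum of the network's internal computational dynamics
  (ICD) — the trajectory of its deep hidden layer's activations across
  unsupervised learning.

The hypothesis under test is directional: performance should *fall* with
the weight of the primary dimensions (`wght_pd`, variance explained by
PC 1–2) and *rise* with the weight of the secondary dimensions
(`wght_sd`, variance explained by PC 3–6).

## Pipeline

1. **Stimuli** (`build_training_set()`, `build_test_set()`). 30×30
   grayscale letter images feed a 900-unit input layer. Two training
   conditions with equal trial counts but different entropy:
   * TC-HE (high entropy): 9 fonts × 3 styles = 27 versions of each of
     the 26 letters, 702 images;
   * TC-LE (low entropy): 2 fonts, normal style only — 52 unique images
     replicated cyclically to 702.
   The test set uses 4 held-out fonts × 3 styles (312 images) with every
   pixel luminosity halved, which makes recognition harder and exposes
   overfitting.
2. **Unsupervised learning** (`train_dbn()`). A two-layer deep belief
   network (900–400–800) trained greedily by one-step contrastive
   divergence, 40 epochs × 120 mini-batch learning events per layer.
3. **Read-out** (`train_readout()`, `evaluate_readout()`). A 26-unit
   logistic output layer trained by the delta rule on the frozen layer-2
   representations simulates the behavioural response; per-letter
   accuracy on the test set is the performance measure.
4. **Dynamics** (`icd_recorder()`, `microstage_sd()`). After every
   layer-2 learning event the recorder presents each letter's probe
   images and stores the 800 mean-field activations — an 800 × 4,800
   matrix per letter. Non-overlapping windows of 20 adjacent cycles are
   condensed to per-neuron sample SDs: an 800 × 240 micro-stage matrix
   that foregrounds local variation of the learning trajectory.
5. **Dimensionality** (`pca_eigenspectrum()`,
   `dimensionality_indicators()`). Each micro-stage matrix is analysed
   by correlation-scale PCA (micro-stages as variables, neurons as
   observations); `wght_pd` and `wght_sd` summarise the spectrum.
6. **Inference** (`standardized_regression()`, `welch_t()`,
   `paired_t()`). Per-letter accuracy is regressed on the z-scored
   indicators (plus each letter's perimetric complexity in Study 1);
   preliminary checks compare active-pixel counts, entropy profiles and
   condition accuracies.

`run_study1()` executes the two-network design (52 letter-by-network
rows); `run_study2()` the 20 + 20 replica design analysing letters A and
M only (80 rows, no complexity covariate).

```{r}
library(harmonium)
study <- run_study1(study_config(1, master_seed = 1))
print(study)
```

## What the synthetic stimuli emulate — and what they do not

The studies this design follows used unnamed desktop fonts. Shipping
font files would make rendering platform-dependent, so the package draws
letterforms procedurally: every letter has a stroke skeleton, and each
of 15 registry "fonts" applies its own parameters (width, stroke weight,
slant, serifs, bowl squareness) plus a deterministic smooth quadratic
warp of the skeleton seeded per font — its typeface identity. Styles are
transformations (italic = extra shear, bold = 1.9× stroke). Rendering
is a pure function of (letter, font, style): bitwise reproducible on any
platform, no downloads.

Consequences worth keeping in mind:

* The *relative* design properties hold by construction: conditions of
  equal size, high- versus low-entropy variability, disjoint test fonts,
  halved test contrast.
* *Absolute* pixel statistics (mean active pixels, the huge-df t
  statistic of the information check) are font-dependent and are not
  expected to match any particular published value; the package checks
  their direction only.
* Procedural fonts share stroke topology across the registry, so
  inter-font variation is probably milder than between arbitrary real
  typefaces. Passing tests show the mechanism — entropy-dependent
  generalisation and its coupling to ICD dimensionality — not
  psychophysical fidelity to human letter perception.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| epochs × batches | 40 × 120 | the cycle schedule; 4,800 recorded cycles |
| CD-1 learning rate | 0.05 | conventional for logistic RBMs of this size |
| momentum | 0 (plain CD-1) | momentum inflates cycle-to-cycle churn and hence the apparent ICD dimensionality; a 0.5 → 0.9 schedule is available via `train_config()` |
| weight decay | 2e-4 | mild L2, keeps weights finite |
| weight init | N(0, 0.01²) | small-weight regime, biases 0 |
| read-out | delta rule, lr 0.1, ≤500 epochs, plateau 1e-5/10 | the literal associative rule, squared error on logistic outputs |
| micro-stage window | 20 cycles | 4,800/20 = 240 micro-stages |
| active-pixel / binarization threshold | 0.5 | discounts anti-aliasing halo |
| indicator components | PC 1–2, PC 3–6 | fixed a priori; the package recomputes the supporting quantile and Kaiser analyses each run |

The unsupervised hyperparameters are *declared* conventions: the design
they implement fixes only the architecture (900–400–800), the schedule
(40 × 120) and the training sets. All are overridable through
`train_config()` / `readout_config()`.

## Numerical and design choices

* **Greedy layer-wise schedule, recording during layer-2 training.** The
  4,800-cycle count is only coherent for a single 40-epoch schedule over
  the recorded layer; layer 1 is trained first and then frozen.
* **Mean-field probes.** Recorded activations (and the read-out's
  inputs) are deterministic logistic probabilities, not binary samples —
  evaluation is deterministic given the weights. Hidden *training*
  states are sampled, per standard CD-1 practice. Recording the sampled
  binary states instead is available (`icd_recorder(sample_states =
  TRUE)`) but mixes learning dynamics with Bernoulli noise whose
  magnitude depends on how many probe versions are averaged, which
  biases comparisons between conditions with different version counts.
* **Letter probes.** How several versions of a letter collapse into one
  trajectory matrix is underdetermined. The recorder computes the
  micro-stage SD for each unique training version separately and
  averages the SD matrices (`version_collapse = "mean_sd"`): this
  preserves each unit's variability level, whereas averaging the
  activations first (`"mean_activation"`, also available) cancels
  version-specific dynamics before the SD is taken and flattens the
  spectrum's leading components. Study 2 probes are a single version
  sampled once per condition with the master seed, where both collapses
  coincide.
* **Mini-batch partition.** 702 is not a multiple of 120, so epochs use
  near-equal batches (sizes differ by at most one, every item exactly
  once) to keep "120 learning events per epoch" exact.
* **TC-LE replication remainder.** 702 = 13 × 52 + 26: the cyclic fill
  repeats the first 26 unique images once more, in fixed order.
* **Correlation-scale PCA, micro-stages as variables.** The
  eigenvalue-greater-than-1 retention rule presupposes the correlation
  scale, and this orientation is the one for which single-digit Kaiser
  counts are meaningful (800 observations, 240 variables). Zero-variance
  micro-stage columns are dropped with a warning and proportions
  renormalized. The alternative orientation can be obtained by
  transposing the matrix before `pca_eigenspectrum()`.
* **Perimetric complexity as printed.** The complexity control covariate
  is area/perimeter of the binarized glyph (exposed pixel edges,
  4-connectivity) — note this *inverts* the conventional Pelli form
  perimeter²/area, which is available via `pelli = TRUE`. The per-letter
  covariate is the mean over all 29 unique training renderings of the
  letter.
* **Lower median for the Kaiser cutoff** on even-length collections, so
  the cutoff is always an observed count.
* **Paired accuracy check.** The condition-effect check is a classical
  paired t-test over the 26 letters (df = 25); a "Welch paired" test is
  a contradiction in terms, and the paired form is what the printed
  degrees of freedom identify.
* **Sample SDs everywhere** (n − 1), matching mainstream statistical
  software.
* **Seeds.** Network i trains with `master_seed + i`, its read-out with
  `master_seed + i + 1000`, probe sampling with the master seed itself.
  Training is bitwise reproducible; the compiled CD-1 kernel draws its
  hidden samples from R's own random stream.

## Degenerate inputs

* An entropy profile of identical images returns the single-component
  profile with a warning.
* `pca_eigenspectrum()` refuses matrices with fewer than two
  non-constant columns.
* Micro-stage reduction requires the window to divide the cycle count;
  trailing partial windows in a streaming recorder are dropped with a
  warning.
* Zero-variance t-test inputs and collinear or constant predictors are
  errors, named after the offending predictor.

## Problem sizes and runtime

Full Study 1 (two networks, all-letter recording) takes a few minutes on
one CPU; the replica study scales linearly in the number of networks, so
the packaged examples and tests use the full schedule but, where many
replicas are involved, a reduced replica count (e.g. 5 per condition),
which already reproduces the directional regression result. The complete
20 + 20 design is a single `run_study2(study_config(2))` call if you
have the better part of an hour.

## Known limitations

* One architecture, one task, one stimulus family, two training
  conditions — the design probes a mechanism, not its generality.
* Absolute accuracy levels depend on the procedural font registry;
  different registries shift them, though the HE > LE ordering is
  robust across seeds.
* Once the low-entropy network converges, its recorded trajectory
  decays to a numerically tiny jitter; standardizing those late, nearly
  silent micro-stage columns lets the correlation-scale PCA spread
  noise into mid-spectrum components. This inflates the Kaiser count of
  converged networks and dilutes the dimensionality contrast between
  conditions — most visibly with single-image probes, where the
  replica-study regression recovers the negative primary-dimension
  slope only unreliably at small replica counts. Column-filtering
  variants (resolution thresholds on SD level or variance) were
  examined and rejected: no single rule improved the spectra without
  distorting the regression, so the package keeps the plain
  numerically-zero-variance rule and reports what the dynamics give.
* OLS ignores the clustering of letters within networks (by design,
  matching the original analysis); standard errors in the replica study
  are therefore optimistic.
* The secondary-dimension range (PC 3–6) is fixed a priori; runs whose
  Kaiser cutoff differs will still be summarised over PC 3–6.
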