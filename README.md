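# harmonium

Simulation framework linking a neural network's **internal computational
dynamics** to its task performance — a computational test of the idea,
from dimensional models of psychopathology, that rigid meaning-making
corresponds to a representational space dominated by a few invariant
*primary* dimensions with little weight on context-sensitive *secondary*
dimensions.

The package is for computational-psychiatry and cognitive-modelling
researchers who want the whole pipeline as tested, seedable R code:
stimulus synthesis, unsupervised deep-network training, dynamics
recording, eigenspectrum analysis, and the inferential layer.

## What it computes

A deep belief network (900–400–800 logistic units) learns a generative
model of letter images by one-step contrastive divergence (40 epochs ×
120 mini-batch *cycles*); a delta-rule read-out on the 800-unit layer
simulates the behavioural response. Two training conditions share size
but differ in entropy: **TC-HE** (9 fonts × 3 styles, 27 versions per
letter) and **TC-LE** (2 fonts, one style, replicated to match). Test
accuracy is scored on 4 held-out fonts at halved contrast.

During layer-2 learning the activation of every hidden neuron is
recorded at each of the 4,800 cycles, per letter. Windows of 20 adjacent
cycles are condensed to per-neuron standard deviations, giving an
800 × 240 *micro-stage* matrix whose correlation-scale PCA yields the
dimensionality indicators

* `wght_pd` — variance explained by PC 1–2 (weight of the primary
  dimensions),
* `wght_sd` — variance explained by PC 3–6 (secondary dimensions; the
  upper index is the Kaiser-like median cutoff, eigenvalue > 1 in at
  least half the PCAs).

Per-letter accuracy is then regressed on the z-scored indicators (plus
perimetric complexity as a letter covariate in Study 1):

```
accuracy ~ β0 + β1·z(wght_pd) + β2·z(wght_sd) [+ β3·z(PeCo)]
```

The directional result of interest is β1 < 0 and β2 > 0: performance
falls as the primary dimensions saturate the dynamics and rises with the
weight of the secondary dimensions.

## Worked example

```r
library(harmonium)

study <- run_study1(study_config(1, master_seed = 1))
print(study)
#> <psm_study> Study 1: 2 networks, 52 indicator rows
#>   mean per-letter accuracy: TC-HE 0.869, TC-LE 0.561
#>   Kaiser-like median cutoff: 9; 5th pct wght_pd: 67.6%
#> <std_regression> n = 52, adj R^2 = 2.36%
#>   (Intercept)  +0.7147 +/- 0.0318  (p = 4.239e-27)
#>   wght_pd      -0.0702 +/- 0.0377  (p = 0.06871)
#>   wght_sd      +0.0050 +/- 0.0368  (p = 0.8928)
#>   peco         -0.0089 +/- 0.0334  (p = 0.791)
```

Read: the high-entropy network generalises well (0.87) while the
low-entropy network overfits its two fonts (0.56); across the 52
letter-by-network rows, accuracy falls by ~0.07 per SD of `wght_pd`
(negative, as hypothesised) and moves weakly positively with `wght_sd`.
The intercept equals the grand mean accuracy exactly (standardized
predictors are mean-zero). Two principal components carry about two
thirds of the micro-stage variance in 95% of the PCAs, and the
Kaiser-like median cutoff sits at component 9 for this seed.

Other entry points: `run_study2()` (the 20 + 20 replica design over
letters A and M), `run_preliminary_checks()` (active-pixel information
check, entropy-profile comparison, paired condition effect),
`export_stimuli()` / `export_study()` for PNG + CSV artefacts, and a
thin CLI at `inst/scripts/harmonium-cli.R`
(`Rscript harmonium-cli.R study1 --seed 1 --out out/`).

The methods vignette (`vignettes/methods.Rmd`) documents the model,
the procedural font registry, parameter defaults and numerical choices.

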