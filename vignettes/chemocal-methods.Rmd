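---
title: "Models and design choices in chemocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in chemocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chemocal quantifies four co-occurring analytes — antipyrine (ANT),
benzocaine (BEN), antipyrine impurity A and p-aminobenzoic acid (PABA) —
from full UV spectra over 250.0–315.0 nm (0.2 nm steps, 326 points).
This vignette explains the models, the simulator that stands in for the
unpublished instrument data, the tunable parameters, and the places
where the design was genuinely open, with the reasoning behind each
choice. Everything quantitative said here is computed by the test suite
or the `analysis/` scripts; nothing is quoted from elsewhere.

## The data model and what the simulator emulates

Mixture absorbance follows Beer–Lambert additivity:
$A = C S^\top + E$, with $C$ the samples × 4 concentration matrix
(µg mL⁻¹), $S$ the wavelength × 4 pure absorptivities and $E$ additive
homoscedastic Gaussian noise. The simulator's pure spectra are sums of
Gaussian bands — documented constants, not fits to any measured
spectrum, because the real spectra are unpublished. They were chosen
once to satisfy, jointly, the features that define this analytical
problem:

* strong mutual overlap of all four bands across the window;
* near-collinearity of ANT and its impurity (Pearson r = 0.956 on the
  default grid), the feature that defeats univariate methods;
* a distinct short-wavelength shoulder on the impurity (253 nm) so that
  the impurity is not *also* collinear with PABA — with a double
  collinearity the impurity channel is unidentifiable at the working
  noise level for every calibration model, which contradicts the
  validated performance the workflow is meant to emulate;
* peak mixture absorbances near but below 1.5 AU at the top of the
  calibrated ranges (about 1.35 AU), mirroring the photometric ceiling
  that motivated restricting the concentration ranges in the first
  place. `simulate_spectra()` warns, rather than errors, above 1.5 AU:
  high absorbance is a design concern, not invalid arithmetic.

Noise defaults to `additive_sd = 0.002` AU, a typical photometric
repeatability for a bench-top double-beam instrument; it is a parameter
of `noise_model()`. Proportional (intensity-dependent) noise, stray
light, baseline drift and wavelength-registration error are *not*
emulated. Passing tests therefore demonstrate correctness of the
algorithms under ideal linear-additive conditions, not robustness of the
laboratory method to instrumental artefacts.

## The calibration design

`brereton_design()` builds the five-level four-factor design as a centre
run plus the 24 cyclic width-4 windows of a balanced generator sequence,
so consecutive factor columns are one-step rotations of each other. The
shipped five-level generator is a documented constant with all lag-1..3
circular autocorrelations exactly zero, giving exactly orthogonal coded
columns; each level appears five times per column and all 25 runs are
distinct. For other odd level counts the generator is constructed as a
deterministic Eulerian circuit over the level digraph (every ordered
level pair once, the centre run supplying the (0,0) pair), which
guarantees balance and exact lag-1 orthogonality.

The 11 default validation rows are the runs whose mapped concentrations
reproduce the printed validation mixtures; the assignment ships as a
constant (`default_validation_rows()`) because only the validation
concentrations, not the full run order, are recoverable from the
published tables.

## PLS

`fit_pls()` is classical NIPALS PLS2: scores and loadings extracted
sequentially with deflation of both blocks, all four analytes modelled
jointly, and the regression matrix $B = W (P^\top W)^{-1} Q^\top$.
Both $X$ and $Y$ are mean-centred; whether the response block should be
centred is not dictated by the method description, but centring both is
standard bilinear practice and makes the intercept exact.

Model size is chosen by leave-one-sample-out cross-validation
(`loo_cv()`) with the Haaland–Thomas rule (`select_n_lv()`): the
smallest $h$ with $\mathrm{PRESS}(h) \le F_{0.75}(n,n)\cdot
\min_h \mathrm{PRESS}$, ties resolving to the smaller model. The 0.75
probability level is the conventional chemometrics choice; it is an
argument, not a constant. On the simulated study the rule selects 4
latent variables — the chemical rank of a four-component linear system.
The 7 reported for the real instrument data reflects additional
instrumental variance the simulator deliberately does not emulate, so
that number is not a package target.

Degenerate inputs: a zero response block yields $B = 0$ rather than an
error; deflation stops early if either block is exhausted, leaving
all-zero trailing components.

## The neural network

`train_ann()` fits a three-layer 326–H–4 regression network
(`n_hidden = 5` by default, scanned over 2–5 in the published tuning
narrative) for 50 full-batch epochs. Four design points were genuinely
open and were settled by implementation evidence (all reproducible with
the configuration options):

* **Trainer.** Plain first-order batch descent cannot fit a
  326-channel collinear problem in 50 epochs at any fixed step size —
  in our experiments it remains far from convergence even after tens of
  thousands of epochs. The default trainer is therefore full-batch
  Levenberg–Marquardt backpropagation, the standard second-order
  trainer for small chemometric networks, which converges within the
  50-epoch budget; the quoted training rate 0.1 is used as the initial
  adaptive damping (`learning_rate`), and plain gradient descent
  remains available via `algorithm = "gradient-descent"`.
* **Input scaling.** Inputs are mapped to [0, 1] by a *single global*
  affine transform of the spectra block. Per-wavelength scaling — the
  other common convention — divides each channel by its own range,
  which at low-absorbance wavelengths amplifies pure noise up to full
  scale and measurably degrades external prediction; a global transform
  preserves the photometric weighting of the data. Outputs are scaled
  per component (their ranges differ by an order of magnitude) and
  inverted at prediction.
* **Hidden transfer.** Linear by default: Beer–Lambert mixing is
  linear, and a linear-transfer network gives the trainer an exactly
  solvable landscape while retaining the network parameterisation;
  `hidden_activation = "sigmoid"` is available for curved response
  surfaces.
* **Initialisation.** Uniform (−0.5, 0.5) scaled by 1/√(fan-in), from
  `seed`; the scaling keeps initial activations in a responsive range
  regardless of layer widths, and the seed makes training bit-exact
  reproducible.

Divergence (a non-finite loss) is reported as an error naming the
epoch. `scan_hidden()` retrains one network per width from a shared
seed; on the simulated study the training error collapses once the
width reaches the chemical rank (4–5) and plateaus beyond, matching the
published sizing narrative.

## MCR-ALS

`fit_mcr()` alternates exact conditional least squares on
$D = C S^\top + E$: contributions given spectra, then spectra given
contributions, with non-negativity enforced by NNLS per row/column
(`nonneg_method = "clip"` offers the fast approximate fallback).
Iteration stops when the lack of fit,
$\mathrm{lof} = 100\sqrt{\sum (D - CS^\top)^2 / \sum D^2}$,
changes by less than `tol` (default 0.1 % relative) or at `max_iter`
(default 50). With exact NNLS and no upper bounds each half-step cannot
increase the residual, so the lof trace is monotone; explained variance
follows the identity $r^2 = 100 - \mathrm{lof}^2/100$.

Decisions worth recording:

* **Raw data.** The factorisation runs on raw (uncentred) absorbances.
  Mean-centred spectra contain negative entries that a non-negative
  bilinear model cannot represent, so the stated preprocessing is
  applied to the regression models only.
* **Initialisation.** The default study initialises from the
  pure-standard spectra — in this laboratory situation every analyte is
  available as a standard, which is also what makes the resolved-versus-
  pure comparison meaningful. A blind purest-sample initialiser
  (`initial_spectra()`, a greedy Gram-determinant criterion in the
  spirit of SIMPLISMA) is provided and tested, but with four heavily
  overlapped components a blind start converges to a rotated solution
  whose impurity channel is quantitatively unusable; rotational
  ambiguity is intrinsic to bilinear factorisation, not an
  implementation defect.
* **Scale ambiguity and quantification.** Resolved spectra are
  normalised to unit length each iteration (contributions rescaled
  inversely), and quantification goes through a per-component
  straight-line regression of contribution on known concentration over
  the calibration rows (`quantify_mcr()`), inverted for the unknown
  rows — exact for any affine contribution-concentration relationship.
* **Upper bounds.** The optional "lower-than" equality constraint is
  implemented as an elementwise upper bound on contributions, applied
  by projection after each C-step. Bounds are meaningful only when `C`
  carries concentration units (true-scale initial spectra,
  normalisation off), so they default to off. The alternative reading —
  fixing known concentration values — is not implemented.
* **Rank collapse** (a component's contribution becoming all-zero) is
  an error naming the component, never a silent drop.

## Figures of merit and statistics

Recovery is `100 · predicted / actual`; summaries use the sample SD.
Prediction errors are decomposed into bias, SEP (bias-corrected, n−1)
and RMSEP (raw, n), linked by
$\mathrm{RMSEP}^2 = \mathrm{bias}^2 + \mathrm{SEP}^2 (n-1)/n$ — an
identity the tests assert on random data. For detection limits,
`LOD = 3.3 σ/S` and `LOQ = 10 σ/S` with σ taken, by package convention,
as the residual standard deviation of the found-versus-actual line
(n−2 denominator): "SD of the response" admits several readings and
this is the most common pharmacopeial one; σ is an explicit argument of
`lod_loq()` for any other convention. Standard-addition recovery is
total-found over total-nominal, `100 · found/(taken + added)`; the
published spiked-sample recoveries follow no standard formula we could
identify, so they are a documented convention here rather than a
reproduction target.

Method comparison uses the pooled-variance two-sample t (the tabulated
critical value 2.145 at df 14 implies pooling, not Welch) and the
variance-ratio F with the larger variance on top; critical values come
from the exact t and F quantiles at p = 0.05. On simulated data the
variance test flags the calibration as *more* precise than the real
reference assay — an artefact of simulating only 0.002 AU of noise,
worth remembering when reading the comparison table.

## Greenness

`eco_scale()` is deliberately thin: penalty points are data, not logic
— the score is 100 minus their sum, with the conventional tiers (> 75
excellent, 50–75 acceptable, below 50 inadequate). The published item
tables for the proposed water-based method and the two earlier
single-analyte methods ship as a CSV fixture; the pictogram-to-points
derivation behind such tables is outside the package's scope.

## Problem sizes and reproducibility

The default study is intentionally small — 25 mixtures × 326
wavelengths, leave-one-out over 14 samples, networks of at most a few
thousand weights — so the complete pipeline, the test suite and the
analysis scripts all run in seconds. All stochastic stages (noise,
weight initialisation) derive from a single seed in `run_config()`;
`run_study()` is bit-reproducible and the tests assert it.

## Known limitations

* The simulator's band constants are plausible, not measured;
  quantities that depend on the real instrument response (the 7-LV
  choice, absolute LODs, the MCR iteration count) are reproduced in
  kind, not in value.
* Single-response noise model: no heteroscedasticity, drift or stray
  light, so robustness claims do not transfer to real spectra.
* MCR-ALS implements single-block factorisation only; no augmented
  multi-set analysis, closure or unimodality constraints.
* The network is a single-hidden-layer regressor without early-stopping
  monitors or regularisation options beyond the trainer itself.
* Blind MCR initialisation is provided but, on this chemistry,
  quantitatively inferior to the pure-standard start; see above.
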