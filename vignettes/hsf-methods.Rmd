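---
title: "Hybrid spectral fingerprinting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid spectral fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Portable drug-checking spectrometers of the kind `hsfkit` emulates excite a
solubilized sample with a ring of 12 UV LEDs (255--400 nm) and record, for
each LED, the full spectrum reaching the detector between 185 and 655 nm.
Unlike conventional fluorescence spectroscopy, the reflected excitation
line is *kept*: its attenuation with analyte concentration acts as a
diffuse-reflectance "pseudoabsorption" measurement, so each scan combines
an excitation--emission matrix (EEM) with per-LED absorbance information —
a *hybrid spectral fingerprint* (HSF). One scan is 12 blocks of 1516
detector pixels = 18,192 rows of (LED index, emission wavelength,
intensity, integration time, LED brightness).

## The forward model

A compound is a parametric fluorophore: absorption
$\epsilon(\lambda)$ (mL mg$^{-1}$ cm$^{-1}$) and a unit-area emission
profile $f(\lambda)$, both sums of Gaussian bands, plus a quantum yield
$\phi$. A sample is a set of (compound, concentration $c_i$) pairs with
Beer--Lambert absorbance $A(\lambda) = \ell \sum_i \epsilon_i(\lambda)\,c_i$.

For LED $k$ at $\lambda_k$, the expected detector rate is

$$
S_k(\lambda) \;=\;
\underbrace{P_k\, \rho\; G(\lambda;\lambda_k,w)\; 10^{-k_r A(\lambda_k)}}_{\text{reflected excitation line}}
\;+\;
\underbrace{g\,P_k\, \bigl(1 - 10^{-A(\lambda_k)}\bigr) \sum_i w_i \phi_i f_i(\lambda)\; 10^{-k_s A(\lambda)}}_{\text{fluorescence}}
$$

with $G$ a unit-peak Gaussian (FWHM $w$), $\rho$ the solvent/well diffuse
reflectance, $w_i = \epsilon_i(\lambda_k) c_i / \sum_j
\epsilon_j(\lambda_k) c_j$ each component's share of the absorbed light,
$k_r = 2$ the effective double-pass exponent of the pseudoabsorption (light
enters and leaves the well), and $k_s = 0.5$ the secondary inner-filter
exponent (emitted light travels on average half the well). The factor
$1 - 10^{-A(\lambda_k)}$ is the primary inner-filter effect and is what
makes the emission peak *saturate* with concentration; $k_s$ additionally
bends it over at very high absorbance.

$g$ (`emission_gain`, default 50) is the relative collection efficiency of
the isotropic emission versus the reflected line. The device this package
emulates is explicitly arranged for *approximate parity* between reflected
and emitted signal sizes; with unit-area profiles
($f \approx 0.02\,\mathrm{nm}^{-1}$ at peak) and benzodiazepine-scale
quantum yields (0.05--0.3), $g = 50$ realizes that parity. With $g = 1$,
$k_s = 0$ the model reduces to the bare inner-filter form
$\ln(10)\,A\,\phi f(\lambda)$ in the dilute limit, which is how the
simulator is verified against a series-expansion oracle.

Detector counts are $t\,b\,S_k(\lambda)$ for exposure $t$ and PWM
brightness $b \in [0,1]$, plus Gaussian noise with variance
$\sigma_0^2 + s\,\cdot\,\mathrm{signal}$ (read floor $\sigma_0 = 8$
counts; $s = 0.5$ approximates shot noise), hard-clipped at the 16-bit
saturation level 65,535.

### Auto-integration

The device exposes until the brightest pixel sits at 80% of saturation.
The loop assumes a linear detector: measure the peak, rescale
$t \leftarrow t \cdot 0.8\,\mathrm{sat}/\mathrm{peak}$, repeat (at most 8
iterations; noiseless linear detectors converge in 2). Samples that cannot
reach the target inside `max_integration` (e.g. a dark well) return the
longest exposure flagged `target_unreached`; nothing divides by zero.

## Preprocessing: scan → 66 × 66 × 1 fingerprint

Five deterministic steps, in order:

1. **Exposure normalization** — divide intensities by
   $t \times b$ per block, making channels comparable across the per-LED
   auto-exposures.
2. **Strip nonspectral fields** — keep only the ordered intensities,
   grouped by channel (12 × 1516).
3. **Trim** to 250--655 nm. The useful-information window is not published;
   250 nm keeps every LED line (≥ 255 nm) and all emission structure. On
   the fixed axis this retains 1306 pixels per channel.
4. **Bin** each channel into 360 near-equal contiguous pixel windows
   (widths differ by at most one pixel; bin centre = mean wavelength).
   360 is the largest round bin count with $12 B \le 66^2$, maximizing
   resolution while leaving a small pad.
5. **Min--max normalize** each channel to $[0,1]$ (a constant channel maps
   to zeros — the blank convention), then flatten row-major
   (channel-by-channel, ascending wavelength), append $4356 - 4320 = 36$
   zeros, and reshape to 66 × 66 × 1.

Consequences worth knowing: the fingerprint is invariant to any positive
rescaling of a single channel (so absolute brightness is discarded;
*relative* reflectance vs emission within a channel is what survives), and
rows of the image interleave channels every ~5.5 rows.

## The synthetic library

`default_registry()` mirrors the structure of the real training library,
which is private: 86 drug/variant/concentration classes — 11
benzodiazepines × {low, medium, high} with the published concentration
triples where stated (alprazolam 0.1/0.2/0.6 mg/mL, etizolam 0.3/0.6/1.2,
lorazepam 0.2/0.8/1.6), 18 single-drug classes (opioids, nitazenes, party
drugs, cutting agents, two seized-ketamine lots), 7 published two-drug
mixtures, 4 nondrug controls, and 24 synthetic filler compounds
(`nps_01..nps_24`, deterministic Gaussian optics) standing in for the
unpublished remainder. Raw counts: 61 classes × 20 plus 25 classes × 10
(the fillers and the blank) = 1470 examples; the deficit pattern is
unpublished, so it is assigned to the classes that are themselves
synthetic. Oversampling with replacement brings every class to 20 (1720),
then a seeded uniform shuffle splits 80/20 into 1376/344.

Balancing happens *before* the split, faithful to the protocol being
reproduced; oversampled duplicates can therefore straddle train and test,
which inflates held-out accuracy. `run_config(strict_split = TRUE)` gives
the leakage-free variant (split raw examples first, balance the training
side only) for honest generalization measurements.

Per-example seeds are derived from a (master seed, class id, replicate)
string hash below $2^{31}$, so libraries are byte-identical across
machines for a given seed.

### What the generator does and does not emulate

It reproduces: concentration-dependent reflectance attenuation, emission
saturation, additive mixtures, heteroscedastic detector noise, per-channel
auto-exposure, and the class structure (same drug at three doses is three
classes with similar shapes). It does **not** emulate: real compound
spectra (all optics are invented Gaussians anchored to a handful of
published band positions), excipient/batch variability, scattering
artefacts, temperature drift, or detector nonlinearity. A green accuracy
test therefore establishes that the *pipeline* discriminates the stated
synthetic world — not that the real instrument reaches any particular
accuracy.

## Models

All four classifiers consume the same flattened fingerprints.

**CNN** (the deployed model class): three stages of 3×3 valid convolution
(16/32/64 filters) + ReLU + 2×2 max pooling, flatten, one dense ReLU layer
(128), softmax output over the classes. No deep-learning runtime exists in
the target environment, so the forward/backward passes are implemented on
BLAS matrix products (im2col) and checked against finite-difference
gradients in the test suite. Training is minibatch Adam (step 3e-3, batch
32), fully seeded. Inputs are centred on the per-cell training mean
(stored in the model): fingerprints are all-positive with large structure
shared by every class, and without centring the optimizer spends the
desk-scale step budget learning that common structure. Layer sizes,
optimizer, and epochs are unpublished for the original model; these
defaults train the full library in minutes of CPU. The packaged
"reduced-epoch" experiment setting is 10 epochs.

**Baselines**, all one-vs-rest with an exhaustive grid search
(3-fold selection on the training split, accuracy criterion, refit on the
full training set): regularization strengths {0, 0.2, 0.4, 0.6, 0.8, 1.0},
kernels {linear, polynomial, RBF, sigmoid} (SVM only), PCA to
{25, 50, 75, 100} components or none. Strength 0 maps to a penalty-free
fit (for the kernel machine, to a vanishing ridge of 1e-6 so the normal
equations stay solvable). Logistic regression is ridge-penalized binomial
glmnet per class; the random forest is an in-package CART/gini
implementation (bootstrap, mtry = √p, 100 trees); the SVM is the
regularized least-squares (LS-SVM) formulation — it preserves the OvR
kernel-machine behaviour over the full kernel grid with base linear
algebra, at the cost of non-sparse solutions. OvR decision scores are
softmax-normalized so every model exposes the same probability interface.

**Evaluation**: accuracy, macro-averaged precision/recall/F1 over classes
present in the test set (the balanced design makes macro the natural
choice), the confusion matrix, and a ranked misclassification list. A
class never predicted has precision 0 by convention.

## Numerical choices and degenerate inputs

* Emission axis: `seq(185, 655, length.out = 1516)`; 18,192/12 forces the
  pixel count.
* LED centres: 12 evenly spaced on [255, 400] (only the range and count
  are published).
* Auto-integration tolerance: ±2% of saturation around the 80% target.
* Min-max of a constant channel → zeros; all-zero fingerprints are valid
  model inputs everywhere (they yield a proper probability vector).
* Max-pool ties break toward the first window element; odd feature-map
  edges are dropped by the 2×2/2 pooling (66→64→32→30→15→13→6).
* Single-class training sets are handled with a two-logit softmax whose
  second column is dead weight, dropped and renormalized at prediction.
* `sample()`'s length-1 surprise is avoided throughout
  (`idx[sample.int(length(idx), ...)]`).

## Known limitations

* The LS-SVM baseline is not a hinge-loss SVM; margins and support-vector
  sparsity differ, though OvR kernel behaviour on these separable
  libraries is equivalent in practice.
* Oversample-before-split leaks duplicates into the test set by design
  (protocol fidelity); use `strict_split` for unbiased numbers.
* The synthetic world is deliberately separable; accuracy floors verified
  against it say nothing about seized street samples.
* Pure-R convolution is CPU-bound: the full default experiment (1470
  simulated scans + 10-epoch CNN) takes several minutes; the complete
  four-model grid search takes substantially longer.
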