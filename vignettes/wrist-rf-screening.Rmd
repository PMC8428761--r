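---
title: "Screening for low bone density from wrist RF transmission spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for low bone density from wrist RF transmission spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristrf)
```

## The measurement and the classification problem

In osteoporosis and osteopenia, bone mass decreases and is replaced by
marrow, which changes the dielectric properties of the tissue and therefore
the radiofrequency channel through it. A pair of patch antennas pressed on
the two flat sides of the wrist measures the complex transmission
coefficient $S_{21}(f)$ — the ratio of received to transmitted signal —
at 201 frequency points over a linear sweep from 300 kHz to 2 GHz, for both
wrists of each subject, along with each wrist's circumference in cm. The
screening task is binary: separate subjects with low bone mineral density
(group 1, DXA T-score below $-1$; the positive class) from healthy controls
(group 2).

`wristrf` implements the full analysis around such data: a cohort data
model with CSV/Touchstone serialization, feature assembly, a two-layer
dropout multilayer perceptron (MLP), stratified $k$-fold cross-validation
with bilateral decision fusion, and a synthetic cohort generator so that
every stage is testable without access to measured subject data.

## Feature assembly

Each analyzer sample arrives as (linear magnitude, phase in degrees) and is
converted to the complex representation
$m\,(\cos\theta + i\sin\theta)$. A `feature_recipe()` fixes four choices:

* **encoding** — `magnitude` ($|S_{21}|$, 201 features), `phase`
  (wrapped radians, 201), `mag_phase` (402), or `complex_reim`
  (real parts then imaginary parts, 402);
* **arm mode** — `average` (complex pointwise mean over arms),
  `concatenate` (left then right, doubling the spectral part), or
  `separate` (one instance per arm, fused back to one diagnosis later);
* **circumference** — append the raw wrist circumference(s) in cm
  (one value for `average`/`separate`, two for `concatenate`);
* **normalization** — multiply the complex spectrum by the scalar
  $\mathrm{Age}/\mathrm{BMI}$ before encoding, folding two clinical risk
  factors into the data.

The longest realizable vector is $2 \times 402 + 2 = 806$ features
(complex both-arm concatenation with both circumferences), the shortest
201. Normalization acts on the *complex* values: magnitude and real/
imaginary features scale by $\mathrm{Age}/\mathrm{BMI}$ while phase
features are unchanged, since phase is invariant under positive scaling.
The circumference feature is never normalized — circumference and the
Age/BMI factor are treated as independent risk proxies. No z-scoring or
other feature standardization is applied before training; the recipe is
the only preprocessing.

## The classifier

The network is deliberately small:

$$\text{input} \rightarrow \text{dropout}(0.5) \rightarrow
\text{dense}(N_{\mathrm{in}} \to N_{\mathrm{hid}}) \rightarrow \mathrm{relu}
\rightarrow \text{dropout}(0.5) \rightarrow \text{dense}(N_{\mathrm{hid}}
\to 2) \rightarrow \mathrm{softmax}$$

with the hidden width fixed by the nearest-integer rule
$N_{\mathrm{hid}} = \mathrm{nint}(N_{\mathrm{in}}/10)$ (ties round away
from zero; no realizable recipe length produces a tie, so the choice is a
documented convention rather than an observable one). Weights are
Glorot-uniform initialized, biases start at zero, and an L2 penalty
(coefficient $10^{-4}$) applies to weights only. Dropout is inverted
(activations rescaled by $1/(1-p)$ during training) and disabled at
inference.

Training minimizes mean softmax cross-entropy plus the weight penalty for a
fixed 1000 epochs — no early stopping and no checkpointing. The optimizer,
learning rate and batching are design choices of this package: full-batch
Adam at learning rate $10^{-3}$. With at most a few hundred instances of at
most 806 features, full-batch steps are cheap, avoid mini-batch ordering as
a hidden source of nondeterminism, and Adam is robust to the very different
scales of spectral features (order $10^{-2}$) and circumference features
(order $10$) without standardization. A single RNG stream seeded from the
configuration drives initialization and every dropout mask, so training is
exactly reproducible; all of these settings are exposed in `mlp_config()`.
A softmax tie ($p = 0.5$) is resolved to the osteo group: in a screening
instrument a false alarm costs a confirmatory DXA scan, a miss costs a
diagnosis.

## Evaluation: stratified subsets and bilateral fusion

Cross-validation partitions *subjects*, never single arms, so the two arms
of one subject can never straddle the training/validation split (this is
asserted on every run). `stratified_partition()` shuffles each class under
the seed and deals the classes round-robin across the $k$ subsets with a
continuing cursor, which guarantees subset sizes within one of each other
and per-subset class counts within one of exact proportionality. With the
reference cohort of 27 + 40 subjects and $k = 7$, every subset has 9 or 10
subjects. The default is 7 subsets; $k$ is configurable (e.g. 10).

Each subset validates once while the other $k-1$ train a fresh classifier.
Reported performance is the arithmetic *mean over folds* of sensitivity,
specificity, accuracy and Youden's $J = \text{sens} + \text{spec} - 1$ (not
the pooled-count metrics). A fold whose validation subset lacks a class
would make a metric undefined; such folds are excluded from the mean with a
warning rather than silently counted as zero.

In `separate` arm mode each arm is classified independently (each arm
inherits its subject's group label, so 67 subjects yield 134 arm-level
instances) and per-arm statistics are reported under the scheme name
`separate`. Four fusion schemes then map the two arm predictions back to
one diagnosis per subject: agreement is always accepted; a conflict is
resolved by `keep_left`, `keep_right`, `keep_osteo` (call the subject
positive), or `keep_healthy` (call the subject negative). `keep_osteo`
trades specificity for sensitivity, which is usually the preferred
direction for screening.

## The synthetic cohort generator

The generator exists so that the pipeline's behaviour can be verified end
to end on data with known structure; it makes no attempt at
electromagnetic tissue modelling. Its defaults describe the reference
study conditions: 27 osteopenic/osteoporotic and 40 healthy subjects, with
group-specific age distributions, a common BMI distribution, and a common
wrist-circumference distribution.

**Spectral model.** Transmission spectra in this band show a handful of
dominant resonance peaks whose relative positions and heights carry the
group information. The generator therefore builds
$$S_{21}(f) = E(f)\, e^{u}\sum_{k=1}^{5}
\frac{a_k}{1 + i\,(f - f_k)/\gamma_k} + \varepsilon(f),$$
a broadband attenuation envelope $E(f)$ times a sum of complex Lorentzian
resonances plus complex Gaussian measurement noise
($\sigma = 10^{-4}$ per point per arm). The peak template (centres evenly
spaced over 0.2–1.9 GHz, widths 100 MHz, geometrically decaying base
amplitudes, envelope scale 0.05 so $|S_{21}|$ sits in the few-percent range
typical of through-wrist transmission) is a fixed population-level
constant. Group 1 scales every peak amplitude by $(1 +$
`effect_amplitude`$)$ (default 0.2) and shifts every centre by the relative
`effect_shift` (default 0.02), so the group difference lives exactly in
the peak heights and positions. Between-subject variability is a
log-amplitude perturbation $u$ (sd 0.1) shared between arms with
correlation 0.9 — wrists of one subject are near-replicates but not
copies. Wrist circumference (mean 16.5 cm, sd 1.5, one draw per subject
used for both wrists) couples positively to broadband attenuation, acting
as the "wrist fat content" proxy; by default it carries no group signal,
and a `circ_group_shift` knob exists for experiments. Passivity
($|S_{21}| \le 1$) holds by construction of the envelope and is
additionally enforced by a hard cap. $S_{11}$ is filled with a
structurally complete placeholder ($1 - |S_{21}|$, zero phase) so cohort
files round-trip; it carries no group signal and is never used for
classification. Sex is not simulated — the pipeline never consumes it.

**Demographics.** Ages are drawn from truncated normals fitted to the
target summaries (group 1: mean 77.5, sd 10.1, range 55–90; group 2: mean
60.2, sd 16.6, range 23–94). The group-1 triple is jointly unattainable:
on [55, 90] no truncated normal with mean 77.5 can reach an sd of 10.1
(the supremum, approached in the flat-density limit, is about 9.3). The
fit therefore weights the mean heavily — the realized group means match
the targets to well under 0.1 years at large samples, which is the
quantity the calibration checks rely on — and accepts the closest
attainable sd (about 8.8 years). Group 2 and the BMI distribution are
matched essentially exactly.

**What passing tests do and do not show.** The synthetic cohort shares the
*statistical shape* of the measured data (group sizes, demographics,
bilateral correlated spectra with multi-peak structure and a group effect
in the peaks) but not its absolute spectral shapes, its noise physics, or
any realistic overlap between groups. Synthetic results therefore validate
the machinery — leakage-free stratification, correct fusion arithmetic,
a classifier able to recover a known effect, and honest null behaviour —
and say nothing quantitative about performance on measured cohorts.

## Numerical and design notes

* The default sweep starts at 300 kHz (the instrument description); the
  grid is fully configurable for exports that start elsewhere, and a
  grid override is needed to read spectra that are not 201 points long.
* Phase is stored in degrees in files (network-analyzer convention) and
  radians internally; no phase unwrapping is performed — the complex
  representation encodes the wrapped phase anyway.
* Spectra with $|S| > 1$ trigger a warning, not an error, when loaded:
  slight passivity violations occur in real calibrated exports.
* Duplicated training rows leave the fitted decision function unchanged
  (mean-loss formulation; exact only with dropout off, since the
  per-row dropout masks consume a different RNG stream when $n$ changes).
* The `separate`-mode truth label of an arm is its subject's label, and
  undefined fold metrics are dropped from fold means with a warning.
* Problem sizes used by the shipped verification runs: feature/partition/
  fusion laws are exact and instantaneous; signal-recovery and
  null-calibration runs use the full 67-subject study configuration with
  1000-epoch training over 3 and 5 seeds respectively; demographic
  calibration uses 10,000 subjects per group.

## A complete run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  simulation = sim_params(effect_amplitude = 0.5),
  recipe = feature_recipe("complex_reim", "separate",
                          include_circumference = TRUE),
  k = 7, seed = 1)
run_pipeline(cfg, out = "results.json")
report_results("results.json")
```

The results JSON embeds the exact resolved configuration (including every
seed), so any reported table is regenerable from the file alone.

## Limitations

* The generator's Lorentzian mixture is a caricature chosen to place the
  group signal in peak heights/positions; it cannot calibrate expected
  performance on measured wrists.
* Only the transmission channel is modelled for classification; the
  reflection channel is carried for structural completeness.
* No ROC/AUC analysis: the classifier's operating point is fixed by the
  softmax argmax, matching how such screening tables are reported.
* The MLP's optimizer settings are this package's own; other toolboxes'
  defaults will differ, and results on measured data differ accordingly.
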