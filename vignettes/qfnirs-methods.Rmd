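---
title: "Quantum-circuit classifiers for fNIRS fear detection: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-circuit classifiers for fNIRS fear detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfnirs)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
optically; a fear response to a stimulus shows up as an oxyhemoglobin
(dHbO) deflection over the seconds following stimulus onset. The datasets
are small — here, 14 subjects with 10 balanced trials each, 27 channels at
10 Hz — which makes heavily parameterized deep models hard to justify.
`qfnirs` implements two *parameterized quantum circuit* (PQC) classifiers
for this setting, simulated exactly on the statevector, together with the
complete preprocessing, training and evaluation protocol and a synthetic
data generator, so that every stage is testable without any external
download.

## Simulation core

States are complex amplitude vectors over `n` qubits with **qubit 0 as the
most significant bit** of the basis index; this convention is stated once
here and enforced against a dense Kronecker-product oracle in the tests.
The gate set is `U3` (general single-qubit unitary with angles
$\theta,\phi,\delta$), the Pauli rotations `RY`, `RZ`, `RX`, `CNOT`, the
two-qubit `IsingXX` rotation $\exp(-i\phi\, X\!\otimes\!X/2)$, and a
two-branch conditional `U3` implementing quantum pooling.

Two data embeddings are provided. *Amplitude embedding* writes an
$N$-feature vector (zero-padded at the tail, then L2-normalized) into the
$2^n$ amplitudes of $\lceil \log_2 N \rceil$ qubits; 250 features fit on 8
qubits with only 6 padding values. *Angle embedding* encodes one feature
per qubit as an `RY` angle; because that encoding is $2\pi$-periodic,
inputs are constrained to $[0, \pi]$ so distinct values cannot alias.
Outputs are Pauli-Z expectations $\langle Z\rangle \in [-1, 1]$.

**Quantum pooling by deferred measurement.** The pooling primitive
"measure a qubit, condition a U3 on the outcome" is implemented as a
block-diagonal controlled operation
$|0\rangle\langle 0|\otimes U3(b_0) + |1\rangle\langle 1|\otimes U3(b_1)$.
By the deferred-measurement principle this is exactly equivalent, for every
terminal Z-expectation on other wires, to explicitly collapsing the
measured qubit and averaging the two branches under their Born
probabilities — while keeping the state pure and differentiable. The
equivalence is a tested invariant, not an assumption.

**Gradients.** Training needs exact derivatives of Z-expectations with
respect to every gate angle. The engine uses reverse-mode *adjoint*
differentiation: after one forward pass, the state and the cotangent are
swept backwards through the conjugate-transposed gates, and each
parameter's derivative is an inner product with the analytic gate
derivative. This costs about two circuit evaluations for the whole
gradient, is exact to machine precision, and is verified against central
finite differences (step $10^{-4}$, relative tolerance $10^{-5}$) — the
finite-difference oracle is the contract; adjoint propagation is an
implementation choice. The hot loops (column-pair updates on a batched
state matrix, one row per sample) are compiled C++; everything else is R.

## Architectures

### AEPQC

The 8-qubit amplitude-embedding classifier takes a pruned 25-channel
window flattened channel-major to 250 features. The circuit is three `U3`
layers interleaved with two `IsingXX` entangling layers, then quantum
pooling on the four alternating neighbouring pairs (measure wires 0, 2, 4,
6; condition a two-branch `U3` on wires 1, 3, 5, 7). Class scores are the
Z-expectations of the two lowest-index surviving wires (1 and 3).

The entangling layers are **rings** of 8 `IsingXX` gates (pairs
$(i, i{+}1 \bmod 8)$). This is a design choice the package makes
deliberately: with pairwise (4+4) entanglers the stated layer sequence
yields 104 trainable angles, whereas the architecture is defined to have
exactly $3\times24 + 2\times8 + 4\times6 = 112$. The constructor
hard-fails if the built circuit does not count 112 parameters, so the
layout cannot drift silently.

### QCNN

The quantum convolutional network slides a 4-qubit kernel over each
channel's 10 time samples with window 4 and stride 2, shrinking the
temporal length by 2 per layer: $10 \to 8 \to 6 \to 4 \to 2$ over 4
layers. Kernel weights are shared across window positions (convolution
semantics) but separate per channel and per layer. Two kernels are
provided:

* **K1** (light): an `RY` + `RZ` rotation pair per wire — 2 weights per
  wire, 8 per kernel — with a circular `CNOT` ring; readout on wires 0 and
  2 (the same alternating pattern the pooling kernels use; the choice of
  wires is free up to training).
* **K2** (pooling): two `U3` layers and a two-branch conditional-`U3`
  pooling stage (36 U3 parameters, 9 per wire) plus `IsingXX` entanglers
  on $(0,1)$, $(2,3)$ and $(1,2)$ (3 entangling parameters), 39 weights in
  total; readout on the surviving wires 1 and 3.

Between layers, kernel outputs in $[-1,1]$ are affinely remapped to
$[0,\pi]$ via $x \mapsto (x{+}1)\pi/2$ before re-embedding — reusing the
embedding's stated input range; without some such map the next layer's
angle embedding would be fed out-of-range values.

After the last layer each channel contributes 2 scores. The $27 \times 2$
matrix is fused either by the **classification head** — a 6-qubit PQC that
amplitude-embeds the 54 values (10 padding zeros) and applies `RY`, `RZ`,
`RX` rotation layers (18 weights) with a `CNOT` ring, reading out wires 0
and 1 — or by a parameter-free column-wise reduction: `avg`, `max`, or
`amax` (largest absolute value, sign preserved).

Softmax is applied only inside the cross-entropy loss; the scores
themselves stay on the $[-1,1]$ Z-expectation scale.

### Ablation design

`ablation_study()` compares the fusion modes per kernel. Each seed trains
the network once *with* the classification head; the parameter-free
fusions are then evaluated post hoc on the identical trained kernel stack,
so the upstream channel scores are bit-identical across fusion rows and
the comparison isolates the fusion stage itself.

## Preprocessing

Trials are restricted to the 3–15 s post-stimulus segment (0-based
samples, half-open interval $[30, 150)$ at 10 Hz) and cut into 12
non-overlapping windows of 10 samples. Features are scaled by

$$x_{\text{scaled}} = \arctan\!\left(\frac{x - Q_2}{Q_3 - Q_1}\right),$$

with quartiles computed **per channel** over all training samples of that
channel (channels have distinct optode gains; time points within a channel
share a scale) using R's default type-7 quantile rule. The median/IQR
location-scale step bounds outlier influence and the arctangent squashes
any residual extremes strictly into $(-\pi/2, \pi/2)$; a single
$|x| = 10^6$ outlier moves other scaled samples by less than 0.05 at
$n \ge 100$ (a tested invariant). For angle embeddings the scaled values
are shifted by $+\pi/2$ — the unique order-preserving shift onto
$[0,\pi]$. Scaler and channel selection are fitted on the training fold
only and applied unchanged to validation data.

For AEPQC, 2 of the 27 channels are pruned so the flattened window has 250
features. Channels are scored by the mean over the 10 within-window time
points of the absolute Pearson correlation between that feature and the
binary label across training windows, computed on the scaled training
windows (the same representation the model consumes); the two
lowest-scoring channels are dropped, ties resolved by dropping the lower
channel label first. Channel labels are 1-based in all I/O and reports.

## Training and evaluation protocol

Two evaluation modes mirror the study design: *subject-independent*
leave-one-subject-out cross-validation (train 1560 windows, validate 120)
and *subject-dependent* per-subject splits (first six trials — three fear,
three non-fear — for training, 72 windows; the remaining four for
validation, 48 windows).

Training is full-batch: one Adam step (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) per
epoch on the entire training set, cross-entropy loss. Default learning
rates are 0.1 (subject-independent) and 0.005 (subject-dependent, the
much smaller batch). Early stopping terminates after 5 epochs without
strict improvement of the validation loss, but only once training accuracy
has reached 75% — the gate prevents stopping on a validation loss that is
small by chance before the model has learned anything. A hard cap
(`max_epochs`, default 200) guarantees termination when the gate is never
reached; hitting the cap that way raises a warning. Each fold is repeated
from 10 seeds (0–9 by default); validation accuracy is reported at the
stopping epoch, and the best-validation-loss epoch is logged alongside.

Because validation sets are small, an accuracy above 50% is not by itself
evidence of learning. The package uses the lower bound of the Wilson score
interval at 95% confidence ($z = 1.959964$) and reports the smallest
accuracy on a 0.01-percentage-point grid whose bound exceeds 50%: 58.95%
for $n = 120$ and 64.15% for $n = 48$.

**Channel importance** is occlusion-based: each channel is zeroed in the
scaled representation the model consumes, and the importance is the mean
absolute change of the pre-softmax score vector over the batch, normalized
across the analyzed channels to sum to 1 (for AEPQC these are the 25 kept
channels). A softmax-probability variant is exposed as an option. If no
channel changes the output, the importances are degenerate-uniform with a
warning.

## Synthetic data

The generator emulates the *structure* the pipeline assumes: balanced
fear/non-fear trials, 27 channels at 10 Hz, 30 s trials, narrow-range
values with occasional heavy outliers. Fear trials add a canonical
double-gamma hemodynamic response (peak 6 s, undershoot 16 s, ratio 1/6,
onset 3 s — the start of the analysis window) scaled by `effect_amplitude`
and a per-subject Gaussian gain to the informative channels; all channels
carry white noise; a small fraction of samples (default 0.5%) is replaced
by spikes 50× the noise scale, exercising the robust scaler. Labels
alternate fear/non-fear so the first six trials satisfy the 3/3 constraint
of the subject-dependent split. Defaults (effect 1.0, noise SD 0.3,
subject gain SD 0.2, channels 8–10 informative) were chosen once as a
plausible strong-response regime with effect-to-noise ratio above 3.

What the generator does **not** capture: Mayer waves and systemic
physiology, spatial correlation between neighbouring optodes, motion
artifacts beyond isolated spikes, and subject-specific response shapes.
Passing the recovery tests therefore shows the pipeline is correct and
can detect a class-conditional hemodynamic effect of realistic size — it
does not certify any particular accuracy on real recordings.

## Numerical choices and degenerate inputs

* Unitarity of gate matrices to $10^{-12}$; engine-vs-dense-oracle and
  pooling Born consistency to $10^{-10}$; gradient-vs-finite-difference to
  $10^{-5}$ relative.
* Weight initialization: independent uniform on $[-\pi/10, \pi/10]$ —
  small angles keep the early circuit near the identity.
* "Improvement" in validation loss means strictly lower than the best
  seen, with no minimum delta.
* Tie-breaks: channel-pruning ties drop the lower label first; `amax` and
  class prediction take the first maximum.
* Degenerate inputs fail loudly: zero IQR names the offending channel;
  all-zero amplitude-embedding input is an error; non-finite losses abort
  training with a diagnostic.
* Angles are radians throughout; no modular reduction is applied (inputs
  are pre-constrained to $[0,\pi]$).

## Problem sizes used by the test suite

The synthetic-recovery study in the tests runs the subject-independent
protocol on 4 subjects with 3 seeds and a 40-epoch cap — sizes the package
chooses so the whole suite stays a matter of minutes while the validation
set per fold (120 windows) still matches the protocol's subject-independent
$n$. The strong-effect arm must beat the 58.95% Wilson threshold; the
zero-effect arm must stay within [40%, 60%]. Full-scale runs (14 subjects,
10 seeds, 200-epoch cap) use the same code paths via `cross_validate()`
and the command-line interface.

## Known limitations

* The simulator targets the architectures' sizes (4–8 qubits); it is an
  exact dense statevector with no shot noise, device noise model, or
  large-`n` backend.
* Full-batch training only, as in the protocol; no mini-batching or
  learning-rate schedules.
* dHbR channels are read and carried through I/O but never analyzed.
* The AEPQC entangling-layer layout is the package's own completion of an
  under-determined textual description, pinned by the 112-parameter check
  (see the design note above).
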