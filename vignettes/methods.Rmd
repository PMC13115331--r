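---
title: "Methods: simulating and classifying EIT gesture measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying EIT gesture measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

eitgest implements a complete electrical impedance tomography (EIT)
gesture-recognition study in software: a finite-element simulator of a
16-electrode forearm armband, a labelled session generator with three
interference ("confounder") models, Tikhonov difference imaging, and a
spatio-temporal sequence classifier (FASPP-GRU) with KNN, SVM and
CNN-LSTM baselines. This vignette records the models, their assumptions,
the tunable parameters and the numerical and design choices, so that a
reader can judge what the package's tests do — and do not — establish.

## Forward model

The forearm cross-section is idealized as the homogeneous-background unit
disk, the standard 2-D EIT geometry. The electric potential obeys
$\nabla\cdot(\sigma\nabla u) = 0$ with current injected through boundary
electrodes. We discretize with piecewise-linear (P1) triangular finite
elements on a structured polar mesh: ring $i$ of $L$ carries $16i$ nodes,
giving exactly $16L^2$ elements. Two non-standard choices matter:

* **Boundary grading.** Ring radii follow $(i/L)^{0.6}$, concentrating
  resolution near the boundary where the injected current density is
  singular. Without grading, the channels measured adjacent to the drive
  pair converge slowly (several percent error at ~800 elements); with it
  the worst-channel error against the closed-form homogeneous-disk
  solution is below 2% at refinement 7 (784 elements).
* **Refinement-independent electrodes.** Each electrode arc carries a
  fixed set of (up to four) dedicated boundary nodes at fixed angles, with
  gap nodes filling between arcs. The discrete electrode model therefore
  does not change as the mesh refines, which makes voltages converge
  cleanly between refinement levels and makes a whole-pitch belt rotation
  an exact symmetry of the mesh.

Electrodes use the gap model: current is spread uniformly over an
electrode's nodes and the electrode potential is the node mean. Contact
impedance is deliberately excluded from the FEM — contact effects enter
the pipeline as measurement-level perturbations in the session generator.
The electrode arc covers 0.8 of the inter-electrode pitch, the ratio of a
1.1 cm electrode on a 22 cm 16-electrode band. Conductivity is real
valued (a single-frequency resistive approximation); capacitive tissue
components are out of scope.

The adjacent drive protocol injects 1 mA (default; voltages are linear in
it) through each neighbouring pair $(k, k+1)$ in turn and reads the 13
adjacent pairs not involving the injecting electrodes:
$16 \times 13 = 208$ channels in a canonical drive-major order,
measurement pairs ascending from two electrodes past the source, with
sign $V = u(m) - u(m{+}1)$.

The pure-Neumann system is grounded at the centre node; assembly uses a
cached triplet pattern so one frame costs a scaled scatter-add plus a
sparse Cholesky factorization whose symbolic analysis is reused across
frames. Solver tolerance is that of the direct factorization (residuals
near machine precision); reciprocity holds to ~1e-15 of the largest
channel.

The sensitivity matrix (Jacobian) uses the adjoint identity: for drive
field $u_d$ and measurement-pair field $u_m$ (both unit current),
$\partial V_{dm}/\partial\sigma_e = -|e|\,\nabla u_d \cdot \nabla u_m$
on each element $e$, where gradients are constant per P1 element. Because
drives and measurements both use adjacent pairs, the 16 pair fields serve
both roles. The adjoint Jacobian is validated against central finite
differences (relative error below 1%).

## Phantom and session generator

The generator defines the study conditions. Stylized anatomy, not
subject-specific geometry:

* **Static anatomy.** Background 0.3 S/m (muscle-like) with two
  low-conductivity discs for the radius and ulna (0.05 S/m). The bones
  anchor the angular reference of the phantom; without them a homogeneous
  disk would be rotationally symmetric and armband rotation would be a
  null perturbation.
* **Gesture templates.** Each of the nine gestures (pointer, power,
  pronation, supination, thumb, tripod, victory, open, rest) is a set of
  2–4 circular inclusions at the angular positions of named forearm
  muscles (electrode 0 over the extensor carpi radialis), with signed
  relative contrasts of 0.08–0.3 applied multiplicatively and scaled by
  the activation level. "rest" has no inclusions. "power" and "thumb"
  share three of four inclusions so their steady-state voltage patterns
  are deliberately similar while their transition dynamics differ.
  Contrast magnitudes were chosen once so that steady-state channel
  changes fall in the few-percent range relative to baseline (median
  ~1–2%, tails to ~10%), the scale reported for real forearm recordings.
* **Participants as seeds.** A participant seed jitters inclusion centres
  (sd 0.02), radii (5%) and contrasts (10%), and draws per-inclusion
  onset lags uniform on [0, 0.3] s — a stable "finger order" per
  participant.
* **Protocol.** Each instruction is held 3 s and followed by a 5 s rest
  interval at 23 frames/s; 10 repetitions per gesture in training
  sessions, 5 in confounder blocks. Frames inside the instructed period
  carry the gesture label (including the transient), interval frames are
  unlabelled. A training session therefore contains exactly
  $9 \times 10 \times \lfloor 3 \times 23 \rfloor = 6210$ labelled
  frames; a confounder block 3105.
* **Transitions.** Onset and release ramps are normalized logistic
  profiles with duration drawn uniformly from 0.4–1.2 s per repetition,
  plus the per-inclusion lags; steady activation jitters around 1
  (sd 0.05, clamped). Activation levels are quantized to steps of 1/8
  before solving: the induced voltage steps sit below the measurement
  noise floor, and repeated levels share one finite-element solve, which
  is what makes full-protocol simulation cheap.
* **Instrument scale.** A global gain calibrated on the clean rest frame
  maps the largest channel to 800 mV; the adjacent protocol's dynamic
  range then spans roughly 90–800 mV across channels, inside the 20–800
  mV working range of the emulated instrument. The gain is fixed per
  participant (an instrument property), so confounder blocks keep the
  training calibration.
* **Noise.** Additive Gaussian per channel at 40 dB SNR relative to the
  channel baseline (the hardware's noise figure is not published; 40 dB
  is a realistic bench value). `Inf` disables noise.

The three confounders mirror the experimental interference conditions:

* **Limb position** (L/R/U/D): a smooth linear background-conductivity
  gradient along the direction plus a small shift of all inclusion
  centres (defaults 0.015 and 0.01), applied before solving, so rest
  frames drift without any gesture. The amplitude is calibrated so the
  posture-induced background change is of the same order as the
  gesture-evoked channel changes: much larger values turn the condition
  into an out-of-distribution collapse for every classifier rather than
  the graded degradation the condition is meant to probe.
* **Time drift:** multiplicative per-channel factor
  $1 + A_c(1 - e^{-t/\tau})$ with $A_c \approx 2\%$ (channel-specific)
  and $\tau = 120$ s — a scaled-down stand-in for multi-hour wear, which
  the source protocol does not quantify.
* **Contact rotation:** the electrode belt is rotated by half a pitch
  (default) and voltages are re-solved on the rotated geometry. A
  whole-pitch rotation followed by cyclic channel relabelling is an exact
  identity, which the tests assert.

What the generator does **not** emulate: physiological EMG-like
variability, electrode-skin contact impedance dynamics, 3-D current
spreading, anatomical detail beyond two bones, or inter-session electrode
placement error. Passing tests therefore demonstrate that the pipeline's
algorithms behave correctly under controlled, separable conditions; they
do not certify performance on real forearm recordings.

## Reconstruction

Time-difference imaging linearizes around the reference state:
$\Delta V = J\,\Delta\sigma$, solved by Tikhonov-regularized least
squares, $\Delta\sigma = (J^\top J + \alpha I)^{-1} J^\top \Delta V$,
computed via a Cholesky solve of the normal equations (never an explicit
inverse). The default $\alpha = 0.01\,\lambda_{\max}(J^\top J)$ adapts to
the sensitivity scale; $\lambda_{\max}$ is obtained from the 208×208 Gram
matrix. The default reference is the mean over rest-interval frames.
Reconstruction is for visualization; classification uses raw boundary
voltages only.

## FASPP-GRU classifier

Per frame, the 208 channels are reshaped into a 16×16 grid (drive-major
rows, 13 true columns, 3 zero-pad columns — the layout keeps one drive's
channels contiguous), bilinearly upsampled ×2 to 32×32, folded (2×2
space-to-depth, a bijective rearrangement) to 16×16×4, passed through an
atrous spatial pyramid: parallel 3×3 convolutions at dilations 1, 2, 4
plus a 1×1 branch (ReLU), concatenated and projected 1×1 (ReLU), and
unfolded back to measurement space. Regional average pooling over a 4×4
grid of spatial blocks plus a linear embedding produce one frame vector;
a single-layer GRU reads the 11-frame sequence (480 ms at 23 frames/s)
and an MLP head with softmax emits the 9-class probabilities. Training
minimizes mean cross-entropy of one-hot targets with Adam at learning
rate 5e-5, early-stopping on validation loss.

The spatial-to-vector interface deserves a note, because the obvious
choice is wrong. Global average pooling — the default ending of most
image encoders — composes with convolution into a translation-invariant
map. EIT measurement grids are not images in that sense: the class signal
is position-coded (which drive/measurement cells respond identifies which
muscles moved), and under global pooling both sequence models plateaued
well short of fitting even their training sets. Pooling over a 4×4 grid
of regions keeps position at drive-group granularity and resolves this
completely; it is the package's frame embedding for both sequence models.
(As an implementation detail, region pooling commutes with the unfold
permutation, so the unfolded tensor never needs materializing.)

Width allocation is the package's choice under the 0.65 M parameter
design budget (8 channels per ASPP branch, 32 projection channels,
embedding 128, GRU hidden 160, MLP hidden 2898; 649,885 parameters). The
CNN-LSTM baseline mirrors the interface at its 0.88 M budget (two 3×3
conv layers of 8 and 16 channels, LSTM hidden 192, MLP hidden 2967;
880,015 parameters). Within each budget, parameters were shifted from
the recurrent state toward the MLP head; recurrent weights are touched
eleven times per sequence, so this allocation minimizes memory traffic
per optimizer step at an unchanged budget.

Numerical/engineering choices worth knowing:

* Forward and backward passes are written explicitly against a small set
  of compiled kernels (im2col/col2im for dilated convolutions, fused
  GRU/LSTM steps, in-place ReLU, in-place Adam); gradients are validated
  against central finite differences on small configurations.
* Inputs are standardized per channel with training-set statistics
  (default on, a config flag). Raw millivolt inputs carry the class
  signal as few-percent modulations on large static baselines; the
  standardizing affine layer removes the static component so that
  gradient descent at the fixed 5e-5 rate makes progress within a
  practical number of steps. The windows themselves remain raw voltages —
  no reference subtraction is used.
* Batch size defaults to 1 (batch size is not part of the architecture
  contract). At a fixed learning rate the total parameter displacement is
  bounded by (steps × rate); small batches maximize optimizer steps per
  pass over a fixed-size training set, which is what convergence is
  limited by at desk scale.
* Initialization is Glorot-uniform, seeded; zero biases (forget-gate bias
  1 for the LSTM). Training, splits and simulation are deterministic
  given their seeds.

## Evaluation

Multiclass accuracy is trace/total of the confusion matrix; per-class
precision/recall/F1 use the one-vs-rest reduction with the 0-convention
for empty denominators; F1 is macro-averaged (class counts are balanced
by protocol design). Models are compared with the Friedman rank test over
paired (participant × condition) accuracy blocks. Feature-space structure
is visualized by projecting either flattened windows or the classifier's
final recurrent state to 2-D with Barnes–Hut t-SNE (the package's choice
of neighbour embedding); decision regions in embedding plots are rendered
by a nearest-centroid rule on a 2-D grid and are a visualization
approximation, not the classifier's true decision surface.

## Reference study sizes

The packaged end-to-end study (`run_experiment()`, also used by the
acceptance script) uses: mesh refinement 6 (576 elements), two emulated
participants, three training sessions each (full 10-repetition protocol),
all six confounder blocks (5 repetitions), a balanced cap of 50 training
windows per class (70-15-15 split) and 30 evaluation windows per class
per condition, batch size 1, up to 25 epochs with early stopping at patience 6. These sizes
are the package's reference configuration for a single-workstation run;
all of them are exposed in `experiment_config()` and scale up directly.

## Known limitations

* 2-D circular geometry and point/gap electrodes; no contact-impedance
  electrode model.
* The phantom's separability is by construction; real inter-participant
  and inter-session variability is far larger.
* Reported accuracies from the synthetic study are analogues of the
  real-data quantities, not reproductions of them (the original
  recordings are not publicly deposited).
* The classifier implementations are CPU-oriented and sized for
  hundreds-of-windows training sets; they are not a deep-learning
  framework.
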