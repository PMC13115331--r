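# eitgest

Hand-gesture recognition from electrical impedance tomography (EIT)
armband measurements, end to end and fully in software. The package is
aimed at researchers studying EIT-based human-machine interfaces who need
a controlled, reproducible test bed: a physics-based simulator stands in
for the armband hardware, and the full recognition pipeline — difference
imaging, sequence datasets, a spatio-temporal deep classifier and
conventional baselines — runs against it, including the interference
conditions that plague wearable EIT in practice.

## What is inside

**Forward model.** A P1 finite-element solver for
$\nabla\cdot(\sigma\nabla u)=0$ on the unit disk with 16 boundary
electrodes and the adjacent current-drive protocol: current through each
neighbouring electrode pair in turn, differential voltages from all other
adjacent pairs — $16\times13=208$ channels per frame. The sensitivity
matrix $J$ (the linearization $\Delta V = J\,\Delta\sigma$) is computed
by the adjoint method and verified against finite differences.

**Phantom & sessions.** Gesture-evoked muscle activity is emulated as
conductivity inclusions over named forearm muscles (plus static bone
anatomy); `simulate_session()` emits labelled 23 frames/s streams that
follow the experimental protocol (3 s instructed gestures, 5 s rests,
logistic 0.4–1.2 s transients), with three confounder models: limb
position change, slow temporal drift, and armband rotation by half an
electrode pitch.

**Reconstruction.** Tikhonov-regularized time-difference imaging,
$\Delta\sigma = (J^\top J + \alpha I)^{-1}J^\top\Delta V$, referenced to
rest frames, with `autoplot()` rendering of the element-wise image.

**Classification.** The FASPP-GRU sequence classifier — per-frame
upsample → fold (2×2 space-to-depth) → atrous spatial pyramid (dilations
1, 2, 4 + 1×1) → unfold → regional pooling → GRU over 11-frame windows →
MLP softmax, 0.65 M parameters, trained with Adam (learning rate
5×10⁻⁵) and cross-entropy $L=-\sum_i y_i\log\hat y_i$ — plus KNN, SVM
and a 0.88 M-parameter CNN-LSTM under the identical window interface.
Forward and backward passes are hand-written against compiled kernels;
gradients are finite-difference-checked in the tests.

**Evaluation.** Confusion matrices, accuracy and macro-F1 from the
one-vs-rest reduction, per-condition reports, Friedman rank comparison
across models, and 2-D feature embeddings.

## Worked example

Simulate a session, inspect a reconstruction, and train a classifier:

```r
library(eitgest)

mesh <- build_disk_mesh(6)              # 576-element graded disk mesh
protocol <- adjacent_protocol()
base <- base_conductivity(mesh)         # muscle background + bones
templates <- gesture_templates(participant_seed = 11)

stream <- simulate_session(session_spec(reps = 10, seed = 1),
                           templates, confounder("none"), mesh,
                           protocol, base)
nrow(stream)                            # 16560 frames (9 x 10 x 8 s x 23 fps)
sum(!is.na(stream$gesture))             # 6210 labelled frames

# difference image of a steady "pointer" frame against the rest reference
J <- compute_jacobian(mesh, base, protocol)
ref <- reference_frame(stream)
idx <- which(stream$gesture == "pointer")[60]
img <- tikhonov_reconstruct(J, difference_voltages(stream$v[idx, ], ref),
                            mesh = mesh)
autoplot(img)

# windows -> split -> train -> evaluate
windows <- window_sequences(stream) |> subsample_windows(50, seed = 2)
splits <- split_dataset(windows, seed = 3)
model <- nn_init(faspp_gru_config(batch_size = 1L, max_epochs = 30L),
                 seed = 7) |>
  nn_train(splits$train, splits$val, seed = 8)
pred <- predict(model, splits$test)
mean(pred$.pred == pred$label)          # 1.0 on this clean session
glance(model)
```

The full study — two emulated participants, four classifiers, all seven
conditions — is one call (about a quarter of an hour on a single CPU):

```r
exp <- run_experiment(experiment_config())
exp$metrics       # pooled accuracy / macro-F1 per model and condition
exp$friedman      # paired rank comparison of the four models
autoplot(exp)
```

On the packaged reference configuration (printed by `print(exp)`), all
four models classify the interference-free test split at 95–100%
accuracy (FASPP-GRU 0.985, CNN-LSTM 0.948, KNN 1.000, SVM 0.993), slow
temporal drift costs every model only a few points (0.91–0.97), limb
position change causes intermediate, direction-dependent degradation,
and armband rotation is the harshest condition — FASPP-GRU retains 0.770
while CNN-LSTM, KNN and SVM fall to 0.596, 0.596 and 0.520. The paired
Friedman comparison over the 14 participant-condition blocks separates
the models decisively (chi-squared 22.5, df 3, p = 5.2e-05).

## Package layout

* `R/` — mesh/protocol/forward model, phantom generator, reconstruction,
  dataset ops, classifiers, evaluation, experiment driver.
* `src/` — compiled kernels (im2col/col2im, fused GRU/LSTM, pooling,
  Adam).
* `vignettes/methods.Rmd` — the science: models, assumptions, parameter
  choices, limitations.
* `inst/scripts/` — thin command-line wrappers (`simulate.R`,
  `reconstruct.R`, `run_experiment.R`).
* `tests/testthat/` — unit, property and acceptance tests.
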