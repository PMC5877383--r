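# semgopt

Feature optimization and control simulation for surface-electromyography
(sEMG) human-computer interfaces.

Four-motion myoelectric interfaces classify short windows of forearm sEMG
(rest, fist, wrist extension, wrist flexion) and turn the predictions into
device commands. Their practical quality hinges on three choices that are
usually made ad hoc: which of the dozens of candidate signal features to
compute, which electrode channels to keep, and how the window-level
predictions are debounced into safe control commands. `semgopt` packages
that whole workflow for researchers building or benchmarking such
interfaces:

* **Preprocessing** — zero-phase Butterworth band-pass (10–450 Hz) with an
  elliptic 50 Hz notch and harmonic band-stops, ICA artifact rejection, and
  multiscale-PCA (wavelet + per-scale PCA) denoising, plus windowed-RMS SNR
  reporting.
* **Feature bank** — the 42-dimension per-channel bank used across the sEMG
  literature: MAV/MMAV1/MMAV2, RMS, VAR, WL, two-threshold ZC, SSC,
  five-threshold Willison amplitude, SSI, 6-bin amplitude histogram,
  order-4 Burg AR coefficients, median/mean frequency, a short-time Fourier
  power scalar, and the average power and standard deviation of DB4 wavelet
  coefficients in 7 sub-bands (D1–D6, A6). Cascading C channels gives a
  42·C-dimension vector.
* **Feature selection** — three separability criteria:
  * *EC* (entropy criterion): with per-class variances `V_k` of a feature
    normalized so `Σ_k V_k = 1`, the score is `J = −Σ_k V_k ln V_k`;
    smaller J (more uneven class variances) = more separable.
  * *FD* (Euclidean Fisher discrimination):
    `J = D²(a,b) / (D²(a,a) + D²(b,b))`, where `D²(a,b)` is the mean
    squared difference over all cross pairs of trials and the within-class
    terms average all distinct pairs; multi-class problems are decomposed
    one-versus-all and averaged. Larger J = more separable.
  * *RFE* (SVM recursive feature elimination): a linear SVM is retrained
    while repeatedly eliminating the feature whose removal least degrades
    the squared-weight margin criterion (`w_i²`); the elimination order
    read backwards is the rank.

  On top of the criteria: optimal-feature-number sweeps (accuracy vs.
  subset size), cross-subject/channel aggregation (normalized-SV averaging
  for EC/FD, top-k frequency counting for RFE), and channel ranking by
  single-channel pairwise classification.
* **Evaluation** — stratified cross-validation of kNN (k = 6), a
  single-hidden-layer sigmoid network (n–2n–4), a 30-tree random forest
  with `s = round(log₂ d)` candidate features per node, and a one-versus-all
  RBF SVM; reports accuracy, macro F-score (`2TP / (2TP + FP + FN)`) and
  row-normalized confusion matrices, plus a window-length comparison study.
* **Synthetic generator** — seeded, labelled multichannel recordings with
  the standard 1.5 s trial envelope (0.25 s onset, 1 s execution, 0.25 s
  offset), class-specific spectral bands and channel coupling gains, a
  noise floor and 50 Hz interference; plus a planted-feature generator for
  testing the selection criteria directly.
* **Control simulator** — discrete-time telecar kinematics (12 cm / 45°
  quanta at 12 cm/s and 0.25π rad/s) under three window-based paradigms:
  double-confirmation fixed moving, two-channel agreement, and a
  state-machine mode toggled by resting; computes travel time, recognition
  rate and trajectories over a square course with obstacles.

## Worked example

```r
library(semgopt)

rec <- generate_semg(synthetic_config(trials_per_class = 10), seed = 2)
rec
#> <semg_recording> 4 channel(s) x 60000 samples @ 1000 Hz (60 s)
#>   channels: APL, ECR, ECU, FCU
#>   trials: 40 annotated ( MF=10, REST=10, WE=10, WF=10 )

rec <- apply_filters(rec)                       # band-pass + notches
windows <- segment_recording(rec, window_spec(0.25))   # 1 s execution -> 4 windows/trial
features <- extract_features(windows, rec$fs)
features
#> <feature_matrix> 160 windows x 168 features (APL, ECR, ECU, FCU)
#>   classes: MF=40, REST=40, WE=40, WF=40

report <- fd_score(features)                    # Fisher-discrimination ranking
selected <- features[, report$order[1:23]]
crossval(selected, classifier_config("rf"), seed = 3)
#> <classifier_result> rf, 10-fold CV: accuracy 100.00%, macro F 1.0000
#> confusion (row %):
#>         MF REST  WE  WF
#>   MF   100    0   0   0
#>   REST   0  100   0   0
#>   WE     0    0 100   0
#>   WF     0    0   0 100
```

160 windows (40 trials × 4 disjoint 250 ms windows of each execution
period) are described by 168 features (42 per channel × 4 channels); the
23 best features by FD separate the four synthetic motion classes
perfectly under 10-fold cross-validation — the generator's default classes
are deliberately well separated, so this is the expected ceiling, not a
claim about real recordings.

Driving the simulated telecar with classified windows:

```r
sim <- run_paradigm(rep(c("MF", "MF", "WE", "WE"), 2), paradigm_config(2))
sim
#> <session_metrics> paradigm 2: 5.00 s travel time, 8 command windows, 0 collisions avoided

ideal_route_time(map_config(side_cm = 40, loops = 2))
#> [1] 42.66667
```

Under paradigm 2 each pair of equal consecutive windows issues one
command (here: two forward translations and two clockwise rotations);
42.67 s is the kinematic lower bound for the standard two-loop 40 cm
square course.

A command-line front end over the same functions is installed at
`inst/cli/semg_tool.R` (subcommands `synth`, `preprocess`, `extract`,
`select`, `evaluate`, `simulate`).

## Vignette

`vignettes/semg-feature-optimization.Rmd` documents the models,
conventions, parameter defaults and design decisions in detail, including
what the synthetic generator does and does not emulate.
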