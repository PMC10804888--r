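# graphmi

Graph-embedded convolutional classifiers for motor-imagery EEG.

Motor imagery — imagining a movement without performing it — leaves
decodable traces in scalp EEG, concentrated over the sensorimotor cortex
(electrodes C3, Cz, C4 in the 10–20 system). `graphmi` implements two
complementary ways of encoding a 22-channel, 250 Hz, 4-second epoch before a
convolutional classifier:

* **Structural pathway (Adj-CNNM-style).** The montage is a 2-D grid; two
  electrodes are connected when their cells are vertical, horizontal or
  diagonal neighbours. With binary adjacency `A` and `Ã = A + I`, each trial
  `X` (22 × 1000) is embedded as

  `G = D̃^(−1/2) Ã D̃^(−1/2) · X`

  — the spectral graph-convolution operator, which averages every channel
  with its grid neighbours — and classified by a wide-kernel CNN
  (conv 22 × 45 / stride 2 × 2 / 64 filters → max-pool 1 × 50 → dropout →
  softmax).

* **Functional pathway (PLV-CNNM-style).** Each trial is band-pass filtered
  (δ, θ, α, μ, β, 8–30 Hz, γ, or broadband 1–51 Hz), each channel's
  instantaneous phase φᵢ(t) is extracted from the analytic signal, and every
  channel pair is summarized by its phase-locking value

  `PLV_ij = (1/M) |Σ_t exp(i(φ_i(t) − φ_j(t)))|`,

  giving a dense 22 × 22 connectivity matrix per trial, classified by a
  compact CNN (conv 3 × 3 × 32 → pool 2 × 2 → conv 3 × 3 × 64 → dropout →
  softmax).

Around the two models the package provides class-stratified k-fold × multi-run
cross-validation with the full metric suite (accuracy, macro/micro F1 and
precision, one-vs-rest ROC-AUC, pooled SD), a hyperparameter-grid harness,
graph-free ablation baselines, first-layer feature-map export, and a
synthetic EEG generator with planted phase coupling and event-related power
modulation whose expectations are known in closed form — so the entire
pipeline is testable without any data download. The CNN engine itself
(im2col convolutions, pooling, Adam, backprop) is implemented in the package
with compiled kernels and is verified against finite differences in the test
suite.

## Worked example

```r
library(graphmi)

# montage graph: Cz sits in the grid interior with eight neighbours
g <- build_adjacency(build_layout("bci2a"))
graph_neighbors(g, "Cz")
#> [1] "FC1" "FCz" "FC2" "C1"  "C2"  "CP1" "CPz" "CP2"
g$A_hat["Cz", "Cz"]      # degree 9 in A + I
#> [1] 0.1111111

# synthetic dataset with class-dependent phase coupling (sigma = 0.3)
ds  <- generate_dataset(synth_spec("plv-separable", trials_per_class = 50,
                                   seed = 11))
plv <- plv_dataset(ds, "mi")          # 8-30 Hz connectivity matrices
cm  <- class_mean_plv(plv)
cm$left_hand["C3", "CP3"]             # a pair coupled for this class
#> [1] 0.8796134
planted_oracle(synth_spec("plv-separable", trials_per_class = 50, seed = 11),
               "mi")$plv$left_hand["C3", "CP3"]
#> [1] 0.8603425

# fit the functional classifier and evaluate it by stratified 3-fold CV
fp  <- make_folds(plv, k = 3, runs = 1, seed = 5)
rep <- run_cv(plv, function(s, k) build_plv_cnnm(s, k),
              train_config(max_epochs = 30, batch_size = 32, seed = 9), fp)
rep
#> <eval_report> plv_cnnm_f32.64_k3x3: 3-fold x 1 runs, n = 200
#>   F1(Ma) 0.9951  F1(Mi) 0.9950  Prec(Ma) 0.9954  Prec(Mi) 0.9950
#>   AUC(Ma) 1.0000  AUC(Mi) 1.0000  Accuracy 0.9950  SD 0.009
```

The class-mean PLV on the planted pair (0.88) matches the generator's
closed-form expectation (0.86) within the package's ±0.05 recovery
tolerance: the coupling factor `exp(-σ²/2) ≈ 0.96` times the per-channel
phase-noise attenuation at the in-band SNR. With distinct coupled pairs per
class the connectivity matrices are linearly separable and the CNN is at or
near ceiling accuracy at desk scale (99.5 % here; 100 % at 200 trials/class).

The structural pathway is exercised the same way on the `"erd-separable"`
preset (power topography instead of coupling):

```r
emb <- embed_trials(ds_erd, g)        # G = Â X, global per-trial scaling
run_cv(emb, function(s, k) build_adj_cnnm(s, k),
       train_config(learning_rate = 1e-3, batch_size = 32,
                    max_epochs = 40, seed = 9), fp)
```

A thin command-line surface over the same functions is installed at
`inst/cli/graphmi.R` (subcommands `synth`, `adj-embed`, `plv`, `train`,
`evaluate`, `tune`, `report`, `feature-maps`).

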