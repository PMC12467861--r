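# locomode

Window-level recognition of lower-limb locomotion intent from fused surface
electromyography (sEMG) and inertial measurement unit (IMU) signals — the
sensing problem at the heart of exoskeleton and smart-prosthesis control. The
package covers a 13-mode taxonomy: five steady-state modes (level walking LW,
stair ascent/descent SA/SD, ramp ascent/descent RA/RD) and the eight
transitions between level walking and the other terrains (e.g. `RD-LW`, ramp
descent to level walking).

Because multi-subject gait recordings of this kind are rarely shareable,
`locomode` ships a calibrated synthetic generator — mode-specific muscle
activation envelopes modulating a 20–250 Hz stochastic carrier, periodic
segment kinematics with soft-tissue artifacts, powerline interference,
baseline drift, per-trial cadence and gain variability — and every empirical
claim in the package is made and tested on that synthetic benchmark.

## The method

For each non-overlapping 100 ms window:

1. **Preprocess** — zero-phase 4th-order Butterworth filters: 20–250 Hz
   bandpass + 50 Hz notch (Q = 30) for sEMG, 6 Hz low-pass for IMU.
2. **Features** — sEMG: MAV, RMS, VAR, median frequency and mean power
   frequency per channel (6 × 5 = 30); IMU: MAV and VAR per axis
   (18 × 2 = 36); fused: 66 dimensions.
3. **Reduce** — kernel PCA with RBF kernel
   `k(x, y) = exp(-||x−y||² / 2σ²)`: eigendecompose the double-centred Gram
   matrix `K α = nλ α`, retain components to 95% cumulative contribution,
   `σ` from the median heuristic.
4. **Classify** — soft-margin RBF SVM (one-vs-one), with `(C, g)` tuned by an
   improved sparrow search algorithm (ISSA) maximising stratified
   cross-validated accuracy. ISSA augments the sparrow search metaheuristic
   with chaotic opposition-based initialisation, an adaptive inertia weight
   `ψ(t) = sin((π/2)(1 − e^{t/T−1}))` on the followers' exploitation step,
   and greedy Gaussian/Cauchy mutation of the incumbent best.

Evaluation protocols: bootstrap resampling with percentile 95% CIs
(stratified trial-level 80/20 splits, the full stack refitted per iteration),
row-normalized confusion matrices, additive-white-Gaussian-noise robustness
sweeps at 10/5/0 dB SNR, single-modality vs fusion ablation, and streaming
window-by-window prediction.

## Worked example

```r
library(locomode)

cfg <- sim_config()                                   # calibrated defaults
ds  <- generate_dataset(cfg, trials_per_mode = 10, seed = 20260929)
ev  <- bootstrap_evaluate(ds, variant = "kpca_issa_svm",
                          n_iter = 10, seed = 7)
ev
#> <lir_eval> kpca_issa_svm / fusion, 10 bootstrap iterations
#>   median accuracy 93.9%  (95% CI 92.49-95.13%)

modality_ablation(ds, variant = "kpca_issa_svm", seed = 7)
#> # A tibble: 3 × 3
#>   modality n_features accuracy
#>   <chr>         <int>    <dbl>
#> 1 semg             30    0.782
#> 2 imu              36    0.926
#> 3 fusion           66    0.944

snr_sweep(ds, variant = "kpca_issa_svm", snr_db_list = c(10, 5, 0), seed = 7)
#> # A tibble: 4 × 2
#>   snr_db accuracy
#>    <dbl>    <dbl>
#> 1    Inf    0.944
#> 2     10    0.944
#> 3      5    0.916
#> 4      0    0.744
```

The numbers mean: over ten stratified trial-level bootstrap splits of the
130-trial benchmark, the fused kernel-PCA pipeline classifies held-out 100 ms
windows with a median accuracy of 93.9%; fusing the modalities beats either
alone (78.2% sEMG-only, 92.6% IMU-only); and accuracy degrades gracefully as
white noise is injected into the test sEMG down to 0 dB. `autoplot(ev)` draws
the 13 × 13 row-normalized confusion matrix — the residual confusions
concentrate where they should, between each steady mode and its transitions
(e.g. RD vs RD-LW).

The optimizer is usable standalone on any box-constrained maximisation
problem:

```r
res <- ssa_optimize(benchmark_function("rastrigin"),
                    search_space(c(-5.12, -5.12), c(5.12, 5.12)),
                    ssa_control(pop_size = 30, max_iter = 100),
                    variant = "issa", seed = 1)
glance(res)
autoplot(res)   # best-so-far convergence curve
```

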