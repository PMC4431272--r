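# emgmotion

Surface electromyography (sEMG) feature extraction and upper-limb motion
classification in R.

## The problem

sEMG electrodes on the skin pick up the electrical activity of skeletal
muscle. Mapping six muscle channels — flexor/extensor carpi radialis and
ulnaris (FCR, FCU, ECR, ECU), biceps and triceps brachii (BB, TB), sampled
at 1000 Hz — onto nine classes (elbow flexion/extension, forearm
pronation/supination, wrist flexion/extension, wrist abduction/adduction,
and rest) is the control front-end for prostheses, exoskeletons and robot
arms. The practical constraints are the recognition rate *and* the
per-prediction latency: at 1 kHz anything above 1 ms per loop falls behind
the signal.

`emgmotion` implements a full comparison stack for this task:

* **Conditioning** — 2nd-order Butterworth high-pass (causal or zero-phase),
  full-wave rectification, MVC normalization.
* **Wavelet packet transform** — Daubechies-2, level 4 (16 subbands),
  perfect-reconstruction filter bank with symmetric or orthonormal
  periodization boundary handling and optional universal soft-threshold
  denoising.
* **Four feature extractors**, each one scalar per muscle per tick:
  * `RMS` — windowed root mean square (100-sample window, 25-sample step;
    40 features/s),
  * `WP` — *Weight Peaks*: thresholded zero crossings → peak/valley
    magnitudes → recursive weighting
    `P[i+1] <- (n-1)/n P[i] + 1/n P[i+1]`, run per wavelet-packet node and
    merged (≈ one feature per sample on broadband input),
  * `DFA` — windowed detrended fluctuation `F(L) = sqrt(mean((X_j - aj -
    b)^2))` on disjoint 100-sample windows (10 features/s),
  * `MM` — Hill-type muscular model: activation recursion
    `u(t) = α e(t-d) - β1 u(t-1) - β2 u(t-2)` with stability constraints
    `β1 = γ1+γ2`, `β2 = γ1 γ2`, `|γ| < 1`, `α - β1 - β2 = 1` (unit DC
    gain), then a 4 Hz force-like low-pass (1000 features/s).
* **Two classifiers** over the 6-dimensional per-tick vectors:
  * `NN` — one hidden layer of 8 tanh units, 9 logistic outputs with
    one-of-k targets, seeded deterministic training,
  * `SVM` — sequential minimal optimization (Platt SMO) with linear or RBF
    kernel, one-vs-one multiclass voting; `n_support` = kernel evaluations
    per prediction.
* **Synthetic data** — six-channel amplitude-modulated 10–450 Hz Gaussian
  sEMG driven by a muscle-by-motion synergy matrix, with per-sample labels;
  every pipeline stage is testable without human recordings.
* **Pipeline + CLI** — `run_training()`, `run_online()` (causal streaming
  evaluation with latency accounting), `run_comparison()` over all 8
  method combinations; subcommands `simulate | extract | train | evaluate |
  compare`.

## Worked example

```r
library(emgmotion)

# 8 motions x 10 trials of synthetic sEMG; train on trials 1-5, test on 6-10
ds <- generate_dataset(1:8, 10, base_seed = 100, snr_db = 15)
sp <- split_by_trial(ds, 5)

cfg <- pipeline_config("MM", "SVM", train_cap = 4000, seed = 7)
tr  <- run_training(sp$train, cfg)
tr$report$train_accuracy
#> [1] 0.971
tr$model$n_support
#> [1] 372

ev <- run_online(sp$test, tr$model, cfg)
ev
#> <evaluation_report MM+SVM> accuracy 0.971 over 160000 ticks
```

Training accuracy 0.971 means 97.1% of the capped training ticks were
assigned the right motion; the held-out streaming accuracy (0.971 here) is
computed tick by tick on unseen trials, building each 6-vector causally from
the data available at that tick. `n_support = 372` says each streaming
prediction costs 372 kernel evaluations. The same dataset pushed through
`run_comparison(sp$train, sp$test, cfg)` yields the 8-row
feature-method-by-classifier table with the per-method feature rates
(RMS 40/s, WP ≈ 1000/s merged, DFA 10/s, MM 1000/s at 1 kHz).

From the shell:

```sh
Rscript inst/cli/emgmotion.R simulate --out data --motions 1-8 --trials 5 --seed 1
Rscript inst/cli/emgmotion.R train    --in data --model model.json --method mm --classifier svm
Rscript inst/cli/emgmotion.R evaluate --in data --model model.json --method mm --classifier svm
```

## Documentation

Function documentation lives in the roxygen comments under `R/`; the
methods vignette (`vignettes/motion-recognition-methods.Rmd`) explains the
models, parameter choices, numerical tolerances, what the synthetic
generator does and does not emulate, and known limitations.
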