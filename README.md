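# nvctf — transfer-function modeling of neurovascular coupling

`nvctf` links neuronal activity to local blood-flow responses through an
impulse-response (transfer-function) model. It is written for experimenters
who record a neuronal trace — dendritic Ca²⁺ from two-photon linescans, or
LFP gamma-band power — together with a vascular trace — capillary red-blood-cell
(RBC) velocity, power-Doppler (ΔPD/PD) functional-ultrasound signal, or
intrinsic optical reflectance — during stimulus-locked trials, and who want
to ask: *can the vascular response be predicted from the neuronal one, with
a single kernel that transfers across animals and stimulation conditions?*

## The model

The kernel is a shifted gamma density with four parameters,

```
TF(t) = H(t − p₃) · p₄ · ( (t − p₃)^(p₁−1) p₂^p₁ e^(−p₂ (t − p₃)) ) / Γ(p₁)
```

where `p₁` is the shape (slope of the rise), `p₂` the rate (1/s, decay),
`p₃` a pure vascular delay (s, Heaviside time shift `H`), and `p₄` the
amplitude (the kernel's integral). The predicted vascular response is the
convolution of the neuronal trace with `TF`, optionally followed by a
post-hoc amplitude rescale that matches the data over the 2–8 s post-onset
window (the rescale cannot change the Pearson correlation used for all
quality scoring). A valid kernel must start at the origin and be smooth
beyond the delay, which for this family means `p₁ > 1`; its peak sits at
`(p₁ − 1)/p₂ + p₃`.

Because Fourier or Toeplitz deconvolution is fragile on noisy Ca²⁺/RBC
traces, the four parameters are estimated by a stochastic protocol:
repeated simulated-annealing descents of the residual sum of squares
(bounded box `10⁻³`–`10`, raised to `20` for slow kernels), candidate
screening for validity, selection of the best candidate by prediction
Pearson, and iterative restarts from the incumbent until the score stops
improving (typically ≤ 3 iterations of 50–100 runs).

On top of the single-trial fit the package provides:

* **cohort cross-validation** — each subject's kernel predicts every other
  subject's data; a *standard* kernel is selected by the highest average
  Pearson and the smallest coefficient of variability;
* **two-component decomposition** — under strong stimulation a delayed
  secondary vascular phase (onset ~15 s, peak ~25–30 s) appears; it is
  isolated by subtracting the standard prediction, fitted with a second
  kernel, and the pair is recombined by nonnegative least squares;
* **AUC voxel ranking** — trapezoidal area-under-curve ranking of a voxel
  panel over a response window;
* **a synthetic trial generator** — stimulus-locked trials (30/60 s
  acquisitions, 5 s baseline, GCaMP6f-like kinetics, ground-truth kernels,
  optional secondary component, Gaussian noise) so the whole pipeline is
  testable without any recordings.

## Worked example

Simulate one trial from the standard kernel (shape 1.3, rate 0.5 /s, shift
0.27 s, amplitude 0.19 — peak at 0.87 s), preprocess, and refit it:

```r
library(nvctf)

cfg   <- sim_config(noise_sd_from = 0.02, noise_sd_to = 0.05, seed = 42)
trial <- simulate_trial(cfg)
from  <- cut_fit_window(trial$from, 30)   # Ca²⁺ trace, 5–27 s fit window
to    <- cut_fit_window(trial$to, 30)     # vascular trace

fit <- fit_tf(from, to, fit_config(runs_per_iteration = 20, seed = 42))
fit
#> <tf_fit> shifted-gamma transfer function
#> <tf_params> shape p1 = 1.125, rate p2 = 0.4675 /s, shift p3 = 0.4583 s, amplitude p4 = 0.1887
#>   peak time: 0.726 s
#>   Pearson r = 0.9895, SSR = 0.03992, 2 iteration(s), 40 runs logged

tidy(fit)
#> # A tibble: 1 × 5
#>      p1    p2    p3    p4 peak_time
#>   <dbl> <dbl> <dbl> <dbl>     <dbl>
#> 1  1.13 0.468 0.458 0.189     0.726
```

At 5 % vascular noise the fit predicts the held-out trace with r ≈ 0.99;
the individual parameters trade off against each other (shape down, shift
up here), but the identifiable quantities — the kernel peak time (0.73 s
fitted vs 0.87 s generating, within the noise-level tolerance) and the
amplitude (0.189 vs 0.19) — are recovered. `autoplot(fit)` draws the kernel
and the prediction overlay; `augment(fit)` returns the per-sample
observed/predicted/residual table.

Cohort-level use follows the same grammar:

```r
cohort <- make_cohort(sim_config(n_subjects = 6, noise_sd_to = 0.05, seed = 1))
fits   <- lapply(seq_len(nrow(cohort)), function(i)
  fit_tf(cut_fit_window(cohort$from[[i]], 30),
         cut_fit_window(cohort$to[[i]], 30),
         fit_config(seed = i)))
report <- loo_cross_validate(cohort, fits)
glance(report)       # per-kernel self/cross summaries + selection
autoplot(report)     # cross-validation heatmap
```

A command-line wrapper over the same functions lives at
`inst/cli/nvctf.R` (subcommands `simulate`, `fit`, `predict`, `crossval`,
`secondary`, `rank-voxels`).

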