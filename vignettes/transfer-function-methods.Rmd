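---
title: "Methods: shifted-gamma transfer functions for neurovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shifted-gamma transfer functions for neurovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvctf)
```

## The model and its assumptions

Neurovascular coupling is modeled as a linear time-invariant system: the
vascular response (capillary RBC velocity, power-Doppler CBV, or optical
reflectance, expressed as a baseline-relative change) is the convolution of
the neuronal activity trace (baseline-subtracted dendritic Ca²⁺, or a
stimulus step function) with a single impulse-response kernel,

$$\mathrm{TF}(t) = H(t-p_3)\, p_4\,
  \frac{(t-p_3)^{p_1-1} p_2^{p_1} e^{-p_2 (t-p_3)}}{\Gamma(p_1)} .$$

This is the single gamma component familiar from BOLD hemodynamic response
functions, augmented with a Heaviside time shift $p_3$ standing for a pure
vascular delay. No negative (undershoot) component is included: the
anesthetized-preparation responses the model targets show no post-stimulus
undershoot, and the family is deliberately kept at four parameters so the
stochastic fit remains well-conditioned on single trials. Linearity and
time-invariance are assumptions, not conclusions: they hold well within a
moderate activation range and visibly fail under strong stimulation, which
is exactly what the two-component extension (below) captures.

A kernel is **valid** when its curve starts at the origin and is at least
twice differentiable past the shift, which for this family reduces to
$p_1 > 1$ (at $p_1 < 1$ the kernel diverges at onset; at $p_1 = 1$ it jumps
to $p_2 p_4$). Validity is enforced as a screen on fit candidates, not as a
bound during optimization, mirroring how a practitioner discards
degenerate annealing runs rather than constraining them away. For a valid
kernel the peak time is the identifiable summary:
$t_{peak} = (p_1-1)/p_2 + p_3$ — individual parameters trade off along
ridges of the likelihood, but the peak survives (the parameter-recovery
tests therefore score peak-time error, not per-parameter error).

## Preprocessing conventions

* Traces are interpolated onto uniform grids with **shape-preserving pchip**
  (monotone piecewise-cubic Hermite, `signal::interp1`). Plain cubic
  splines are avoided because their overshoot distorts onset kinetics; the
  cost is that pchip is not exact on polynomials above degree one, which
  the tests acknowledge by asserting knot exactness plus an $O(h^3)$-scale
  band between knots.
* Baselines use the **5 s immediately preceding stimulus onset** (onset is
  trial metadata, never inferred from the trace): Ca²⁺ is
  baseline-subtracted; vascular traces are subtracted and divided
  (relative change). An optional 3-point median filter attenuates isolated
  RBC-velocity overestimates; it is opt-in because not every trace needs it.
* Fitting and scoring use the window **5–27 s for 30 s acquisitions and
  5–59 s for 60 s acquisitions** (absolute time from acquisition start).
  The output grid starts at the first grid point at or past the window
  start; sub-sample windows are not interpolated.
* The canonical From grid is **50 ms**; vascular traces keep their native
  uniform grid (power-Doppler is under-sampled to 20 Hz through the same
  pchip path before fitting). Baseline subtraction is applied after the
  final interpolation.

## Discrete convolution convention

The From signal is treated as a zero-order-hold step function (constant
over each 50 ms bin, zero before its first sample — justified for
baseline-subtracted traces). The kernel weight at lag $m$ is then the exact
bin integral
$w_m = p_4[P(p_1, p_2(m\Delta t - p_3)) - P(p_1, p_2((m{-}1)\Delta t - p_3))]$,
$w_0 = 0$, with $P$ the regularized lower incomplete gamma. Two properties
motivate this over sampling the kernel pointwise and multiplying by
$\Delta t$: the weights sum to $p_4$, so the amplitude parameter has a
sampling-rate-independent meaning; and the response to a unit step equals
the closed-form incomplete-gamma expression exactly at grid points, so the
convolution error does not grow with kernel sharpness. Any residual
convention mismatch against external kernel tables is absorbed by the
post-hoc amplitude rescale.

The rescale itself finds the scalar minimizing the squared residuals
between prediction and data over 2–8 s after onset, by a derivative-free
bounded line search. A positive scale cannot change the Pearson
coefficient — the invariance is asserted to machine precision in the
tests — which is why all quality scoring is done on the correlation, before
rescaling.

## The stochastic fitting protocol

Deconvolution by Fourier or Toeplitz inversion is too noise-sensitive for
single-trial Ca²⁺/RBC data, so the kernel is fitted by bounded simulated
annealing of the residual sum of squares:

* box bounds $10^{-3}$ to $10$ on all four parameters (raised to $20$ where
  slow kernels require it; the Ca²⁺→power-Doppler convention restricts
  $p_3 \le 0.5$ s);
* initial set $(6, 1, 0.001, 1)$ — the first gamma component of the
  canonical HRF, with the shift started at the $10^{-3}$ numerical floor
  standing in for zero;
* per run: 600 Metropolis moves with initial temperature 100 and
  exponential cooling ($0.95^k$), Gaussian proposals scaled to the box and
  to $\sqrt{T/T_0}$, and triangle-wave reflection at the bounds, followed
  by a short Nelder-Mead refinement clamped to the box (the same
  derivative-free simplex family used for the amplitude rescale; it
  converts the annealing basin into a precise minimizer at negligible
  cost);
* per iteration: 50 independent runs (50–100 is the intended range); valid
  candidates are scored by prediction Pearson with SSR as tie-break; the
  best becomes the next iteration's initial set;
* the protocol stops when the relative Pearson improvement drops below
  $10^{-3}$, with a hard cap of 3 iterations.

Every run's seed derives deterministically from the master seed, so the
nondeterministic algorithm is an exactly reproducible function of (inputs,
configuration, seed). "Prediction quality" for candidate scoring is
defined as the Pearson coefficient — the study metric throughout — rather
than the SSR being annealed; on clean data the two agree, and on noisy data
the correlation is the quantity the downstream cross-validation uses.

## Cross-validation and standard-kernel selection

For a cohort, each subject's kernel predicts every subject's data, filling
a full matrix (diagonal = self-validation). The reported cross statistics
(mean and coefficient of variability, SD/mean — the standard definition,
since none is prescribed) exclude the diagonal: they measure pure
cross-subject transfer. **Selection** of the standard kernel, however,
judges each kernel on the full row — its own dataset *and* the others':
highest average Pearson and smallest CV, the first criterion preferred when
no kernel wins both, ties broken toward the lowest subject index. The
self entry is included deliberately. A kernel fitted on a corrupted
recording can still predict clean subjects tolerably (zero-mean noise does
not bias the least-squares kernel much), while every clean kernel is
penalized equally for being scored against the corrupted subject's data;
only the self entry separates the two cases, and excluding it can make the
corrupted subject the *winner* of a purely off-diagonal score. The
corrupted-cohort simulation in the test suite exercises exactly this.

Self-validation scores the raw (un-rescaled) prediction: a positive scale
factor cannot change the coefficient, and scoring before rescale keeps
anti-correlated data visibly negative instead of letting a negative scale
flip it.

## Secondary vascular component

Under strong stimulation the response becomes bimodal: a delayed CBV phase
starts around 15 s and peaks around 25–30 s. The decomposition is:
subtract the amplitude-rescaled standard prediction; fit a second kernel to
the residual with the same protocol but widened bounds (upper bound 20 on
all parameters, time shift allowed up to 20 s, so the delay can be carried
by $p_3$ rather than forcing extreme $p_1/p_2$ ratios — the
parameterization of the delay is a package decision, as no reference
parameter table exists for the secondary kernel); recombine as
$a_1 (x \ast TF_1) + a_2 (x \ast TF_2)$ with $(a_1, a_2)$ fitted by
nonnegative least squares (closed-form two-variable active set) over the
full window. Residual fluctuations between 5 and 15 s mostly reflect small
onset/slope mismatches rather than a genuine component; the fit uses the
full window by default but an optional mask for that band is exposed.

## The synthetic trial generator

The generator emulates the study conditions so that every stage has a
ground-truth test surface: 30 s or 60 s acquisitions with a 5 s
pre-stimulus baseline (onset 10 s by default), boxcar odor-like stimuli of
0.12–5 s, a calcium transient formed by convolving the boxcar with a
unit-peak difference-of-exponentials kernel (rise 0.1 s, decay 1 s —
GCaMP6f-like), and a vascular trace formed by the package's own forward
convolution with a ground-truth kernel (default: shape 1.3, rate 0.5 /s,
shift 0.27 s, amplitude 0.19, peaking at 0.87 s), optionally plus a
delayed secondary kernel at a fixed amplitude ratio. Noise is i.i.d.
Gaussian, scaled to the noiseless response peak; cohorts apply lognormal
multiplicative jitter per kernel parameter (redrawn until valid).

What the generator does **not** emulate: sniff-locked stimulus timing,
olfactory nonlinearities, autocorrelated physiological noise, slow drifts,
or the awake-state undershoot. Passing tests therefore demonstrate that
the pipeline recovers what it models — not that real recordings satisfy
the linear model; the cross-validation machinery exists precisely to test
that on data.

## Numerical choices and problem sizes

* Degenerate fits: with a zero (or pure-noise) target, the SSR floor is a
  collapsed prediction, reachable either by the amplitude at its lower
  bound or by pushing the kernel mass outside the window; tests assert the
  collapse, not a particular minimizer coordinate.
* Ties in AUC voxel ranking use dense ranking (AUCs rounded at 1e-12 to
  absorb float noise); trapezoidal integration over
  [stimulus onset, window end] by default.
* Returned parameters are clamped strictly inside the box (margin
  $10^{-9}$ of the box width) so downstream validity checks never sit on a
  boundary.
* Monte-Carlo study sizes in the test suite: noiseless recovery uses the
  full 50-run × ≤3-iteration protocol; the 10%-noise recovery study (20
  seeds) and the cohort studies (6 clean subjects; 3 clean + 1 corrupted
  × 20 seeds) use 8–12 runs over ≤2 iterations with 400 moves — enough for
  the scored properties while keeping the suite comfortably within a
  desktop run.

## Known limitations

Single-kernel linearity fails under strong stimulation (that failure is
modeled, not fixed); the secondary kernel is phenomenological, with no
mechanistic claim about astrocytic or other origins; amplitude is
explicitly not transferable across subjects (only the dynamics are — hence
the per-trial rescale); and irregularly sampled inputs are handled only
through the initial interpolation, so gaps longer than a few samples
should be treated upstream.
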