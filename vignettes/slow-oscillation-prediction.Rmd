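---
title: "Predicting slow hemodynamic fluctuations with a GRU: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting slow hemodynamic fluctuations with a GRU: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slowpred)
```

## The problem

Resting-state fMRI signals are dominated by slow (< 0.1 Hz in awake
humans, < 0.05 Hz in anesthetised rodents) hemodynamic fluctuations.
Signals extracted from single penetrating venules carry this slow
oscillation with a much better contrast-to-noise ratio than parenchymal
voxels, and their phase structure tracks brain state. `slowpred`
implements a forecasting view of this signal: a gated recurrent unit
(GRU) is trained to output, at every time step, the band-limited slow
oscillation 10 s into the future. How well a fixed trained network
predicts a session (the Pearson correlation CC between prediction and
target, the *prediction score*) then becomes a data-driven index of
brain state.

Three ingredients make the score meaningful:

* **IAAFT surrogate controls.** For every trace a surrogate is built
  with identical amplitude distribution and near-identical power
  spectrum but randomised Fourier phases. Any excess prediction score
  of real traces over their surrogates measures structure beyond
  second-order (linear Gaussian) statistics, because all linear
  statistics are shared by construction.
* **An ARMAX baseline.** A classical autoregressive-moving-average
  model with exogenous input, estimated by prediction-error
  minimisation, forecasting the same 10-s horizon. It bounds what
  linear system identification achieves on the same data.
* **Session classification.** Applying one trained network across many
  sessions, grouping sessions by extreme prediction scores (top/bottom
  5%), and relating scores to seed-correlation maps, global-signal
  variance and the intrinsic default-mode-network (DMN) correlation.

## The GRU forecaster

The recurrence, for scalar input $x(t)$ and hidden state $h(t)$:

$$
\begin{aligned}
r(t) &= \sigma(W_{ir} x(t) + b_{ir} + W_{hr} h(t-1) + b_{hr})\\
z(t) &= \sigma(W_{iz} x(t) + b_{iz} + W_{hz} h(t-1) + b_{hz})\\
n(t) &= \tanh(W_{in} x(t) + b_{in} + r(t) \odot (W_{hn} h(t-1) + b_{hn}))\\
h(t) &= (1 - z(t)) \odot n(t) + z(t) \odot h(t-1)
\end{aligned}
$$

with a linear readout $y(t) = w_{out} \cdot h(t)$ (optionally with the
input concatenated into the readout, the *residual* path). The
forward pass and backpropagation through time are implemented in
compiled code (`src/gru_ops.cpp`) and verified in the test suite
against an independent scalar R implementation of the four equations
and against finite-difference gradients.

Two presets ship with the package (`gru_preset()`): *human* (1 layer,
hidden size 88, CC loss, Adam learning rate 0.00121, L2 0.0221, batch
10, 69 epochs) and *rat* (2 layers, hidden 290, CC loss, learning rate
0.001, L2 3e-4, dropout 0.128, residual readout, batch 22, 87 epochs).
Both use a 250-sample washout: the first 250 outputs only drive the
network into a trace-specific state and are excluded from the loss and
from all scoring. The optimiser is Adam; the reference work used
gradient-based training without specifying the optimiser in detail, and
Adam is the conventional choice for gated recurrent networks.
Parameters are initialised uniformly in $\pm 1/\sqrt{H}$.

The CC loss returns $-\mathrm{CC}$ (prediction vs. target over
post-washout samples, averaged over the sequences of a batch); since CC
is the evaluation metric, optimising it directly is natural, and it
makes training invariant to affine rescaling of the targets (a property
the tests assert). `mse_cc` combines the two objectives with equal
unit weights; the weights were a genuinely open choice and are
configurable.

## Preprocessing

* **Welch PSD** (`welch_psd()`): 1024-point DFT, Hann window of length
  128, 50% overlap; these defaults are used everywhere a spectrum is
  needed, including normalisation.
* **Frequency normalisation** (`frequency_normalize()`): the mean is
  removed and the trace divided by the *square root* of its mean PSD
  above 0.2 Hz. Above 0.2 Hz vessel spectra are flat (noise floor), so
  this brings all traces to a common unit high-frequency baseline while
  preserving relative slow-oscillation strength. Dividing by the mean
  PSD itself (not its square root) would not produce a unit baseline,
  since power scales quadratically with amplitude; the package
  nevertheless exposes `literal_division = TRUE` for that variant. The
  square-root convention is the package's resolution of this
  ambiguity, chosen so that the documented postcondition (recomputed
  mean high-frequency PSD equal to 1) holds exactly and the operation
  is idempotent and scale-invariant.
* **Band-pass filtering** (`bandpass()`): Butterworth design, order 4
  per pass, applied forward-backward for zero phase (effective order
  8). The exact order of the original MATLAB filter is not
  recoverable; order 4 is the conventional default and is exposed as a
  parameter. Edge handling uses odd-reflection padding of three filter
  lengths plus steady-state initial conditions, the standard zero-phase
  recipe.
* **Targets** (`make_target_pair()`): input = normalised raw trace;
  target = band-passed normalised trace advanced by 10 s
  (`target[t] = filtered[t + 10/dt]`). The 10-s horizon matches the
  lag at which the slow oscillation's autocorrelation is strongly
  reduced. For noiseless synthetic inputs (pure sinusoids) whose
  high-frequency power is numerically zero, `normalize = FALSE` skips
  the (degenerate) normalisation.
* **Resampling** (`resample_to_dt()`): windowed-sinc interpolation
  with an anti-aliasing cutoff at the smaller Nyquist frequency,
  used e.g. to bring 0.72-s-TR sessions to the 1-s grid of the trained
  models. Linear interpolation is available for comparison.

Whether scoring should use only post-washout samples is implied but
not fully pinned by the source material; the package scores
post-washout only (the washout argument of `predict_gru()` makes the
choice explicit and configurable).

## IAAFT surrogates

`iaaft()` iterates two steps from a seeded random permutation of the
source: impose the source's Fourier magnitudes keeping current phases,
then rank-remap values onto the source's sorted amplitudes. The
iteration reaches a fixed point within roughly a hundred steps whose
residual spectral error depends on the starting permutation (observed
range about 0.007-0.012 relative RMS on 900-sample vessel traces), so
the iteration budget (`max_iter`, default 1000) is spread over ten
seeded restarts and the best surrogate kept; the achieved error and
total iteration count are recorded in the result. The amplitude step
runs last, so the value multiset is preserved exactly; ties in the
rank remap are broken stably. One surrogate per vessel is generated
(`surrogate_set()`), with per-vessel seeds derived deterministically
from the master seed.

## ARMAX baseline

The model
$y(t) + a_1 y(t-1) + \dots + a_{n_a} y(t-n_a) =
 b_1 u(t-n_k) + \dots + b_{n_b} u(t-n_k-n_b+1) +
 c_1 e(t-1) + \dots + c_{n_c} e(t-n_c) + e(t)$
is estimated by prediction-error minimisation: a Hannan-Rissanen start
(long-AR residuals feeding a linear regression), extended-least-squares
iterations, then BFGS refinement of the exact one-step error recursion.
The delay is fixed at $n_k = 10$ samples so that, with unshifted raw
inputs $u$ and band-passed outputs $y$, forecasting 10 steps ahead
matches the GRU's prediction horizon. Multi-step forecasts set future
innovations to zero (minimum-MSE forecast). `grid_search_orders()`
evaluates $(n_a, n_b, n_c)$ grids by cross-validated 10-step forecast
CC; the desk-scale default grid is 1-10 x 1-10 x 0-5 (the full-scale
published search, orders to 50 by 1 and to 150 by 5, is the same code
on a larger grid and is cluster-scale). The exogenous input is the
normalised raw trace and the output the band-passed trace — the
pairing implied, though not spelled out, by the source description.

## Brain-state classification

`score_sessions()` applies one trained model to many sessions and
tabulates per-session CC, lag, global-signal variance and (when a DMN
component trace is available) the intrinsic DMN correlation — the mean
over DMN voxels of their correlation with the DMN component time
course (mean of correlations, not correlation of means).
`percentile_groups()` selects top/bottom 5% sessions;
`difference_map()` contrasts group-averaged seed-correlation maps with
a Fisher-z two-sample test and Benjamini-Hochberg FDR mask;
`binned_relationship()` produces the 2%-binned score-vs-DMN-index
curve; `variance_groups()` builds the competing variance-based
classification; `spectral_reorder()` reorders correlation matrices by
the Fiedler vector of the graph Laplacian of the affinity
$A = (C + 1)/2$ (zero diagonal, sign fixed by the first element,
per-component ordering with a warning if the affinity graph is
disconnected). `probe_preference_map()` probes a trained model with
narrow-band signals over a grid of peak frequencies and widths,
averaging the prediction CC per cell. Probes are fed at their
generated unit variance without the high-frequency renormalisation
(which is degenerate for signals with no noise floor), and probes
whose in-band power fraction falls below 1e-4 score 0: their
band-passed "target" would consist solely of filter edge ringing (an
inherent property of zero-phase filtering, not an implementation
artifact), so there is no in-band structure to predict.

With real data the DMN component trace is user-supplied (e.g. from a
group ICA); deriving group ICA maps and full dual regression are out of
scope, and only the correlation-with-supplied-trace step is
implemented.

## Vessel localisation

Venules appear as dark dots on anatomical images. `localize_vessels()`
runs a local-minimum filter over a 3x3 window (the literal reading of
"1 voxel-wide neighbourhood" — a 1x1 window — would be a no-op, so the
centre +/- 1 voxel is used and the size is configurable), then a 10x10
moving-average filter normalised by the filter size, then thresholds at
the darkest 2% quantile (no threshold value is given in the source;
2% is the package default and a parameter). Both filter stages are
documented interpretations, not published facts. `combine_masks()`
ANDs the vessel mask with a thresholded component map;
`extract_timecourses()` averages each connected mask component.

## The synthetic data generators

The generators define the study conditions under which the pipeline is
tested; no external data are needed.

* `generate_vessel_trial()` emulates 15-minute, 1-s-TR single-vessel
  recordings: 900 samples per trace, one shared slow component
  $s(t)$ mixed into every vessel with weight drawn from [0.8, 1.2],
  plus 1/f colored noise (sd 0.7) and white noise (sd 0.7) at a
  combined variance close to the (unit) variance of $s$ — an SNR of
  about 1, consistent with vessel traces whose spectra show the
  shared component clearly but with substantial noise. The shared
  component is a band-limited Gaussian process built by
  frequency-domain shaping; its spectral envelope is a Gaussian peak
  at 0.035 Hz with standard deviation 0.013 Hz (FWHM 0.031 Hz, the
  width reported for human vessel spectra) rather than a flat band.
  The peak matters beyond realism: for a flat in-band spectrum even an
  optimal 10-s-ahead predictor's cross-correlation with its target
  peaks at a positive lag (nearer targets always correlate better
  with the causal past when the autocorrelation decays
  monotonically), whereas predictions of a peaked, oscillatory
  process phase-lock and the lag distribution centres at 0 — the
  behaviour real vessel data show. `peak_hz = NA` selects a flat band.
* **Phase-amplitude coupling.** Real vessel signals carry
  cross-frequency structure: high-frequency power rides on the phase
  of the slow oscillation. The generator therefore modulates the
  amplitude of the vessel noise by the momentary value of $s(t)$:
  `amp(t) = max(1 + pac * s(t), 0) / sqrt(1 + pac^2)` with
  `pac_strength = 4` by default. This is exactly the feature that
  IAAFT surrogates destroy and linear statistics cannot capture, and
  it is why a trained nonlinear forecaster can score real traces above
  their surrogates even though both have identical spectra and
  amplitude distributions (for a linear-Gaussian trace the surrogate
  is statistically equivalent to the source, and no predictor can
  separate them in expectation). With `pac_strength = 0` the traces
  are linear-Gaussian and the real-vs-surrogate score difference
  vanishes — a useful negative control.
* `generate_network_session()` builds multi-ROI sessions as
  `global_coupling * g(t) + dmn_coupling * d(t)` (DMN subset only)
  plus noise, with independent band-limited `g`, `d` returned as
  ground truth. Sweeping the couplings in opposite directions across
  sessions emulates the regime where global fluctuation strength rises
  while DMN-internal coherence falls.
* `generate_probe_signal()` shapes white noise by a Gaussian spectral
  envelope (peak `f0`, width `width`), unit variance.
* `generate_vessel_image()` draws non-overlapping dark discs on a
  bright background (rejection sampling, minimum centre distance three
  radii) with a ground-truth mask.

What the generators do *not* emulate: cardiac/respiratory
quasi-periodic confounds, head motion, MRI physics, spatial
autocorrelation of noise, inter-subject variability beyond independent
seeds. Passing the synthetic-mirror tests therefore shows the pipeline
implements the method correctly under the stated statistical structure;
it does not certify performance numbers on real recordings.

## Numerical choices and degenerate inputs

* Sub-seeds for vessels, surrogates and probes are derived as
  `(seed * 48271 + index * 7919) mod 2147483629`, keeping all seeds in
  32-bit range.
* Training is single-threaded and bit-deterministic given the config
  seed; batches group equal-length sequences.
* Constant traces are rejected by `iaaft()` (undefined ranks),
  `frequency_normalize()` (zero high-frequency power) and correlation
  routines (zero variance); sliding windows truncated below 3 samples
  yield `NA`.
* Cross-correlation lags use unnormalised cross-correlation of
  z-scored series (ties broken toward the smallest absolute lag), the
  convention under which a prediction that lags the target gets a
  positive lag.
* `percentile_groups()` breaks ties by stable original order (earliest
  indices to the bottom group, latest to the top).
* The ARMAX recursion restarts at trial boundaries when trials are
  pooled; unstable or non-invertible estimates are flagged in the
  returned model, never silently accepted.

## Problem sizes used by the test-suite and acceptance script

The synthetic mirrors run at desk scale, chosen so the full suite
completes comfortably on a single CPU: 24 synthetic trials of 5
vessels each — 120 traces of 900 samples over 24 independent shared
components, the forecaster trained on half and scored on the held-out
half — one surrogate per held-out vessel, an ARMAX comparison on a
reduced order grid (1-4 x 1-2 x 0-1), and 60 synthetic network
sessions for the brain-state analyses. Spreading the suite over many
independent shared components matters for the lag statistics: vessels
of one trial share a component, so their lags are correlated, and the
median over few components is dominated by each component's realised
peak frequency; 12 held-out components give a stable median. These
sizes are the package's own defaults for reproducible examples; the
same code scales to larger cohorts unchanged.
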