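---
title: "Methods: spatial-template transient detection, network statistics, and the bi-stable plasticity network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-template transient detection, network statistics, and the bi-stable plasticity network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(devnetdyn)
```

This vignette describes the models and procedures the package implements,
the assumptions behind them, and the numerical and design choices that a
user or reviewer would want to audit. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The problem

Densely labeled two-photon calcium imaging of developing hippocampal CA1
produces movies in which neighboring somata overlap optically. Detection
methods based on the ROI-mean fluorescence then misattribute transients of
one cell to its neighbors. The package implements, end to end:

1. a synthetic movie generator with ground truth (ring-shaped somata,
   controllable pairwise overlap, neuropil contamination, photon noise);
2. spatial-template matched-filter detection of somatic Ca²⁺-transient
   (CaT) onsets — a spatial analog of the Clements–Bekkers sliding
   template;
3. a suite of network-dynamics statistics on binary onset rasters;
4. a ten-dimensional Wilson–Cowan-type rate model of the PC/IN circuit
   with short-term synaptic depression and facilitation (STP-RNN),
   including fixed-point, stability, operating-regime, and
   pulse-experiment analyses.

## 2. Synthetic movies (`simulate_movie`, `overlap_benchmark`)

A movie is `baseline + Σ_cells (ring mask × amplitude × spike train ⊛
kernel) + uniform neuropil ⊛ kernel`, Poisson-resampled per pixel at
`noise_scale` photons per intensity unit. Choices:

* **Transient kernel.** Difference of exponentials, rise 0.18 s, decay
  1.6 s (GCaMP6s-like), unit peak, sampled at the frame rate with value 0
  at the spike frame. Sensor saturation, dye buffering and motion are out
  of scope.
* **Overlap control.** With two cells, the second is translated along the
  line of centers; the realized overlap is the pixel-count intersection
  divided by the single-cell area, bisected and then grid-refined to
  within 2 percentage points (radii ≥ 5 px).
* **Noise.** Per-pixel Poisson with intensity `noise_scale ×` the
  noiseless image, rescaled back, so the relative noise at baseline F is
  `1/sqrt(noise_scale × F)`.
* **Spike trains.** Counts are Poisson at the per-cell rate; frames are
  uniform draws. Each cell has its own RNG sub-stream derived from the
  seed, so editing one cell leaves the others' draws unchanged.
  `min_isi_frames` draws uniformly among minimum-separated configurations;
  `min_cross_isi_frames` additionally enforces separation across cells.

**The standard benchmark** (`overlap_benchmark_config`): two identical
rings (inner 4 px, outer 7 px) in a 40×60 field, 6978 frames at 11.63 Hz
(10 min), amplitude 50% of the baseline fluorescence, neuropil events at
3/min with 10% amplitude, `noise_scale = 4` (≈5% photon noise at
baseline), CaT rate 3/min with ≥1 s within-cell and ≥0.5 s across-cell
event separation, overlaps 0–0.75 in steps of 0.05. Rationale: developing
CA1 pyramidal cells fire CaTs at a few events per minute; discrete somatic
CaT events are separated by seconds; and the across-cell separation makes
the benchmark probe what the spatial template is designed for —
*rejection of crosstalk from an overlapping neighbor* — rather than
demixing of synchronous events, which template matching does not claim to
solve. These settings were fixed once; the tests and the acceptance
script use them as-is. What passing this benchmark does **not** show:
performance under motion artifacts, sensor nonlinearity, slow drift, or
synchronized assemblies of overlapping cells.

## 3. Detection (`detect`, and the pieces it orchestrates)

Per cell:

1. **Candidate onsets.** The ROI-mean fluorescence is differentiated and
   Savitzky–Golay smoothed (order 2, window 6 frames). Peaks are selected
   greedily in descending amplitude, suppressing peaks closer than
   5 frames to an already selected one; up to 8 candidates.
   `signal::sgolayfilt` only supports odd windows, so the package carries
   a small generic local-polynomial smoother (`sg_smooth`) that handles
   even windows and shrinks at the edges.
2. **Template.** For each candidate, the spatial fluorescence change
   (mean of 5 successive frames, minus the per-pixel 500-frame rolling
   median baseline) over the 2-px-expanded ROI is z-scored across ROI
   pixels. Quality control replaces the original protocol's visual
   inspection with two deterministic rules: a candidate is rejected if its
   correlation with the pixelwise median candidate is < 0.5, or if its
   mean weight inside the raw ROI does not exceed the mean weight in the
   expansion rim (both target activations of overlapping somata or
   neurites). Survivors are averaged and re-z-scored; a cell with no
   survivor is excluded and carries an all-zero raster row.
3. **Criterion.** Each frame's spatial change is fit as `ΔF ≈ A·T + C`
   (least squares with free offset); `D = A/σ` with `σ` the residual
   standard error. `D` is invariant to spatially uniform offsets and to
   global intensity rescaling. The residual sum of squares is floored at
   `1e-12·N·Var(T)` because the criterion is undefined at an exact fit.
4. **Onset extraction.** `D` is smoothed (order 2, window 5), negatives
   are clamped to zero (negative-to-positive transitions otherwise create
   false positives), and the noise scale is `1.4826 × median |negative
   deviations|` (the negative half-distribution is signal-free). The
   leading threshold is `max(3.5 × noise, floor)` with `floor = 1.0` in
   `D` units. Because a transient's decay keeps `D` near threshold for
   seconds, a *trailing* threshold at half the leading one adds
   hysteresis: re-crossings inside an open event region are not onsets.
   Events riding on a decay are caught by a rise rule: a local minimum
   followed by a rise of at least the leading threshold before the next
   local maximum. Onsets are placed at the first rising frame and merged
   within a 3-frame refractory gap; invalid frames never carry onsets.
   These internals are the package's own design: the underlying
   general-purpose event-detection routine is cited, not specified, in
   the literature the method derives from, and its leading-threshold
   lower bound is known to exist but not its value.

The comparison detector (`detect_mean_dff`) uses the raw-ROI mean
fluorescence change with the identical extraction machinery (floor 0 in
intensity units), and inherits neuropil and neighbor contamination by
construction.

Evaluation (`evaluate_detection`) matches detections greedily one-to-one
to the nearest unmatched ground-truth event within a 3-frame tolerance
and reports recall, precision, F1 and the mean signed onset delay. With
zero detections, precision is reported as 1 and flagged.

## 4. Network statistics (`cell_statistics` … `detect_motifs`)

All statistics operate on binary onset rasters (`event_raster`), use only
valid frames for time-normalized quantities, and derive every surrogate
from a user-supplied seed.

* **CV2** — `1/(K−1) Σ 2|ICI_{k+1}−ICI_k|/(ICI_{k+1}+ICI_k)`; 0 for
  periodic, 1 for Poisson trains; cells with < 10 intervals are flagged.
* **Gini** — 1 minus twice the trapezoidal area under the Lorenz curve of
  per-cell frequencies.
* **Φ(t)** — fraction of active cells per frame after ±3-frame dilation
  of each cell's vector (tolerates onset jitter). The dilated raster is
  also used for network-burst sizes and participation; raw onsets are
  used for CV2, STTC and population coupling.
* **Network-burst threshold** — the 99.99th percentile of Φ pooled over
  1000 (tests: fewer) surrogate rasters whose per-cell onsets are redrawn
  uniformly over valid frames, preserving counts. Surrogates never place
  events on invalid frames.
* **Continuity** — 116-frame bins are continuous when Φ > 3% in more than
  70% of the bin's frames; a trailing partial bin is dropped.
* **Spectral power** — classical variance-normalized Lomb–Scargle
  periodogram on the valid frames only (tolerates the gaps left by
  drift); band power by trapezoid. Implemented in-package; no installed
  R package provides it.
* **STTC** — the spike-time tiling coefficient with a ±3-frame window;
  per-pair significance against the 95th percentile of per-pair surrogate
  STTCs (count-preserving uniform reshuffles). The percentile is not
  stated in the source literature for this statistic; 95 matches the
  population-coupling convention and is configurable. The pairwise kernel
  is compiled (C++); tests verify it against a brute-force frame-loop
  oracle to 1e-9.
* **Population coupling** — Pearson correlation of a cell's
  Gaussian-smoothed (SD 3 frames) vector with the smoothed sum of all
  others; chance level from surrogates that permute, within 10-frame
  bins, the frame assignments among that bin's events — preserving each
  cell's total count and each frame's population count exactly (asserted
  on every shuffle in the tests). Reported coupling subtracts the mean
  surrogate value; cells with < 5 events are excluded. Rare permutation
  collisions are re-drawn per bin, with the empirical arrangement kept in
  (very rare) stubborn bins.
* **Motifs** — binned activation patterns, matching-index matrix
  (silent patterns excluded), eigendecomposition. Eigenvalue k is
  significant when it exceeds the 95th percentile of the rank-k surrogate
  eigenvalues; the motif count is the *leading run* of significant
  eigenvalues, because the MI matrix has fixed trace (its diagonal is 1),
  so mid-rank eigenvalues co-vary with the leading ones and isolated
  mid-rank exceedances carry no motif structure. Membership uses a deterministic, scale-free loading rule:
  pattern p joins a significant eigenvector when `|v_k(p)| > 2/√P`, and is
  assigned to the eigenvector with maximal |loading| — a documented
  stand-in for the original clustering reference's unstated rule.
  Global similarity is λ₁ normalized by its mean surrogate value.
* **Physiology** — STFT (1-s window, 50% overlap) of the chest-pressure
  trace; respiration and heart rates are the first two ascending-frequency
  peaks of the time-median PSD (a peak must reach 20% of the maximum to
  guard against noise ripples; unresolvable traces yield NA). Movement
  bins exceed the moving median (60 s) plus three moving absolute
  deviations (300 s) of the 0.1–8 Hz band power.

## 5. The STP-RNN model

Two populations (PC ≡ P, IN ≡ I) with threshold-linear responses
`f_i(h) = G_i (h−θ_i)_+` and dynamic synapses carrying depression `x` and
facilitation `u` per synapse class:

```
τ_P Ȧ_P = −A_P + f_P(J_PP u_PP x_PP A_P − J_PI u_PI x_PI A_I + e_P)
τ_I Ȧ_I = −A_I + f_I(J_IP u_IP x_IP A_P − J_II u_II x_II A_I + e_I)
ẋ_ij = (1−x_ij)/τ_r,ij − u_ij x_ij A_j
u̇_ij = (U−u_ij)/τ_f,ij + U (1−u_ij) A_j
```

Defaults (second-postnatal-week parameterization, inhibitory GABA):
τ_P = 15 ms, τ_I = 7.5 ms, J_P = 6.5, J_I = 3, τ_r = 3 s (glutamatergic)
/ 2.5 s (GABAergic), τ_f = 0.4 s, U = 0.8, θ_P = 0.22, θ_I = 0.53,
G = 1, e = 0. Variants: `Mono-RNNi` (θ_P = −0.18) and `Mono-RNNe`
(θ_P = −0.3, θ_I = −0.1, J_I = −1.5, i.e. excitatory GABA).

* **Integration** — fixed-step classic Runge–Kutta (RK4) at dt = 0.2 ms
  in compiled code; the source literature for the model states only the
  step size, and the right-hand side is smooth and non-stiff at this dt.
  Tests cross-check against forward Euler at small dt and verify
  dt-halving convergence. Rates are clamped at 0 and `x`, `u` kept inside
  their invariant intervals against round-off only.
* **Fixed points** — the stationary synaptic variables have closed forms
  `u* = U(1+τ_f A)/(1+U τ_f A)`, `x* = 1/(1+τ_r u* A)`; substituting them
  reduces the steady state to two rate equations. The solver enumerates
  the four threshold regions, runs damped Newton from a log-spaced grid of
  starts in each, deduplicates, verifies each root against the full 10D
  residual (< 1e-9), and reads stability off the numerically
  differentiated 10D Jacobian's eigenvalues.
* **Frozen network** — fixing `u, x` at a state gives a 2D piecewise
  -linear system whose fixed points are solved in closed form per region;
  this exposes the fast dynamics (amplification threshold at the silent
  state, attraction domains at the active state).
* **Pulse experiments** — 20-ms rectangular pulses from a spontaneous
  fixed point; the outcome is the fixed point whose 1e-3 neighborhood
  (uniform norm over all 10 state variables) contains the state after a
  30-s settle. 30 s, rather than the 20 s one might first choose, because
  after a large burst the depression variables recover with τ_r = 3 s and
  need ≈ 21 s to re-enter the 1e-3 ball. A simulated network burst
  (simNB) is flagged when the post-offset peak of `A_P + A_I` exceeds
  both its value at input offset and twice the active-state total rate —
  the literature gives no quantitative criterion; both constants are
  configurable.
* **Deadline** — with the network silenced from its active state at t = 0
  (pulse 0.25/1), the probe (0.25/0.25) is applied at varying inter-pulse
  interval (IPI, measured from the silencing pulse onset); the boundary
  between reaching the active state and falling back to silence is
  bracketed on an IPI grid and bisected to 5 ms. The scan also records
  simNB size and the non-scaled efficacies `u·x` just before the probe.
* **Operating regimes** — a rate-plane point, treated as a candidate
  fixed point with stationary synapses, is ISN when recurrent excitation
  alone would destabilize the PC population (`G_P J_PP u* x* > 1` at
  clamped inhibition) while the full 2×2 frozen Jacobian is stable;
  Non-ISN when stable without excitatory instability; otherwise unstable.
  For excitatory GABA the ISN notion is undefined and Non-ISN means
  stable. **Areas:** the ISN domain narrows to a sliver at high IN rates,
  so cell counting does not converge at practical grids; areas are
  instead measured per IN-rate column from root-refined interval
  boundaries of the switching functions and integrated across 200
  columns (midpoint rule), which is stable to < 0.1% under refinement.
  Plane limits default to A_P, A_I ∈ [0, 50] Hz and are reported with
  every area, as the limits behind published area comparisons are not
  numerically specified; area claims are therefore treated as orderings.

## 6. Problem sizes

The shipped tests and the acceptance script use: the 16-overlap two-cell
benchmark at 10 min per movie (≈1000 ground-truth events); calibration
rasters of 50 cells × 10 min with 200 surrogate shuffles (scaled down
from the 500–1000 used at full scale) and 8 rasters pooled for the
population-coupling fraction; 100-instance oracle sweeps; regime maps at
50×50 labels with 100–200 area columns; and model experiments at
dt = 0.2 ms with 30-s settles. These sizes were chosen once as the
package's standard desk-scale configuration.

## 7. Known limitations

* The generator has no motion, drift, saturation, or depth-dependent
  background; detection performance on it bounds, but does not certify,
  in vivo performance.
* Template matching assumes a stable cell-specific spatial signature; it
  does not demix synchronous events of overlapping cells.
* The motif-membership rule and the STTC significance percentile are
  documented stand-ins where the upstream references leave the choice
  open; both are configurable.
* The model analyses assume the tied parameterization (J_PP = J_IP,
  J_II = J_PI, shared presynaptic STP constants); the fixed-point solver
  handles the general case, but regime analysis is only meaningful under
  the stated criteria.
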