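# devnetdyn

Tools for studying network dynamics in the developing hippocampus from
population calcium imaging, in three connected parts:

1. **Transient detection in densely labeled tissue.** Somatic GCaMP
   signals have a cell-specific, ring-like spatial profile. For each cell
   the package builds a z-scored spatial template of its fluorescence
   change and scales it optimally to every frame, `ΔF ≈ A·T + C`; the
   detection criterion `D(t) = A/σ` (the Clements–Bekkers statistic,
   applied in space rather than time) rises only when the frame's spatial
   configuration matches the template, making detection robust to
   overlapping neighbors and neuropil. A mean-ΔF reference detector is
   included for comparison.
2. **Network statistics on event rasters.** Firing irregularity (CV2),
   Gini dispersion of event frequencies, fraction of active cells Φ(t)
   with surrogate-calibrated network-burst detection, discontinuous /
   continuous activity classification, Lomb–Scargle spectral power,
   spike-time tiling coefficients (STTC), population coupling, motif
   detection by eigendecomposition of the matching-index matrix, and
   pressure-sensor physiology (respiration/heart rate, movement epochs).
3. **A bi-stable recurrent network model.** A 10-dimensional
   Wilson–Cowan-type model of pyramidal-cell and interneuron populations
   with short-term synaptic depression and facilitation (STP-RNN):
   simulation, fixed points and their stability, frozen-weight 2D
   analysis, inhibition-stabilized-network (ISN) regime maps,
   pulse-driven state transitions, the internal deadline of the
   silent-to-active transition, and synaptic-strength scaling studies.

A synthetic data generator (ring-shaped somata with controlled spatial
overlap, ground-truth spike trains, structured rasters) makes the whole
pipeline testable without recordings.

## Worked example

Simulate two cells whose somata overlap by 50% of their area, detect
transients with both detectors, and score them against ground truth:

```r
library(devnetdyn)

cfg <- overlap_benchmark_config(seed = 11)
cfg$overlap_fraction <- 0.5
sim <- simulate_movie(cfg)
labels <- masks_to_labels(sim$masks)

res  <- detect(sim$movie, labels)            # spatial template matching
ref  <- detect_mean_dff(sim$movie, labels)   # ROI-mean baseline detector

for (i in 1:2) {
  m  <- evaluate_detection(res$event_series[[i]], sim$truth$spikes[[i]], 3)
  m2 <- evaluate_detection(ref$event_series[[i]], sim$truth$spikes[[i]], 3)
  cat(sprintf("cell %d: template recall %.2f precision %.2f | mean-dF precision %.2f\n",
              i, m$recall, m$precision, m2$precision))
}
#> cell 1: template recall 1.00 precision 1.00 | mean-dF precision 0.50
#> cell 2: template recall 1.00 precision 1.00 | mean-dF precision 0.60
```

The template detector retrieves every ground-truth event without false
positives; the mean-ΔF detector fires on the neighbor's transients and on
neuropil events, costing it nearly half its precision.

Model side — the default network is bi-stable, and a probe pulse from
silence evokes a supra-amplification burst (simNB):

```r
p <- stp_rnn_params()
find_fixed_points(p)
#>          A_P       A_I stable  max_re_eig     residual
#> 1 0.00000000 0.0000000   TRUE  -0.3333333 0.000000e+00
#> 2 0.06205785 0.0000000  FALSE 236.2901066 6.013708e-15
#> 3 0.63048160 0.3204816   TRUE  -0.5698868 1.480297e-14

pulse_experiment(p, "silent", 0.25, 0.25)[c("outcome", "simNB")]
#> $outcome
#> [1] "to_silent"
#> $simNB
#> [1] TRUE
```

Two stable states (silent at exactly 0 Hz; active at A_P ≈ 0.63 Hz,
A_I ≈ 0.32 Hz) flank one unstable fixed point; from silence, a balanced
20-ms pulse triggers a large transient burst and the rested network falls
back to silence.

A thin command-line wrapper over the same functions lives at
`inst/scripts/devnet`:

```sh
Rscript inst/scripts/devnet all --config cfg.json --out results/ --seed 7
```

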