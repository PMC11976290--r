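# seqphase

Does the theta phase at which a neuron fires encode *where* in a remembered
sequence its preferred item occurred — and does the *order* of those phases
follow the order of the items? `seqphase` implements the complete analysis
chain for this question on simultaneously recorded spikes and local field
potentials (LFPs), together with a firing-rate recurrent network model of
the same task, so that every claim can be exercised end-to-end on synthetic
sessions with known ground truth.

The package is aimed at computational neuroscientists working on
spike-phase coding and working memory. It provides:

- a **synthetic session generator**: 4-item sequences drawn from 8 stimuli
  (balanced across positions), jittered delays, theta-band LFP whose power
  rises during the delay over a 1/f background, and inhomogeneous-Poisson
  spike trains whose delay firing is von Mises phase-locked with
  position-dependent preferred phases;
- **Morlet-wavelet spectral analysis** (c = 7 cycles) with instantaneous
  phase, baseline z-scored power, delay spectra, and spike-phase
  assignment;
- **circular statistics**: Rayleigh test, von Mises maximum-likelihood
  fits, and the *circular variance explained*,

  V_j^w = 1 − |(1/N_j) Σ_k e^{iθ_k}|,  V^w = (1/N) Σ_j N_j V_j^w,
  V^a = 1 − |(1/N) Σ_k e^{iθ_k}|,      V_ex = 1 − V^w / V^a,

  with label-permutation nulls (p = (1 + #{null ≥ obs})/(1 + N_perm)),
  Hedges' g, bootstrap proportion CIs, Simes correction and rate-matched
  subsampling controls;
- **phase-order analysis**: anchoring per-position phases to their
  circular mean, counter-clockwise order extraction under rotation
  equivalence (1,2,3,4 ≡ 4,1,2,3; 24 permutations collapse to 6 classes,
  so a specific order has chance 1/6), and the **phase-reset model**
  predicting the order from oscillation frequency f and stimulus onset
  asynchrony (SOA): phase_k = φ0 + 2πf·k·SOA (mod 2π);
- **position decoding** from phase with an RBF one-vs-one SVM on
  (cos θ, sin θ) features, repeated stratified 85/15 splits, label-shuffle
  nulls, and pseudo-population assembly;
- a **Dale-constrained rate RNN** trained on the sequence match/non-match
  task by backpropagation through time, with an LFP proxy
  (Σ_ij |J_ij| φ(x_j)) and an oscillation regularizer
  reg_osc = −|(1/T) Σ_n normalized-LFP^n e^{−i2πf n Δt}| that steers the
  network's emergent rhythm to a target frequency.

## Worked example

```r
library(seqphase)

# a session with forward-ordered preferred phases planted (kappa = 2)
cfg <- default_session_config(n_units = 6L, n_trials = 96L, fs = 250,
                              ordering_mode = "forward", kappa_ps = 4,
                              selectivity_gain = 8, noise_amp = 0.5)
report <- run_empirical_pipeline(cfg, seed = 23, n_perm = 99L,
                                 decode = FALSE, grid = c(2.37, 2.8, 3.2))

sum(report$unit_summary$significant)  # units with V_ex above the null
#> [1] 6
report$order_categories               # planted forward order dominates
#> forward reverse   other
#>       6       0       0
chance_probabilities(4)$forward       # enumeration, not a constant
#> [1] 0.1666667

predict_reset_phases(1.5, 0.4)$phases * 180 / pi  # reset-model ramp
#> [1]   0 216  72 288   (canonical class 1-3-2-4)
```

All six units are detected by the permutation test and every recovered
phase order falls in the planted forward class, against a 1/6 chance
level per specific order.

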