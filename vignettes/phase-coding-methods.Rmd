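---
title: "Phase-of-firing analysis of sequence working memory: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-of-firing analysis of sequence working memory: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seqphase)
```

This vignette is the package's own account of its models and numerical
choices: what is being estimated, under which assumptions, which knobs
matter, and where genuinely open design decisions were settled.

## The scientific question

During maintenance of a 4-item sequence in working memory, single neurons
in the medial temporal lobe fire preferentially at particular phases of
the ongoing theta oscillation (2–8 Hz). The question the toolchain
addresses is twofold: (1) does the *preferred phase* of a neuron's delay
firing depend on the sequence position at which its preferred stimulus
(PS) was shown, and (2) if so, does the *circular order* of those phases
match the item order, as classic phase-coding models of sequence memory
predict? The package answers both on synthetic data with planted ground
truth, and in a trained recurrent network performing the analogous task.

## The synthetic session generator

The generator emulates the structure of the recordings; it is the study
condition, not a tuning knob.

- **Task**: 224 trials; 4 of 8 stimuli per trial, 200 ms each, onsets
  400 ms apart (SOA); delay uniform on 2.4–2.6 s (median 2.5 s, IQR
  0.1 s); probe matches the sample order on half the trials; in balanced
  mode every stimulus appears exactly equally often at every position
  (28 times per position at 224 trials). Trials are marked correct with
  probability 0.77, the typical observed performance level.
- **LFP**: 1/f background (spectral exponent 1) plus a theta cosine
  (default 2.8 Hz, amplitude 1) whose amplitude is multiplied by 3 inside
  the delay window, reproducing the delay theta-power increase. Each
  trial draws an independent uniform theta phase offset, recorded so the
  spike generator locks to the true phase.
- **Spikes**: inhomogeneous Poisson by thinning with rate
  r(t) = r_base · g_stim(t) · exp(κ cos(θ(t) − μ)) / I0(κ).
  The I0 normalization makes the cycle-averaged rate independent of κ, so
  phase coding is planted without a rate confound — matching the
  empirical picture of position effects in phase but not in delay rate.
  During encoding, the PS multiplies the rate by
  (1 + selectivity_gain · primacy_p) with primacy gains (1, 0.85, 0.70,
  0.55) over positions, a primacy gradient. During the delay of PS
  trials, κ and μ are those of the PS's position; trials without the PS
  use a reduced κ (default 0.5; the magnitude is a free parameter since
  no empirical value is available).
- **Orderings**: preferred phases per position follow the configured
  mode: `forward`/`reverse` place positions at ±40° steps (a ~120°
  span, consistent with the fraction-of-cycle ranges observed
  empirically), `arbitrary` draws them uniformly, and `reset_model`
  takes them from the closed-form phase-reset ramp below.

What the generator does **not** emulate: epileptic artifacts, electrode
drift, spike-sorting errors, non-sinusoidal theta, across-trial
non-stationarity. Passing tests on this generator therefore demonstrate
the correctness and calibration of the *analysis chain*, not robustness
to every pathology of real recordings.

All randomness flows from one session seed through named substreams
(trials, lfp, spikes), so each component is independently reproducible.
Time is measured in seconds from fixation onset; event windows are
half-open `[on, off)`.

## Spectral analysis

Complex Morlet wavelets with c = 7 cycles (Gaussian envelope
σ_t = c/(2πf), truncated at ±3.5 σ_t) on the analysis grid 1.5, 1.75,
2.03, 2.37, 2.8, 3.2, 3.7, 4.4, 5.1, 5.9, 6.9, 8 Hz. Edges are handled
by reflect padding plus a validity mask covering half a wavelet support
at each end; spikes falling into invalid margins are excluded and
counted. The **phase convention** is fixed package-wide: phase 0 at the
peak of a cosine at the wavelet's center frequency, increasing at 2πf
rad/s. Spike phases are looked up at the nearest sample (at 1 kHz and
≤ 8 Hz the discretization error is below 3°). Power is z-scored per
frequency against a 1,000 ms pre-stimulus baseline; delay spectra
average the last 1,500 ms before probe onset, and peak selection breaks
exact ties toward the lowest frequency.

## Circular variance explained

Per unit, per frequency, per trial k: θ_k is the circular mean of the
delay-window spike phases (trials with no delay spikes drop out; the
pipeline reports the excluded fraction). With condition j = sequence
position of the PS:

- V_j^w = 1 − |(1/N_j) Σ_{k∈j} e^{iθ_k}| (within-condition variance),
- V^w = (1/N) Σ_j N_j V_j^w (trial-count weighted pooling),
- V^a = 1 − |(1/N) Σ_k e^{iθ_k}| (across-condition variance),
- V_ex = 1 − V^w / V^a.

V_ex is 1 when phases are identical within conditions but differ across
them, and 0 in expectation when labels carry no information. It is
undefined when V^a = 0 (all phases identical); that degenerate case
raises an error rather than returning a value. The null distribution
shuffles condition labels across trials (default 1,999 draws; the
add-one convention p = (1 + #{null ≥ obs})/(1 + N) avoids p = 0; for
tiny samples the exact relabeling distribution is enumerated instead).
A unit counts as significant when p < 0.05 at **two or more**
frequencies of the grid. Proportions of significant units get
bootstrap percentile CIs (1,999 resamples); correct/incorrect contrasts
use Hedges' g between observed and shuffled V_ex; multiple comparisons
use the Simes procedure (stepwise-adjusted values via
Benjamini–Hochberg, which coincides with stepwise Simes, plus the
global Simes p).

Parametric alternatives (Watson–Williams circular ANOVA) are
deliberately not offered as substitutes: the permutation test makes no
von Mises assumption.

## Phase order and the reset model

Per-position mean phases are anchored by subtracting their circular
mean, sorted counter-clockwise, and the position indices are read off.
Orders are compared under rotation equivalence — (1,2,3,4) ≡ (4,1,2,3)
≡ (3,4,1,2) ≡ (2,3,4,1) — so 24 permutations collapse to 6 classes and
a specific order has chance probability 1/6, computed by enumeration
(and cross-checked by Monte-Carlo over uniform phase quadruples).
Because "forward", "reverse" and "other" must partition the outcome
space, their chance probabilities are 1/6, 1/6 and 4/6; the complements
"not forward" and "not reverse" (5/6 each) are also reported, since
chance values quoted for the three categories elsewhere (1/6, 1/6, 5/6)
cannot be a partition — both readings are computed here and neither is
asserted as the only sensible one. Exact phase ties are broken toward
the lower position index and flagged.

The **phase-reset model**: if each stimulus resets its preferred
neuron's firing phase to a constant while the reference oscillation
(frequency f) runs on, the relative phase of position k is
φ0 + 2πf·k·SOA (mod 2π). The predicted order depends only on the
fractional cycle advance f·SOA mod 1 (and φ0); an integral advance makes
all phases coincide (flagged degenerate). For empirical-style data φ0 is
the reference phase at first-stimulus onset, estimated per trial at a
mid-delay time point (clear of wavelet edge margins), projected back
along the oscillation and averaged circularly — the estimator is a
documented choice, since no canonical definition exists. Observed vs
predicted class match rates are tested by shuffling the
unit-to-(frequency, SOA) assignment.

## Decoding

An RBF-kernel SVM (libsvm's native one-vs-one multiclass scheme)
predicts position from per-trial mean phases embedded as
(cos θ, sin θ) — raw angles would break wrap-around continuity.
Repeated stratified 85/15 splits; the label-shuffle null (default 101
permutations; 199 for rate decoding) re-runs the full decoder per
shuffle. The RBF scale is fixed by the median-pairwise-distance
heuristic with unit cost, for determinism given the seed.
Pseudo-populations are assembled by sampling trials without replacement
within position classes and concatenating units' features; units
lacking enough trials in any class are dropped and reported.
Cross-validated accuracy under permuted labels sits slightly below the
nominal 25% chance (the usual pessimistic bias of cross-validation),
well within three standard errors.

## The recurrent network model

N = 200 rate units (default), τ = 0.1 s, obeying

x' : τ ∘ dx/dt = −x + J φ(x) + I u(t) + √(2τσ_ξ²) ξ,

simulated exactly with the Euler update x^{n+1} = (1−α)∘x^n +
α∘(Jφ(x^n) + I u^n) + √(2ασ_ξ²)∘ε, α_i = Δt/τ_i. The activation is a
rectified tanh (0 below 0, tanh above): rates are nonnegative —
required by the LFP proxy — and saturating, with the L2 rate penalty
keeping them off the saturation. Dale's law is enforced by sign
projection of J's columns after every optimizer step (80% excitatory;
magnitudes free, signs fixed, zero diagonal). The readout is linear;
both conventions found in the model's definition are implemented —
y = wᵀx (currents; the default, which also avoids zero gradients from
sub-threshold rectified units) and y = wᵀφ(x) (rates).

**Task**: four of eight input channels pulse for 0.2 s at the SOA;
after the delay the same four stimuli are presented again, in the same
order (match) or a shuffled order; the target is ±1 during a decision
period after the probe, and the loss is the decision-masked MSE
normalized by the mask mass, plus λ_FR·(1/NT)ΣΣφ² and λ_osc·reg_osc.
Evaluation sets use 224 unique sequences with exactly half match.

**Oscillation regularizer**: the LFP proxy is normalized to zero mean
and unit sinusoid scale, LFPbar = (LFP − μ)/(√2 σ), and
reg_osc = −|(1/T) Σ_n LFPbar^n e^{−i2πf_osc nΔt}|. A pure sinusoid at
f_osc spanning integer cycles gives exactly −0.5 (the minimum for real
signals up to edge effects), white noise ~0, and the value is
amplitude-invariant by construction. Published post-training values of
"power at the target frequency" around 0.68 are not attainable by this
modulus (bounded near 0.5 for any real normalized signal); the package
reports the modulus as defined and treats such larger figures as a
different power normalization.

**Training**: Adam (β = 0.9/0.999) with global-norm gradient clipping
on analytically derived BPTT gradients (verified against finite
differences in the test suite, including the regularizer paths through
the rates and through |J|). Two procedure choices matter and are the
package's own: trials come from a **fixed training set iterated in
shuffled minibatch epochs** with fresh intrinsic noise each pass — a
stream of never-repeated batches leaves the network at the zero-output
saddle (the match/non-match signal is not linearly present in the
initial dynamics, so per-batch gradients average out), whereas repeated
exposure to a large fixed set (default 1,536 trials) lets the
comparison rule form and generalize; and a **delay curriculum** —
the rule is learned at a 0.1 s delay first, then the delay is stretched
(0.4, 0.8 s, …) to the target, each stage advancing at 85% validation
accuracy. The learning rate decays by 0.7 every 60 epochs. Training
stops at ≥95% validation accuracy at the target delay, where the
decision rule is the sign of the time-averaged readout over the
decision period. Since no reference hyperparameters are available,
every optimizer and architecture constant is explicit config with the
defaults above. At N = 200 units, Δt = 0.05 s and a 1.5 s delay this
recipe reaches the 95% criterion in under 200 epochs (tens of minutes
on one CPU) with the delay-LFP spectral peak at the regularization
frequency; the test suite runs a smaller configuration (N = 100, a
~110-epoch budget) sized for a desk-scale suite run and reports
whatever that budget achieves.

**Model phase analysis**: stimulus-responsive units (paired Wilcoxon,
baseline vs stimulus period, p < 0.001) with their preferred stimulus
defined by the largest mean evoked rate; delay rates normalized per
unit, samples above the 50th percentile kept, and their phases with
respect to the reference oscillation (sine at the LFP spectral peak,
phase fixed at the onset of the last sample stimulus) averaged with
rate weights per trial. The resulting phase sample sets feed the same
V_ex and order machinery as spike data. Model inclusion follows the
LFP-peak-within-0.5 Hz rule (and the 0.2 Hz rule for order-vs-frequency
maps); the delay-vs-baseline power comparison uses the pre-first-
stimulus period as baseline.

## Numerical choices, degeneracies, tie-breaks

- Circular mean of an antipodal (zero-resultant) sample is undefined
  and flagged, never silently 0.
- κ estimation inverts A(κ) = R with Fisher's three-regime
  approximation; R = 1 caps κ at 10³ with a flag. The von Mises sampler
  is Best–Fisher. The Rayleigh p uses the standard series
  approximation, with Monte-Carlo fallback below n = 5.
- Permutation and bootstrap p-values use add-one conventions.
- Peak/argmax ties break toward the lowest frequency; phase-order ties
  toward the lower position index, with flags.
- Session bundles serialize to plain CSV/JSON with 17 significant
  digits, which reloads the doubles exactly.

## Known limitations

- The V_ex permutation test conditions on the realized trial counts;
  severely unbalanced conditions reduce its power.
- The reset-model φ0 estimator assumes a sustained oscillation between
  first stimulus and the measurement point; phase slips bias it.
- The RNN's match/non-match task is hard for gradient descent at
  desk-scale iteration budgets; training runs in the tests use scaled
  problem sizes and report convergence honestly rather than asserting
  it unconditionally.
- Cross-correlogram analyses of neuron pairs, regional anatomy, and
  gamma-nested-in-theta modelling are out of scope.
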