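---
title: "Comparing spectro-temporal encoding models with adaptation and gain control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing spectro-temporal encoding models with adaptation and gain control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audenc)
```

# The scientific question

A linear-nonlinear (LN) model — a spectro-temporal receptive field (STRF)
followed by a static output nonlinearity — is the workhorse description of
how auditory cortical neurons encode sound. It fails, however, on slower
*contextual* effects: responses depend on the recent stimulus history over
hundreds of milliseconds. Two mechanisms are commonly invoked to close that
gap: short-term synaptic plasticity (STP), which scales a neuron's inputs by
a history-dependent vesicle pool, and contrast-dependent gain control (GC),
which rescales the output nonlinearity by the recent spectro-temporal
contrast of the stimulus. `audenc` implements both extensions, their
combination, a staged estimation procedure, and — the analytical core — a
framework for asking whether two such model extensions are *equivalent*
(capture the same response component) or *complementary* (capture different
ones), together with a synthetic-data generator that makes the whole
pipeline testable end to end without any recorded data.

# The models

All architectures share a common front end: a spectrogram `s(f, t)` of
log-compressed level in `F = 18` channels with log-spaced center
frequencies (200 Hz – 20 kHz) and 10-ms bins. For waveform input,
`gammatone_spectrogram()` applies an order-2 gammatone filterbank with
ERB-scaled bandwidths, half-wave rectifies, smooths with a 4th-order 30-Hz
low-pass, samples at 100 Hz, and applies `log10(x + x0) - log10(x0)` with a
floor `x0` fixed at 1e-3 of full-scale RMS. The "order 2" follows the
filter-order reading of a second-order gammatone; the smoothing and
compression constants are concrete choices where only the operation itself
is conventionally specified.

**LN.** The STRF is rank-3 factored: an `F x 3` spectral weighting matrix
followed by a `3 x 15` bank of temporal filters (lags 0–140 ms),
`linear_drive()`. The output nonlinearity is the double exponential

$$y = b + a\, \exp(-\exp(-k\,(x - s)))$$

with baseline `b`, amplitude `a`, offset `s` and gain `k`
(`double_exponential()`). We use the increasing form (sigmoid in `x` for
`k > 0`); the amplitude is constrained non-negative. The final predicted
rate is rectified at 0 spikes/s.

**STP.** Each of the three spectrally weighted channels feeds a virtual
synapse with release fraction `u_i` (positive = depression, negative =
facilitation) and recovery time constant `tau_i` (seconds). The vesicle
availability starts at `d(0) = 1` and updates per 10-ms bin with release
proportional to `u * s(t-1)` and recovery `(1 - d) * dt / tau`, clamped to
`[0, 2]`. Two discretization choices matter and are fixed here: `dt` enters
only the recovery term (so `tau` is in seconds and comparable across bin
widths), and the release drive uses the *rectified* channel signal while
the output scales the *raw* signal. The latter resolves a genuine tension:
vesicle depletion is only meaningful for non-negative stimulation, but the
architecture must reduce to the LN model *bit-exactly* at `u = 0` — which
it does under this convention, because `d` stays identically 1.

**GC.** The per-channel contrast `C_f(t)` is the coefficient of variation
(SD/mean) of the log-level in a 70-ms window ending 20 ms before the
current bin (`compute_contrast()`); `K(t)` sums it across channels
(`contrast_index()`). `K` is rescaled so that its 95th percentile over the
estimation stimuli is 1, with the normalizer stored in the model
(`calibrate_contrast_norm()`); this keeps the endpoint parameters
interpretable as "parameter value at high contrast". Each nonlinearity
parameter is then linearly interpolated,
`theta_i(t) = theta_i0 + (theta_i1 - theta_i0) K(t)`. Because the linear
map extrapolates beyond the calibrated range when validation stimuli exceed
the estimation set's contrast, the modulated amplitude is clamped at zero
there; inside `K in [0, 1]` the map is exactly linear and the
`theta1 = theta0` restriction reproduces the LN prediction bit-exactly.

**GC+STP** composes both stages around the shared STRF. The nesting
identities (STP at `u = 0`, GC at `theta1 = theta0`, and both at once,
each equal to the LN prediction to the bit) are enforced by running all
architectures through the same compiled forward pass, and are tested.

# Estimation

Models are fit by bounded L-BFGS-B on the mean-squared error between the
prediction and the repetition-averaged response, with analytic
reverse-mode gradients (verified in the test suite against central finite
differences). Estimation is staged, coarse to fine:

1. the linear STRF alone against the response (coarse stop, relative loss
   change `1e-4`);
2. the output nonlinearity (static) with the STRF fixed;
3. all LN parameters jointly (fine stop, `1e-7`);
4. *(STP architectures)* re-factorization of the LN effective filter by a
   seeded rank-3 non-negative matrix factorization, then the nonlinearity
   and STP parameters with the factors fixed, then all LN+STP parameters
   jointly;
5. *(GC architectures)* the contrast-modulation endpoints (plus STP
   parameters where present) with the LN stage fixed, then everything
   jointly.

Stages are warm-started, a stage is never allowed to end with a higher
loss than it started, and the whole schedule can be restarted from
multiple seeded initializations with the best final loss retained
(`n_restarts`). Two less-standard steps deserve justification:

* **Non-negative re-factorization.** The rank-3 STRF is only identified up
  to an invertible mixing of its factors. For the LN model this is
  harmless; for STP it is not, because each factor column owns a synapse.
  Fitting the STP stages from the raw linear-stage factors routinely lands
  in sign-mixed local minima with spurious facilitation. Re-factorizing the
  positive part of the fitted LN filter into non-negative spectral "parts"
  pins the synapses to non-negative input bands — the regime in which
  vesicle depletion is defined — and empirically moves parameter recovery
  from hopeless to reliable on identifiable ground truths.
* **Column renormalization.** The transformation
  `(W_j, u_j, H_j) -> (c W_j, u_j / c, H_j / c)` leaves every prediction
  unchanged, so `u` has no absolute scale until one is imposed. Spectral
  columns are renormalized to unit norm (with exact compensation of `u`
  and the temporal filters) at stage boundaries; reported `u` values are
  in units of log-level drive through a unit-norm spectral profile.
* **LN fallback.** Because the re-factorization step can move the search
  off the LN optimum, a nested architecture that ends its schedule with a
  higher estimation loss than its own LN stage is returned *as* that LN
  solution (exactly embedded with `u = 0`, `theta1 = theta0`). This keeps
  the nested models' estimation loss monotone in model complexity, which
  the comparison logic relies on.

Initialization: spectral weights from channel-wise stimulus–response
correlations plus seeded jitter; temporal filters from a delta at lag 1
scaled to the response; nonlinearity from response percentiles with the
gain scaled to the drive SD (a fixed unit gain is badly conditioned when
the drive SD is far from 1); `u = 0.05`, `tau = 0.1 s`;
`theta1 = theta0`. Bounds: `|u| <= 1`, `tau in [1 ms, 1 s]`, `a >= 0`.

## Scoring

Prediction accuracy is the Pearson correlation between the prediction and
the repetition-averaged validation response, adjusted for finite sampling:
the raw correlation is divided by the square root of the split-half
reliability of the validation response stepped up by the Spearman–Brown
relation (odd/even repetition split). This split-half contract is a
standard, testable substitute for the finite-sampling correction that the
field's literature cites in several variants; with noise-free repetitions
the ceiling is exactly 1 and the adjustment vanishes.

# The equivalence framework

For each neuron, equivalence of the STP and GC models is the first-order
partial correlation between their validation predictions, controlling for
the LN prediction (`equivalence_partial_correlation()`): 1 when both
models deviate from the LN prediction identically, 0 when their deviations
are unrelated. Because finite, noisy estimation data bias this score
downward, an upper bound is computed per model by splitting the estimation
stimuli into two balanced halves (alternating assignment after a seeded
shuffle), fitting the same architecture to both halves, and computing the
partial correlation between the two half-fits' validation predictions
(`within_model_ceiling()`); the reference LN model is always the fit on
the full estimation set, so the conditioning variable is constant across
comparisons. The half-data ceiling `W_half` is corrected by the ratio of
between-model equivalence on full versus opposite-half data,
`W_plus = (B_full / B_half) W_half`, with `B_half` averaged over both
opposite-half pairings. On pure-mechanism synthetic neurons the `B` terms
sit near zero and the ratio is meaningless, so the pipeline falls back to
the uncorrected `W_half` whenever the two `B` terms disagree in sign or
`|B_half| <= 0.05`; the flag is reported alongside.

Two significance tests complete the per-neuron record:
a permutation test for responsiveness (null built from circular shifts of
the prediction by at least 500 ms, preserving autocorrelation), and a
delete-one-block jackknife t test over 20 contiguous validation segments
for the improvement of the combined model over LN. "Auditory-responsive"
means all fitted architectures beat the permutation null at `alpha`;
"improved" additionally requires the jackknife test.

The response reliability metric is the signal-power fraction: per
repetition, total power is `<y_j, y_j>` and signal power the mean of
`<y_j, y_k>` over `k != j`; per-stimulus reliability averages the ratio
over repetitions and the overall value averages over stimuli. The
cross-term average uses `1/(m-1)` over the `m - 1` partners — the unbiased
convention — so that a response with equal signal and noise power scores
0.5 exactly in expectation, which the acceptance suite verifies by
simulation.

# The synthetic-data generator

No recordings ship with this package; every downstream stage is exercised
on synthetic model neurons.

**Stimuli.** Spectrograms are built directly in log-level space as sparse
spectro-temporal ridges (sharp 10–30-ms attacks, 80–350-ms decays — the
temporal asymmetry of natural sound events) over a slowly
amplitude-modulated smoothed-noise floor, with 200–450-ms quiet gaps
between events and occasional "texture" epochs in which the ridge field is
replaced by dense flat noise at a comparable mean level. The gaps let
adaptation and gain state recover between events, and the texture epochs
make contrast vary at roughly fixed level — without them a rank-3 linear
filter mimics both mechanisms alarmingly well, because contrast and level
are then almost collinear. The `smooth_contrast` regime draws per-stimulus
contrast from a continuous range; the `bimodal_clean_noisy` regime pairs
each clean sample with a variant whose linear power is mixed with a flat
broadband floor equal to the clean sample's mean power (a 0 dB SNR
equivalent applied in spectrogram space, standing in for additive acoustic
white noise whose exact peak-to-peak convention is not reproducible from
text alone). Clean and noisy samples then form the two labeled contrast
clusters that characterize that regime.

**Neurons.** `random_model()` draws ground truths per architecture:
non-negative unit-norm spectral bumps (suppression carried by the temporal
filters), gamma-shaped temporal kernels, and an output nonlinearity
calibrated so the sigmoid operates in the dynamic range of the drive the
synapses actually transmit (the post-adaptation drive for STP-bearing
architectures — calibrating on the unadapted drive silently turns a
combined-mechanism neuron into a GC-only neuron because depression pushes
the drive into the sigmoid's floor). STP neurons are strongly adapting
(`u ~ U(0.35, 0.55)`, `tau ~ U(0.08, 0.15) s`): the regime in which
plasticity shapes responses beyond what a linear filter can mimic, as in
the strongly improved cells that motivate these models. GC neurons halve
to quarter their gain and amplitude from low to high contrast with a
baseline rise. Trial noise is Gaussian with SD expressed relative to each
neuron's prediction SD (two levels cycled across a population by default),
or Poisson on spike counts.

**Defaults and scale.** The default estimation/validation design holds 90%
of stimuli at 3 repetitions and 10% at 24 repetitions, mirroring the
low-repetition-estimation / high-repetition-validation logic of chronic
natural-sound experiments, and the default population is 60 neurons in
equal LN/STP/GC thirds with two noise levels. The shipped tests and the
worked examples run scaled-down versions (10–20 stimuli of 1.5–3 s,
populations of 10–16 neurons, 12–18 channels, a few hundred optimizer
iterations per stage) chosen once so the full suite completes in minutes
on a single core; the methods themselves are size-agnostic.

# What the synthetic experiments do and do not show

Passing tests on this generator demonstrate that the pipeline is
*internally correct*: the architectures nest exactly, the estimator
recovers models from their own simulations, the equivalence score and its
ceilings behave as designed, and the qualitative population patterns
(single mechanisms beat LN, the combination beats both; between-model
equivalence far below within-model ceilings; gain control's relative
contribution growing in the clean/noisy regime) emerge for the stated
reasons. They do not show that real cortical neurons obey these models:
the generator's neurons are pure or additive mixtures of exactly the
mechanisms being fitted, its noise is independent across bins and
repetitions, and its stimuli — however naturalistic their contrast
statistics — are not sounds. Conclusions about biology require recorded
data; this package provides the calibrated instrument.

## Numerical and design notes

* The printed form of the double-exponential nonlinearity is typographically
  ambiguous in parts of the literature; the increasing
  `b + a exp(-exp(-k (x - s)))` is adopted throughout and stated wherever
  the function appears.
* Parameter recovery for `(u, tau)` is only meaningful for identifiable
  ground truths. The acceptance check uses spectrally separated synapses;
  with heavily overlapping spectral profiles the per-synapse decomposition
  is close to unidentifiable at desk scale even though predictions are
  recovered almost perfectly, and fitted `u` values can then differ
  substantially from the generating ones. This mirrors the general caution
  that mechanistic parameters from nonconvex fits deserve skepticism.
* The recovery experiment's class-by-architecture table
  (`model_recovery_experiment()`) uses noise-free simulations so that any
  cross-architecture difference reflects representational capacity, not
  noise; its margins at desk scale (20–30 stimuli) are a few hundredths of
  a correlation point for GC, versus several points for STP.
* The permutation null shifts the *prediction* circularly; whether one
  shifts predictions or responses is immaterial to the correlation null,
  and shifting preserves both series' autocorrelations.
* Degenerate inputs are flagged rather than propagated: constant
  predictions give permutation p = 1, zero-variance predictions score 0,
  a model prediction numerically identical to the LN reference yields a
  flagged missing equivalence, all-zero repetitions are skipped in the
  reliability ratio, and `B_half = 0` leaves the ceiling correction
  undefined.

# A worked example

```{r example, eval = FALSE}
library(audenc)

# a small synthetic study: stimuli, one adapting neuron, four fits
bank <- generate_stimulus_bank("smooth_contrast", n_stimuli = 12,
                               duration_s = 2, n_channels = 12, seed = 1)
truth <- random_model("STP", bank, seed = 2)
neuron <- ground_truth_neuron(truth, noise = "gaussian", noise_sd = 3,
                              seed = 3)
resp <- simulate_neuron(neuron, bank)

est <- fit_data(bank, resp, "est")
fits <- lapply(setNames(nm = c("LN", "STP", "GC", "GC+STP")),
               fit_model, est_data = est, config = fit_config(seed = 4))
sapply(fits, function(f) score_model(f, bank, resp)$r_adj)

# population-level replication
report <- run_experiment(experiment_config(n_neurons = 12, seed = 1))
glance(report)
autoplot(report)
```
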