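---
title: "EEG identity authentication with windowed discriminants and genetic channel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG identity authentication with windowed discriminants and genetic channel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The authentication problem

`rsvpauth` implements an EEG biometric: a person is authenticated by the brain
response their own face evokes. In a rapid serial visual presentation (RSVP)
trial, ten face images flash for 300 ms each — one of them the registered
user's own face. The self-face elicits event-related potentials (ERPs) —
occipito-temporal N170 and N250, parieto-central P3a and P3b — whose
amplitudes and latencies differ from the response to another person's face;
the P3 complex carries most of that contrast. A classifier trained on a
user's registration EEG can therefore decide, from roughly two trials (6 s),
whether the person watching the sequence is the account owner or an imposter
— including an informed ("non-blind") imposter who knows which face to look
for but whose P3 to a foreign face is smaller and later.

The package covers the full pipeline: a seeded synthetic recording generator,
preprocessing, the hierarchical discriminant component analysis (HDCA)
classifier, genetic-algorithm (GA) channel selection, and the biometric
evaluation protocol (ACC / FAR / FRR, stratified cross-validation, retest
permanence). A thin command-line front end (`inst/cli/rsvpauth.R`) exposes
each stage file-to-file.

## The synthetic generator

Real registration EEG is not bundled; every analysis here runs on a simulator
whose defaults encode the acquisition protocol the framework targets: 16
channels (Fz, Cz, P3, Pz, P4, Po7, Oz, Po8, C3, C4, F3, F4, Af7, Af8, Cp5,
Cp6) at 2400 Hz, 20 blocks of 10 trials, 10 images per trial at 300 ms
(3 s/trial, contiguous), one self-face target per trial at a random serial
position — 200 target events per registration run.

ERP components are Gaussian bumps in time, scaled by a fixed per-channel
topography:

* N170: 170 ms, SD 20 ms, −5 µV (self) / −4.5 µV (non-self), occipito-temporal;
* N250: 250 ms, SD 30 ms, −4 / −3.2 µV, occipito-temporal;
* P3a: 300 ms, SD 50 ms, +7 / +3.5 µV, parieto-central, non-self delayed 30 ms;
* P3b: 450 ms, SD 80 ms, +8 / +4 µV, parietal (largest on P3, Pz, P4, Po8),
  non-self delayed 30 ms.

The self/non-self gap is deliberately concentrated on the P3 complex at
parietal channels, matching where face-evoked self/other differences are
reported to be largest. A `class_mix` between 0 and 1 interpolates amplitudes
and latencies, modelling the familiar (non-blind) imposter
(`simulate_subject_triplet()` uses 0.35 by default); the size of that
familiarity effect is a simulator knob, not an empirical claim.

Background activity is 1/f ("pink") noise, independent per channel, plus a
common-mode term shared by all channels (removed by the average reference).
The noise scale was fixed once against the design condition that single-trial
SNR is low while two-trial averages classify well: at `noise_rms = 5` µV with
1.5 µV common mode, full-protocol pooled cross-validation reaches about 90%
on pair-averaged trials versus the mid-80s on single trials. What the
simulator does **not** model: eye blinks and muscle artifacts, volume
conduction from a head model, overlapping responses from the nine non-target
images, inter-subject topography variability, or electrode drift. Passing
tests therefore demonstrate correctness of the algorithms under a controlled
ERP model, not performance on real recordings.

```{r}
library(rsvpauth)
cfg <- sim_config(seed = 1)              # the full registration protocol
tri <- simulate_subject_triplet(cfg)     # user, blind + non-blind imposter
```

## Preprocessing

`preprocess()` applies a fixed stage order; each stage is exported on its own
and logs its parameters into the output metadata.

1. **Re-referencing** — common average by default. A true
   reference-at-infinity operator needs a head-model lead field the package
   does not ship; any precomputed square matrix can be supplied instead and
   is applied as a drop-in linear transform.
2. **Low-pass** — Chebyshev type-I, passband edge 40 Hz, stopband edge 49 Hz,
   ≥ 40 dB stopband attenuation, applied forward–backward (zero phase). The
   single-pass ripple budget is 0.5 dB so the two-pass magnitude stays within
   1 dB. `signal::cheb1ord` picks the minimum order (10 at 2400 Hz), which is
   bumped to the next odd value (11) so the DC gain is exactly 1. The filter
   is realised as a cascade of analytically derived second-order sections:
   at this narrow normalized cutoff the expanded direct-form polynomial is
   numerically unstable (rounded poles leave the unit circle), while biquads
   keep every pole at its designed radius. Each biquad starts at its
   steady state for the first padded sample, and the signal is extended by
   odd reflection, which suppresses start-up transients (a constant passes
   through unchanged to machine precision).
3. **Downsampling** — mean of every 4 consecutive samples, 2400 → 600 Hz;
   event indices map by integer division (sub-sample jitter of at most one
   output sample is accepted).
4. **Epoching** — −200 to +1000 ms around each target onset, half-open
   windows; 720 samples at 600 Hz. Events whose window crosses a recording
   edge are dropped with a warning.
5. **Baseline correction** — subtract the −200–0 ms mean per trial and
   channel (idempotent).
6. **Crop** — classification uses the 0–1000 ms segment: 600 samples.
7. **Pair averaging** — consecutive same-class trials are averaged without
   overlap (200 → 100 trials), halving i.i.d. noise variance; an odd trailing
   trial is dropped. Acquisition order is used; a seeded shuffled pairing
   exists for robustness checks.

A peak-to-peak artifact rejection threshold is available but off by default:
the protocol's artifact criterion is unspecified, and the simulator produces
no artifacts.

## The HDCA classifier

HDCA is a two-level linear discriminant exploiting the fact that the scalp
distribution of discriminative activity changes over the epoch:

1. The 0–1000 ms epoch is tiled into N = 10 windows of T = 100 ms. Within
   window *n*, the per-channel means x̄ᵢ,ₙ are compressed to one score
   yₙ = Σᵢ wₙ,ᵢ x̄ᵢ,ₙ. The weights are Fisher linear discriminants,
   w ∝ (S_w + λI)⁻¹(μ₁ − μ₀), computed per window with Ledoit–Wolf shrinkage
   of the pooled within-class covariance toward the scaled identity
   (λ = "auto"; any fixed intensity in [0, 1] may be forced). Weights are
   unit-norm with sign fixed so self-class projections are higher.
2. The window scores are fused into one interest score
   Y_S = logistic(Σₖ vₖ yₖ + b) by ridge-penalised logistic regression
   (penalty 10⁻², on the weights only). The light L2 keeps the fit finite on
   linearly separable folds; it is small enough that the fit matches the
   unpenalised solution wherever that exists. The IRLS solver is internal —
   the penalised path of `glmnet` refuses single-column designs, which the
   one-window reduction (below) requires.

A trial is accepted when Y_S ≥ 0.5 on the calibrated probability scale; a
login pools `trials_per_login = 2` consecutive trials (6 s) and accepts on
the mean score, which also breaks ties between disagreeing trial decisions.
An equal-error-rate threshold mode (`threshold = "eer"`) supports FAR/FRR
trade-off studies.

Two structural reductions anchor the implementation: with a single window
spanning the epoch, HDCA orders trials exactly as a plain FLD on whole-epoch
channel means; and multiplying all inputs by a positive constant leaves
held-out decisions unchanged (the FLD direction is scale-free and the
logistic refit absorbs the scale).

On the interpretation of the window features: the per-window compression is
stated per time point, and the window score is the time-average of the
compressed signal; since the spatial weights are constant within a window,
averaging channels first and projecting once is the same operation, so the
FLD is fit directly on window-mean features (one weight vector per window,
60 samples averaged at 600 Hz). A raw-time-point variant is deliberately not
implemented.

## Genetic channel selection (GA-HDCA)

Channel subsets are encoded as 16-bit masks. The GA uses population 100,
single-point crossover with probability 0.85, per-individual single-bit
mutation with probability 0.1, size-2 tournament selection, one elite copied
unchanged, and stops at 50 generations or after 10 without improvement.
Fitness is 5-fold cross-validated HDCA accuracy restricted to the masked
channels. Three details matter for search quality:

* **Frozen folds** — the stratified fold assignment is fixed per run, so
  fitness is a deterministic function of the mask; otherwise CV resampling
  noise swamps selection pressure.
* **Caching** — fitness is cached by mask; with frozen folds repeated masks
  cost nothing, and fitness evaluation may be parallelised with results
  identical to sequential execution (a single panmictic population, not an
  island model).
* **Ties to sparsity** — equal fitness resolves toward fewer channels, in
  tournaments and in the reported optimum, favouring practical montages.

All-zero masks (at initialisation or after mutation) are repaired by setting
one random bit rather than penalised, keeping fitness total. For problems of
at most ~8 channels, `exhaustive_mask_search()` provides the brute-force
optimum over all non-empty masks; the test suite requires the GA to match it
on a 6-channel problem across seeds.

`ga_hdca()` runs the search and refits HDCA on all trials restricted to the
winning mask. Channel selection is treated as part of model identification,
performed once on the registration data; the reported cross-validated
accuracy reuses the same frozen folds, so the HDCA and GA-HDCA numbers
differ only in the channel mask.

## Evaluation protocol

Per user, the positive class is the user's 100 pair-averaged registration
trials and the negative class the 200 pair-averaged trials of the two matched
imposters. `auth_metrics()` reports

* ACC = 100 · (1 − (FA + FR) / n_test),
* FAR = 100 · FA / n_imposter,
* FRR = 100 · FR / n_user,

asserting these identities on every computation; a missing class flags the
undefined rate as `NA` rather than failing (the usual user-only retest yields
only ACC and FRR). `crossval()` uses stratified seeded folds — every trial
tested exactly once, both classes in every fold — and pools held-out
decisions into a single confusion table (per-user pooling, rather than
averaging per-fold rates). `permanence_test()` applies a trained model to a
later session without refitting. Simulating a retest with the P3 class gap
attenuated shows the expected graceful degradation, and the GA-optimised
montage remains at least comparable to the full montage out of session.

## Numerical and testing choices

* Sample indexing is 1-based in memory (R convention) and 0-based half-open
  in every on-disk format; times are ms relative to stimulus onset.
* The native container is raw little-endian float64 plus a JSON sidecar
  (sampling rate, channel names, events, provenance) — bit-identical round
  trips, no quantisation mid-pipeline. EDF export (16-bit, physical µV) is
  provided for interchange; its quantisation step is the physical range
  divided by 65535.
* Degenerate inputs fail loudly: single-class training sets, all-zero
  feature matrices, empty channel masks, epochs crossing recording edges.
  Duplicated (collinear) channels are handled by shrinkage, not errors.
* Test problem sizes are chosen so the full suite runs in minutes: most
  statistical checks use 600 Hz generation with unit downsampling (skipping
  the 2400 Hz filtering stage, which is covered separately), 3–10 blocks
  instead of 20, and GA populations of 40 where the search space is small.
  The design-arithmetic checks and the acceptance script run the full
  2400 Hz, 20-block protocol.
* The fusion-weight recovery check runs under temporally white noise: under
  1/f noise, windows without injected effect legitimately earn large
  weights as noise references (inter-window noise correlation), which is a
  property of the optimal fusion solution rather than a defect, and it
  obscures which window carries the class signal.

## Known limitations

* Average reference only approximates a neutral reference; a genuine
  reference-standardisation operator must be supplied externally.
* The GA wraps a single objective (accuracy); no parsimony pressure beyond
  tie-breaking, no adaptive rates, no multi-objective trade-off.
* Simulated permanence only probes amplitude attenuation of the P3 gap;
  real cross-session drift (impedance, cap placement, vigilance) is richer.
* Headline numbers from real 45-subject recordings are not reproducible
  here; the synthetic benchmarks establish correctness and qualitative
  behaviour (channel optimisation helps; accuracy survives moderate drift),
  not field performance.
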