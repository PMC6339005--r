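# rsvpauth

EEG-based identity authentication from face rapid serial visual presentation
(RSVP), for researchers building or benchmarking ERP biometrics. A registered
user watches a 3-s stream of ten face images (300 ms each), one of which is
their own; the self-face evokes event-related potentials — most prominently
the parietal P3a/P3b complex — that differ in amplitude and latency from the
response to anyone else's face, including an informed imposter. `rsvpauth`
implements the full decision pipeline on top of a seeded synthetic ERP
generator, so every stage is testable without access to recordings.

## Method

**HDCA (hierarchical discriminant component analysis).** The 0–1000 ms
post-stimulus epoch (600 samples at 600 Hz) is tiled into N = 10 windows of
T = 100 ms. In window *n* the channels are compressed to a single score with
Fisher-discriminant spatial weights computed on window-mean features,

> yₙ = Σᵢ wₙ,ᵢ x̄ᵢ,ₙ,  w ∝ (S_w + λI)⁻¹(μ₁ − μ₀),

with Ledoit–Wolf shrinkage λ of the pooled within-class covariance. The
window scores are fused by ridge-penalised logistic regression into one
interest score per trial,

> Y_S = logistic(Σₖ vₖ yₖ + b),

and a login pools two consecutive trials (6 s), accepting when the mean
score reaches the threshold (0.5, or an equal-error-rate cutoff).

**GA-HDCA.** A genetic algorithm searches over 16-bit channel masks
(population 100, single-point crossover 0.85, single-bit mutation 0.1,
tournament selection, elitism, stall-based stopping), with 5-fold
cross-validated HDCA accuracy — frozen folds, cached by mask — as fitness.
The selected subject-specific montage typically concentrates on parietal
channels and improves accuracy, false acceptance and false rejection rates
over the full montage.

**Evaluation.** `auth_metrics()` reports ACC, FAR and FRR from pooled
held-out decisions; `crossval()` runs seeded stratified k-fold CV;
`permanence_test()` applies a trained model to a later session without
refitting.

## Worked example

```r
library(rsvpauth)

# a registered user and two imposters watching the same 20-block sequence
# (600 Hz generation; the default 2400 Hz protocol adds a downsampling step)
cfg  <- sim_config(n_blocks = 20, fs = 600, seed = 42)
tri  <- simulate_subject_triplet(cfg)
eps  <- lapply(tri, preprocess, ds_factor = 1)
pool <- bind_epochs(eps$user, eps$imposter_blind, eps$imposter_nonblind)
pool
#> <eeg_epochs> 300 trials x 16 channels x 600 samples @ 600 Hz, t = [0, 1000) ms
#>   labels: 100 self / 200 non-self

crossval(pool, folds = 5, seed = 42)
#> Authentication metrics (100 user + 200 imposter test trials)
#>   ACC 87.67%   FAR 7.00%   FRR 23.00%

model   <- hdca(pool)                         # full-montage classifier
login_u <- authenticate(model, eps$user, trials_per_login = 2)
login_i <- authenticate(model, eps$imposter_blind, trials_per_login = 2)
sum(login_u$accept); sum(login_i$accept)
#> [1] 46        # 46 of the user's 50 two-trial logins accepted
#> [1] 0         # none of the blind imposter's 50 logins accepted
```

The pooled trials are pair-averaged epochs: 200 registration trials per
subject become 100, and the 100-vs-200 composition mirrors the
one-user-versus-two-imposters test design. `ga_hdca(pool, config =
ga_config(seed = 42))` runs the channel search and returns a refitted model
whose mask, fitness trace and cross-validated metrics can be compared with
the full montage via `compare_methods()`.

A command-line front end wrapping the same functions ships in
`inst/cli/rsvpauth.R` (`simulate`, `preprocess`, `train`, `select-channels`,
`authenticate`, `evaluate`, `permanence`), reading YAML run configurations
and the package's native array container or EDF.

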