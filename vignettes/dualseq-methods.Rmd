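---
title: "Decoding cognitive-operation sequences from dual-task EEG: models and methods"
author: "dualseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding cognitive-operation sequences from dual-task EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In the psychological refractory period (PRP) paradigm a participant performs
two speeded tasks whose stimuli are separated by a stimulus-onset asynchrony
(SOA) — here 300 ms (Short) or 1200 ms (Long). Behavioral averages hide how
the two tasks' latent processing stages actually interleave on individual
trials. `dualseq` implements a trial-level analysis chain that

1. decomposes multichannel EEG epochs into probabilistic onsets of three
   latent *cognitive operations* per task — Encoding (E), Central (C),
   Response (R) — using an EM algorithm over brief multivariate events with
   gamma-distributed stage durations;
2. trains a causal spatiotemporal sequence labeler on those probabilistic
   onsets (soft labels) with a Kullback–Leibler loss, using only Long-SOA
   trials, where the two tasks do not overlap;
3. applies the trained model to all trials — including the overlapping
   Short-SOA condition it never saw — and compares operation *embeddings*
   across conditions;
4. converts the model's per-timestep onset probabilities into a per-trial
   posterior over the six possible cross-task operation sequences
   (labels A–F); and
5. propagates that posterior uncertainty into mixed-effects models of
   reaction time and accuracy by multiple imputation with Rubin's-rules
   pooling and Holm-adjusted pairwise contrasts.

A synthetic-data module generates dual-task EEG with known ground truth
(onsets, sequence labels, behavioral effects), so that every stage of the
chain is testable end to end without any external data.

# The sequence taxonomy

Each task's operations are strictly ordered (E before C before R). Of the
`choose(6, 3) = 20` order-preserving interleavings of (E1, C1, R1) and
(E2, C2, R2), exactly six begin with E1 and end with R2:

| Label | Ordering |
|-------|----------------------------|
| A | E1 C1 R1 E2 C2 R2 (serial) |
| B | E1 C1 E2 R1 C2 R2 |
| C | E1 E2 C1 R1 C2 R2 |
| D | E1 C1 E2 C2 R1 R2 |
| E | E1 E2 C1 C2 R1 R2 |
| F | E1 E2 C2 C1 R1 R2 |

Anything else — including exact onset ties, which the classifier treats
conservatively — is INVALID. `enumerate_valid_sequences()` verifies this
taxonomy by brute force.

# The synthetic generator: what it emulates

`sim_config()` fixes the study conditions. Each operation onset is marked by
a 50 ms half-sine event with a fixed unit-norm channel topography; the six
topographies are mutually distinguishable (pairwise |cosine| at most 0.3).
Within a task, onsets are separated by gamma-distributed stage durations
with shape fixed at 2 (scale = mean/2), stage means 150 ms. In the Long
condition the whole Task 1 chain completes before the Task 2 stimulus
(enforced by resampling the rare violating trial). In the Short condition a
sequence label is drawn from the participant's *strategy mixture* and the
six onsets are laid out as cumulative gamma gaps (mean 90 ms) in the order
the label dictates, so the planted label holds by construction; the Task 2
Encoding onset is floored at SOA plus a short sensory delay (gamma,
mean 60 ms). Default strategy mixtures are heterogeneous — each participant
prefers one label with probability 0.5 — emulating the marked individual
differences in strategy use seen in dual-task data.

RT is the final Response onset plus a gamma motor delay (mean 50 ms) plus a
per-sequence shift (defaults 0, 15, 25, 50, 35, 45 ms for A–F);
correctness is Bernoulli with a per-sequence logit shift (overlapping
sequences slower but more accurate). The motor delay is deliberately short:
the Response event is taken to immediately precede the recorded keypress,
the same assumption that makes a 50 ms post-RT analysis window sufficient
for estimating it.

**Signal-to-noise calibration.** Additive Gaussian noise has standard
deviation 0.6 against events of unit peak amplitude spread over 32
channels: per-channel peak SNR ≈ 0.18, and the realized matched-filter
z-score of one event in one trial is ≈ 3.4 on the standardized match
series. This places the simulation in the regime where single-trial events
are statistically detectable but individually uncertain — the regime the
method is designed for. What the generator does *not* emulate: realistic
ERP morphology and volume conduction, ocular/muscle artifacts, 1/f
background spectra (an optional AR(1) noise flag provides temporal
coloring), or electrode geometry. Passing recovery tests on this generator
therefore demonstrates the statistical machinery under its stated
assumptions, not robustness to real-world artifacts.

# Event decomposition

`prepare_for_decomposition()` average-references each epoch, band-pass
filters 1–50 Hz (zero-phase forward–backward Butterworth, so no latency
shift biases the onset labels), drops trials with RT < 0.2 s, and crops
each trial to [stimulus, RT + 50 ms] (50 ms → 13 samples at 250 Hz,
rounded up). The spatial basis is the top 10 eigenvectors of the channel
covariance averaged over training-split trials only; projected component
series are standardized by their training RMS.

Each event is assumed to be a unit-energy half-sine of width W;
`pattern_match()` cross-correlates the components with the template. The
EM model (`em_fit()`): K ordered latent onsets per trial, separated by
K + 1 stage durations following discretized gamma(shape 2) distributions
(CDF differences on sample bins, renormalized over the trial support), and
emission log-evidence `sum_d(m[k,d] y_d(t) - m[k,d]^2/2)` — the Gaussian
likelihood-ratio score of the match series. The E-step is an exact
forward–backward dynamic program over (event index × time), implemented
with FFT convolutions; the M-step re-estimates magnitudes by
posterior-weighted averages and stage scales by moment matching
(θ = E[duration]/2). Iteration stops when the relative likelihood gain
falls below 1e-4 (at most 200 iterations).

Numerical and identifiability choices, each adopted after observing the
corresponding failure mode of the plain likelihood formulation:

* **Match standardization** (`match_series()`): matched-filtering
  band-limited data inflates the output variance ≈ 1.6× above the
  component variance; the emission model assumes unit noise variance, so
  the match series is standardized to unit RMS. Without this, emission
  evidence is systematically over-weighted and the event count inflates.
* **Minimum inter-onset gap** of one template width: the match series has
  a ridge spanning two template widths around each true event, so without
  a gap constraint EM happily places two "events" one sample apart on the
  same pattern. Events are changes in the multivariate signal of width W;
  two onsets closer than W would describe the same change twice.
* **Moment-matched duration update**: under truncation and the gap
  constraint this is a generalized-EM step; the likelihood is
  non-decreasing up to the convergence tolerance (measured terminal dips
  ~1e-4 relative), and iteration stops at the first non-improving step.

`cumulative_fit()` determines the event count: fit one event, then add one
at a time, initializing known events from the previous solution and the
new event inside the final stage, with a fresh-restart fit run alongside
(EM is local; the warm start alone can trap the new event in the wrong
stage). A larger model is accepted only if (i) the log-likelihood gain
exceeds 0.5 × (D + 1) × log(total samples) — the BIC penalty for the new
event's D magnitudes and one stage scale; a bare "likelihood improves"
rule always over-segments, because maximum likelihood never decreases with
K — (ii) every event's magnitude norm clears a floor (default 0.05), and
(iii) no two events carry near-collinear magnitude patterns
(|cosine| < 0.8): a duplicate pattern indicates the same underlying event
fitted twice, not a distinct operation.

`tune_event_width()` runs the cumulative fit over widths 20–60 ms (5 ms
steps) and selects the most stable width: the center of the longest run of
consecutive widths yielding the same K (ties resolved toward larger
widths; even runs take the upper middle). The pipeline's final
decomposition then fixes K at the stable plateau's value and fits at the
chosen width — the tuned width "giving K events" defines the model. This
matters because one systematic residual, the band-pass undershoot that
trails each event, can otherwise enter as a weak satellite event when the
trial count grows faster than the logarithmic BIC penalty.

`build_label_tensors()` converts posterior onset marginals into
per-timestep soft labels with a Negative class so each timestep sums to
exactly 1; timesteps where event probabilities sum above 1 are rescaled
(Negative 0), and pad samples outside the decomposition window are pure
Negative.

# The sequence labeler

`build_model()` composes: a per-timestep linear channel mix (pointwise
convolution, 48 spatial features) → temporal dropout (whole timesteps
zeroed with probability 0.1 during training) → two parallel causal
temporal convolutions at 12 ms and 36 ms (3 and 9 samples at 250 Hz, 48
features each, ReLU), concatenated → an appended relative positional
feature (0 until stimulus, linear to 1 at RT, 1 after) → five stacked
causal sequence-mixing layers → one linear softmax head per task over
{E, C, R, Negative}.

The sequence-mixing layer is a *gated diagonal state-space scan*: per
feature, `h_t = α h_{t-1} + (1 - α) u_t` with a learned decay gate
α = sigmoid(a) initialized to span fast and slow time constants, wrapped
in tanh input and linear output mixes with a residual connection. It
honors the architectural contract (causal, five layers, shared across
tasks, 96-dimensional latent features = the embedding space); the
published selective-state-space kernel would be a drop-in replacement.
The scan and its backward pass are the only compiled code (RcppArmadillo);
all other gradients are hand-derived matrix operations, verified against
finite differences in the test suite.

Training (`train_model()`): Long-condition trials only, both tasks jointly
through the shared encoder with task-specific heads; each epoch draw
re-jitters every trial's window within the 250 ms pre-stimulus and 300 ms
post-RT pads (pad samples carry pure Negative labels); loss is the KL
divergence from the soft labels to the predictions, summed over tasks;
optimization is NAdam (adaptive moments with Nesterov lookahead).
Early stopping halts training when validation loss has not decreased for
three consecutive epochs, and the best-validation-epoch weights are kept.
The reference learning rate is 5e-5; the desk-scale pipeline default is
2e-3 followed by a fine-tuning pass at lr/5, which reaches the same
validation loss in minutes rather than hours at these problem sizes. A
causal model can only begin to detect a centered 50 ms event once roughly
half of it has been observed, so late-epoch sharpening of the
probabilities is where much of the decoding accuracy lives.

At inference (`infer()`) dropout and jitter are off; traces and embeddings
are produced for every trial, including the Short condition the model
never saw. Probability traces outside a trial's own analysis window
(stimulus − 250 ms to RT + 300 ms) are extrapolation over storage padding
and are zeroed before decoding (`crop_traces()`).

# Embedding similarity across conditions

For each trial and operation, the embedding record is the mean latent
vector over 13 samples (52 ms) centered on the operation's peak predicted
probability (peaks below 0.1 are skipped and counted). Long-condition
records come from held-out participants only; Short-condition records from
everyone.

`similarity_resampling()` forms, per task and operation, the sets
Short-same, Long-same and Long-other, and over 1000 iterations resamples
1000 rows from each with replacement, computing
|mean cross-set pairwise cosine distance − mean within-Long-same pairwise
distance| for the same-operation and other-operation comparisons. Mean
pairwise cosine distances are computed in closed form — the mean pairwise
cosine similarity between two sets equals the inner product of their mean
unit vectors (within-set: corrected for self-pairs) — so each resample's
statistic is exact and O(n); no random pair subsetting is needed.
Summaries are medians with percentile 95% CIs. When the same operations
are present in both conditions, the same-operation statistic concentrates
near zero while the other-operation statistic stays well above it, with
non-overlapping intervals.

# Sequence decoding and behavior

`sample_onsets()` aligns Task 2 traces onto the Task 1 clock by the SOA,
normalizes each operation's (window-cropped) trace into a distribution
over time, draws the six onsets independently (1000 draws per trial), and
retains draws satisfying both within-task orderings; `classify_sequence()`
maps each retained draw to A–F or INVALID. The per-trial posterior weights
each retained draw by its predicted probability — the product of the six
sampled onsets' trace probabilities — so a sequence counts in proportion
to how probable the model found it, not only to how often rejection
sampling produced it ("sampling from the distributions, weighted by the
predicted probabilities"). Plain draw counting is available via
`weight_draws = FALSE`; at desk-scale trace sharpness the weighted
posterior recovers planted Short-condition strategies markedly better
(roughly three quarters versus two thirds mode agreement at the fixture
size) and substantially reduces the posterior mass lost to INVALID
orderings. An operation with
essentially no probability mass (< 1e-6 total) marks the trial
undecodable; onset ties are classified INVALID (conservative).

`impute_and_fit()` draws one A–F label per trial from its posterior
(INVALID mass renormalized away; all-INVALID trials excluded), fits
`rt ~ sequence + (1 | participant)` (and the logistic analog for
correctness) with sequence A as the reference level, 100 imputations by
default; non-converging mixed fits fall back to fixed participant
effects, and label levels absent from an imputation leave that
coefficient out of pooling, logged. `pool_rubin()` applies
Q̄, Ū, B, T = Ū + (1 + 1/m)B and df = (m−1)(1 + Ū/((1+1/m)B))²; B = 0
falls back to the normal reference. Pairwise contrasts are computed per
imputation from the coefficient covariance, pooled per contrast, and
Holm-adjusted (`stats::p.adjust`; validated against a hand-computed
example in the tests). Omnibus multi-parameter pooling is out of scope.

# Problem sizes and what the tests show

The default test-suite and acceptance problem sizes are chosen so a full
run completes on a single CPU in minutes: 6 participants with 36 trials
per condition for the end-to-end fixture (about 215 Long trials per
task), width tuning on up to 80 trials per task, training ≤ 60 + 40
epochs at the desk-scale learning rate, 1000 posterior draws, and
100-replicate scaled-down coverage simulations for the pooling
machinery. The generator
itself defaults to 120 trials per condition — the full study conditions —
and all recovery margins (onset error well under one event width, 3-event
plateaus, ≥ 95% serial decoding in Long) hold with margin at the fixture
sizes.

Known limitations worth stating plainly:

* Likelihood-based event-count selection remains liberal against *systematic*
  model misfit (e.g., filter undershoot) as trial counts grow; the
  stability plateau over widths, not the raw cumulative fit, is the
  event-count authority.
* The sequence posterior treats per-operation onset draws as independent;
  correlations the model's traces cannot express are lost, and posterior
  mass on INVALID grows with trace uncertainty rather than indicating
  genuinely impossible behavior.
* CI coverage of the pooled estimates is validated on direct simulations
  of the posterior-to-behavior stage (known estimand); end-to-end
  coverage through the EEG stages inherits whatever bias the decoding
  leaves in the posteriors.
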