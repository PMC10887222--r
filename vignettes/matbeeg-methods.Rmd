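---
title: "Simulating and classifying mental workload in MATB-II EEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and classifying mental workload in MATB-II EEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Task load (TL) is the external demand a multitasking environment places on
an operator — how many subtasks arrive per unit time. Mental workload (MWL)
is the cognitive effort the operator actually expends. The two are related
but not identical, and a long-standing question in applied neuroergonomics
is whether EEG can resolve *quantitative* changes in task load (more events
of the same kind per minute) as opposed to *qualitative* ones (harder
subtasks).

`matbeeg` implements a complete, desk-scale test bed for this question
around the NASA Multi-Attribute Task Battery II (MATB-II): four concurrent
subtasks — System Monitoring (SYSM), compensatory Tracking (TRCK),
Communications (COMM) and Resource Management (RMAN) — arranged into blocks
of four load levels (PW, passive watching; LL low; ML medium; HL high).
Because real recordings from such protocols are rarely shareable, the package's
first-class citizen is a *synthetic study generator* whose outputs carry
exactly the statistical structure the downstream analysis assumes. Every
stage of the pipeline — preprocessing, segmentation and labeling,
convolutional classification, and evaluation statistics — is then testable
end to end against known ground truth.

## The study protocol

A session lasts 51 minutes (3060 s) and is a gapless sequence of blocks:
360 s of PW (blocks of 60 or 150 s) and 900 s each of LL, ML and HL (blocks
of 300 or 150 s). Per 5-minute block the demand rates are fixed by the
protocol table: SYSM anomalies 10/10/20, response-required COMM calls
6/10/14, RMAN demands 5/10/20 for LL/ML/HL; TRCK is off in PW/LL, active in
ML and faster in HL. 150 s blocks carry half the counts, rounded half-up.
The NASA-TLX questionnaire is administered six times per session, twice per
task block type, always after a 5-minute block.

Four fixed block arrangements are used, cycled across sessions. The exact
orders are constructed once by constrained randomization (no two adjacent
blocks of one type; all totals and TLX rules satisfied) from fixed internal
seeds — the testable content of the protocol is its constraint set, and the
constraints are what the package validates (`validate_session_config()`).

Scheduled events are placed on a jittered-uniform grid with a 5 s minimum
gap per subtask: MATB-II scripts are scheduled rather than memoryless, and
segment-label balance downstream depends on this choice, so it is exposed
(`schedule_events()`). COMM additionally receives one distractor
(other-callsign) call per two own-callsign calls; distractors require no
response and are not part of the protocol counts.

## Operator behavior

`simulate_behavior()` turns the event schedule into a response log. Each
response-required event is missed with a small per-subtask probability
(defaults: 4–7%), otherwise answered after a truncated-normal latency.
Engagement intervals follow the subtask's character: SYSM is a short notice
plus one click (0.8 s); COMM spans listening and radio adjustment (≈4.5 s);
RMAN is sustained valve management whose duration follows a per-block-type
duty cycle (20/35/50% of the event spacing in LL/ML/HL). TRCK produces no
discrete events — in the real logs one cannot tell joystick action from
random drift, so the simulator mirrors that by making tracking a
continuous background activity. Out-of-bounds excursions (tracking circle,
tank levels) are scattered as short intervals at configurable rates; they
drive the time-fraction error definitions in `error_rates()`. The default
profile produces the overall-low error rates of well-adapted operators
(all per-subtask rates well below 0.15).

## The EEG forward model

`synthesize_eeg()` builds each 24-channel, 500 Hz recording as a sum of
interpretable components:

* **1/f background** per channel (exponent 1, 10 µV RMS by default);
* a **frontal-midline theta source** (4–7 Hz, centred on Fz/AFz/F3/F4)
  whose amplitude is a nondecreasing step function of the block's load
  class — default 2/5/8/11 µV RMS for PW/LL/ML/HL;
* a **parietal alpha source** (8–12 Hz, Pz/P3/P4/POz/O1/O2) with the
  mirrored nonincreasing gains (11/8/5/2 µV);
* **subtask signatures** — one narrowband, spatially weighted source per
  subtask (SYSM: central beta 18–28 Hz; COMM: temporal 5–9 Hz; RMAN:
  frontal 9–13 Hz; TRCK: centro-parietal 13–18 Hz) that is switched on only
  while the operator is engaged with that subtask (TRCK: continuously
  during ML/HL, stronger in HL);
* **blink artifacts** — stereotyped biphasic transients at 15/min, 80 µV at
  Fp1/Fp2, falling off steeply away from the eyes (0.25 at mid-frontal
  sites). Artifacts are kept on purpose: the pipeline trains on raw
  filtered data.

This encodes the classical workload signatures — frontal theta rising and
parietal alpha falling with demand, hence a monotone theta/alpha index —
as *generator ground truth*, together with subtask-specific spectral
patterns for the detection task. Two calibration points deserve note.
First, the frontal channel group used for the theta source (and for the
monotonicity checks) excludes Fp1/Fp2: prefrontal sites are dominated by
ocular activity in real recordings, and with blinks present a theta
estimate at Fp is a blink meter, not a workload meter. Second, the default
gains are strong enough that block-level band-power estimates order
correctly against the blink and narrowband-estimation noise over ~150 s
blocks (verified by a paired sign test over ten seeded sessions in the test
suite); they remain configuration values, not claims about any real
dataset.

`eeg_params_strong()` is a high-contrast preset used by the scaled-down
training experiments; `ml_hl_confusable = TRUE` equalizes every ML/HL
source statistic (class gains, TRCK gain, and — via `generate_study()` —
the RMAN duty cycle), so the two highest load classes differ only in
event-locked signature counts. This is the controlled analogue of the
situation where two load levels share the same active subtask set and
differ only quantitatively.

What the generator does **not** emulate: inter-subject anatomical and
spectral variability beyond seeded gain jitter, non-stationary drowsiness
or adaptation effects, volume-conduction mixing beyond fixed topographies,
muscle or line-noise artifacts, and any behavioral coupling from EEG back
to performance. Passing tests therefore demonstrate that the pipeline
recovers structure *of the kind assumed*, not that it would reach any
particular accuracy on real recordings.

## Preprocessing

`preprocess_eeg()` applies exactly four steps, in order: (1) zero-phase
1–40 Hz FIR band-pass (windowed sinc, order 1500; >20 dB attenuation at
0.2 Hz and 60 Hz, flat 5–35 Hz passband); (2) average re-referencing with
the channel mean appended as a 25th channel (compensating the rank
reduction); (3) per-channel standardization over the whole session using
the population convention; (4) downsampling 500 → 125 Hz. Because the
band-pass already confines the signal to 40 Hz — well below the 62.5 Hz
output Nyquist — the chain decimates directly; the standalone
`downsample_eeg()` keeps its own anti-alias filter for arbitrary inputs.
Filters are applied in a single pass with reflection padding and exact
group-delay compensation (linear-phase FIR), so the chain is strictly
zero-phase and deterministic. Standardization scope (whole session,
population SD) is one reasonable reading of "channel standard deviation";
it is configurable in spirit by composing the steps manually.

## Segmentation, labeling and splits

Task-load classification cuts 10 s windows with 5 s overlap; subtask
detection cuts 15 s windows with 10 s overlap (both hop 5 s). Over a
3060 s session this yields 611 and 610 windows, and over the full
50-subject × 2-session study exactly 61,100 and 61,000 segments — these
totals forbid dropping block-straddling windows, so a straddler is labeled
by the block containing its midpoint (boundary midpoints go to the earlier
block).

Subtask labels are a 3-bit vector over SYSM/COMM/RMAN driven by *operator
activity*, not stimulus presence: an ignored anomaly leaves no trace in
cognition, so it gets a 0. SYSM (discrete) fires if a responded event
starts inside the window; COMM and RMAN (continuous) fire when the engaged
time inside the window totals at least 2 s. The 2 s threshold is the
standard operating point for this protocol and remains configurable, since
it trades false positives near block edges against false negatives for
partially covered engagements. TRCK is never labeled (unobservable in the
logs).

Splits are session-exclusive: whole sessions go to train or test, so
overlapping windows can never leak across the boundary. The default holds
out 5% of sessions; `make_cv_folds()` partitions all sessions into 20
grouped folds so each fold's test share is 5%.

## The model

The encoder is a 10-layer 1-D CNN over time in the style of a wav2vec
feature encoder: kernel sizes (3, 2, 2, 3, 4, 5, 6, 7, 8, 9), strides
(2, 1, 1, 1, 2, 2, 2, 1, 2, 1), valid convolutions (no padding — the
23-frame/42-frame output lengths for 10 s/15 s inputs depend on this
convention), residual skip connections over layers 2 and 3 (each kernel 2,
stride 1; the identity path is cropped by its trailing frame before
addition), and group normalization + GELU + dropout between layers. The
decoder pools encoder frames over time and applies a 2-layer fully
connected network (hidden width 128): a 4-class softmax head with
cross-entropy loss for task load, or a 3-unit sigmoid head with binary
cross-entropy for subtask detection.

The pooling is concatenated mean **and** max over frames. Plain mean
pooling was the original choice (simplest length-independent collapse),
but it fails the detection task structurally: a System-Monitoring
engagement lasts under a second, i.e. about 2 of the 42 encoder frames of
a 15 s window, and averaging dilutes that burst below learnability at
reduced scale. Max pooling preserves the strongest frame per feature
channel; concatenating both keeps the sustained spectral evidence the
task-load head relies on. Both variants are length-independent, which is
why one architecture serves both window lengths. The pooled vector is
normalized per sample (learnable scale and shift) before the FC stack:
the max branch runs on a different scale than the mean branch, and
without this normalization optimization is fragile — on some seeds the
task-load head collapses to a single class.

One detection label has an inherent ceiling worth knowing about: SYSM is
labeled 1 when a *responded event's onset* falls inside the window, but
the evoked burst starts one response latency later — so bursts from
onsets in the last couple of seconds of a window largely fall outside it,
and symmetric spillover contaminates windows labeled 0. Roughly a tenth
of positive windows carry little or no in-window signal, which caps SYSM
F1 well below the continuous subtasks regardless of signature strength.

Choices the architecture description leaves open, resolved here: GELU in
the encoder and ReLU in the decoder; normalization placed after each
convolution and before the activation; a single normalization group per
sample by default (batch-size-independent, like all per-sample schemes, and
cheap — the group count is configurable); dropout 0.1; batch size 64 in
the full configuration; AdamW weight decay 0.01 applied to weight matrices
only. The GELU uses the standard sigmoid approximation
`x · σ(1.702 x)`; its gate is cached so the backward pass is pure
arithmetic.

Training follows the study schedule: 35 epochs of AdamW with the
learning rate rising linearly to 0.05 over 5 epochs, constant to epoch 20,
then cosine-decaying to 0.005 (per-epoch steps). A peak rate of 0.05 is
aggressive for AdamW; it is implemented verbatim, and the scaled-down
validation runs override it (see below). The whole stack — initialization,
data order, dropout — is a pure function of its seeds; training twice with
one seed gives bit-identical parameters.

All tensor operations are written on BLAS matrix products (im2col +
GEMM convolutions with hand-derived backward passes); analytic gradients
are verified against central finite differences in the test suite at
tolerance 1e-4 and agree to ~1e-8.

## Evaluation and statistics

`tl_confusion_matrix()`, `detection_metrics()` (per-label precision /
recall / F1 / accuracy plus AUC via the midrank Mann–Whitney statistic) and
`error_rates()` implement the reported metrics. "Overall" detection
figures are reported both ways the term can be read: `micro` pools all
label-instances, `macro` averages per-label metrics. The pooled-score ROC
is the single-curve reading of an all-subtasks ROC. The hard-decision
threshold is 0.5, with scores exactly at the threshold labeled 1.

`tlx_anova_tukey()` tests the NASA-TLX ratings (LL vs ML vs HL; PW is
excluded as a no-load resting state) with a balanced one-way ANOVA and
Tukey's HSD: a pair differs significantly exactly when its absolute mean
difference exceeds `qtukey(0.95, 3, N−3) · sqrt(MSW/n)`. The module is
implemented from the closed-form sums of squares and the numerically
computed studentized-range quantile so that `stats::aov`/`TukeyHSD` can
serve as an independent cross-check (they agree to 1e-8 over randomized
designs in the test suite); unbalanced input falls back to Tukey–Kramer
with a flag.

TLX generation uses class means with gaps of ≈12 points between LL and ML
and ≈6 between ML and HL on the four workload variables, and a default
within-class SD of 10 points. The dispersion is a design choice: it keeps
the simulated study's inferential structure (every pairwise HSD comparison
significant at 200 assessments per class) stable across seeds. Real TLX
dispersions are larger (≈20 points), under which the smallest gap sits at
the HSD threshold's knife edge — worth remembering when reading the
simulated statistics as a template rather than a prediction.

## Scaled-down validation experiments

The package validates learning end to end on a reduced study whose size is
chosen for desk-scale runs: 8 subjects × 2 sessions of 12 minutes (a
"mini" protocol assembled from the same allowed block durations — two 60 s
PW blocks and four 150 s task blocks), the high-contrast generator preset,
encoder width 32, 5 epochs, batch 32, and a session-exclusive 12/4 split.
At this width and horizon the full-scale peak rate of 0.05 diverges, so the
validation runs use peak 0.002 with a 1-epoch warmup, constant to epoch 3,
cosine to 2e-4 — the config-override path the full schedule also uses.
Under these conditions the held-out 4-class task-load accuracy clears 0.60
(chance 0.25), subtask detection clears macro-F1 0.80, and in the
confusable configuration the ML-vs-HL restricted accuracy collapses to
0.5 ± 0.1 while the other classes remain separable — the package's
controlled reproduction of the finding that quantitatively differing load
levels with identical subtask sets are the ones EEG fails to separate.

## Numerical conventions and degenerate inputs

Worth knowing when extending the package:

* population (divisor-n) SD in standardization; zero-variance channels are
  a hard error naming the channel;
* EDF I/O quantizes to the 16-bit step of each channel's physical range;
  truncated files error rather than return partial data;
* windows start at 0 and advance by the hop; a session shorter than one
  window is an error;
* encoder inputs shorter than 537 samples exhaust the convolution stack and
  error with the offending layer;
* argmax ties in prediction resolve to the earlier class in (PW, LL, ML,
  HL) order; sigmoid scores exactly at threshold label 1;
* all generators restore the caller's RNG state and derive per-session
  streams from a master seed kept below 2^31.

## Known limitations

The forward model's subtask signatures are fixed narrowband topographies;
a richer simulator would add event-related transients and cross-frequency
structure. The mini protocol's class balance differs slightly from the
full protocol's (PW ≈17% rather than ≈12%). Training is CPU-bound R; the
full 61k-segment, width-128, 35-epoch configuration is expressible but
meant for workstations, not laptops — the package's claims are validated at
the reduced scale described above.
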