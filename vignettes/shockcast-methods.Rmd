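---
title: "Methods: hourly septic-shock labeling, feature pipeline and LSTM evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hourly septic-shock labeling, feature pipeline and LSTM evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

shockcast implements an early-warning pipeline for septic shock in ICU
admissions: a rule-based hourly phenotyper under the Sepsis-2 (SIRS-era)
operational definitions, a feature-extraction pipeline that turns raw
timestamped event tables into dense standardized hourly grids, a stacked
LSTM sequence classifier emitting a per-hour probability of impending
septic shock, and an evaluation harness built around stratified six-fold
cross-validation, bootstrap AUROC confidence intervals, hours-before-onset
(HBO) lead times and a sliding pre-onset AUROC curve. This vignette
records the scientific and numerical choices behind each stage.

## The clinical rule core

Each admission-hour is assigned the highest applicable state in
`negative < sepsis < severe_sepsis < septic_shock`:

* **SIRS criteria** (0-4, each counted once even when both of its
  sub-conditions hold): temperature below 36 or above 38 degC; heart rate
  above 90/min; respiratory rate above 20/min *or* PaCO2 below 32 mmHg;
  white-cell count below 4,000 or above 12,000 per microlitre.
* **Sepsis**: at least two SIRS criteria during an hour at which an
  infection is suspected.
* **Severe sepsis**: sepsis plus at least one sepsis-related organ
  dysfunction: SBP < 90 mmHg; lactate > 2.0 mmol/L; urine output
  < 0.5 mL/kg over the trailing 2 h *despite adequate fluid
  resuscitation*; creatinine > 2.0 mg/dL unless chronic renal disease is
  coded (ICD-9 V45.11/585.9); bilirubin > 2.0 mg/dL unless chronic liver
  disease is coded (ICD-9 571.x); platelets < 100,000/uL; INR > 1.5;
  PaO2/FiO2 < 200 with coded pneumonia (ICD-9 486) or < 250 without it.
* **Septic shock**: severe sepsis plus hypotension (SBP < 90 mmHg)
  despite adequate fluid resuscitation, where adequacy means at least
  20 mL/kg over the trailing 24 h or at least 1,200 mL in total.

Conventions worth making explicit:

* All comparisons are exactly as printed: strict for `<`/`>`, inclusive
  for the two fluid thresholds. SBP of exactly 90 mmHg is *not*
  hypotension; 20.000 mL/kg *is* adequate.
* Infection suspicion is an **input** (per-admission half-open hour
  intervals), not a computed quantity. How suspicion is operationalized
  from orders or coding varies by site and data source; keeping it out of
  the rule core keeps the rules verifiable. Adapters for real extracts
  should populate the intervals upstream.
* "Simultaneity" means co-occurrence within the same hourly bin; the
  labeler runs on the binned, imputed grid, always in physical units
  (standardization exists only for the model).
* `fluids_total` is cumulative since admission. A windowed total is a
  plausible alternative reading of "total fluid replacement"; the window
  quantities are derived by one function from raw event times, so a
  different convention is a one-line change.
* The same fluid-adequacy predicate gates both the oliguria criterion and
  the shock criterion ("despite adequate fluid resuscitation" appears in
  both), so there is a single code path for it.
* The two acute-lung-injury criteria are implemented purely as
  PaO2/FiO2-ratio thresholds split by the pneumonia flag; no separate
  acute-lung-injury diagnosis is required.
* Features never observed during an admission fall back, for *labeling
  only*, to a per-feature reference normal value shipped in the feature
  table, rather than to a population mean. An unmeasured lab should never
  fire a criterion, and a cohort mean of a pathological cohort could.
  (Model inputs use the population mean instead, which preserves
  cohort-level information; see below.)

Newer Sepsis-3/SOFA definitions are deliberately out of scope: the
SIRS-based rules are the ones used by the TREWScore family of early
warning systems this pipeline is designed to be comparable with.
Treatment-censoring effects (shock-directed therapy masking criterion
fulfilment) are likewise not modelled explicitly; a sequence model can in
principle learn them from data where they occur.

## Feature pipeline

1. **Age filter**: admissions younger than 15 years are removed (the
   pediatric sepsis definitions differ).
2. **Clinical-range outlier removal**: an event is dropped when its value
   lies strictly outside the `[lower, upper]` range of its feature;
   boundary values are retained. The shipped range table
   (`default_feature_table()`) is documented configuration, not ground
   truth — users can supply an edited copy everywhere a `ranges` argument
   appears.
3. **Hourly binning**: each event goes to its nearest whole hour; ties at
   .5 round half up (deterministic and exhaustively tested). Multiple
   events of a feature in one bin are reduced to their arithmetic mean
   (symmetric, order-independent).
4. **Zero-order hold**: missing cells take the most recent observed value
   of the same feature in the same admission; imputation never crosses
   admission boundaries and is idempotent.
5. **Population-mean fallback**: cells before an admission's first
   observation of a feature take the population mean of observed values.
6. **Standardization**: non-binary features are mapped to
   `(x - mean) / sd`; binary flags pass through unchanged.

Population statistics (mean and n-1 SD over *observed* cells only) are
computed on the training folds of each cross-validation rotation and
applied to validation and test admissions, so no distributional
information leaks across the split. The observation mask is preserved
through imputation precisely so the fitting scope can be restated at any
time.

Trailing-window quantities (urine output per kg over 2 h, fluids over
24 h, cumulative fluids) are computed from raw event times *before* any
binning or imputation: window semantics are physical, not grid artifacts.
Fluid boluses are episodic orders rather than an hourly signal, so they
enter the model only through these window features.

The model feature set (about 30 inputs) comprises the vitals and labs
named by the criteria, routine ICU chemistry, the three window features,
age and weight, and the three chronic-condition flags broadcast per hour.
Feature-specific look-back windows for imputation (as used by some
earlier systems) are intentionally not implemented; zero-order hold with
a population-mean fallback is the simpler, fully-specified scheme.

## The LSTM classifier

Each layer follows the standard LSTM recurrence with logistic-sigmoid
gates and tanh state nonlinearities,

$$
\begin{aligned}
f_t &= \sigma_g(W_f x_t + U_f h_{t-1} + b_f)\\
i_t &= \sigma_g(W_i x_t + U_i h_{t-1} + b_i)\\
o_t &= \sigma_g(W_o x_t + U_o h_{t-1} + b_o)\\
c_t &= f_t \circ c_{t-1} + i_t \circ \sigma_c(W_c x_t + U_c h_{t-1} + b_c)\\
h_t &= o_t \circ \sigma_h(c_t),
\end{aligned}
$$

with states initialized to zero at hour 0, layer $\ell$'s hidden state
feeding layer $\ell + 1$, and a single affine + sigmoid head mapping the
top layer's $h_t$ to a per-hour probability. The head is the minimal
choice for a scalar risk; nothing in the training regime depends on it
beyond its gradient.

The reference full-scale configuration (`lstm_config()`) is four layers
of 100 units, dropout probability 0.4, 1,000 epochs of 40 mini-batches
with 50 sequences each, and positive sequences weighted 3 times higher in
the loss. The weight of 3 rather than the ~10x admission-level imbalance
reflects hour-level counts: positives' stays contribute proportionally
more labeled hours, leaving roughly a 4:1 hour imbalance. The test suite
constructs this configuration and verifies one forward/backward step, but
routine runs use `desk_scale_preset()` — 2 layers of 16 units, dropout
0.2, 30 epochs of 8 x 32-sequence batches, learning rate 0.01 — sized so
the full six-fold harness on a 300-admission synthetic cohort completes
in about half a minute on one CPU core.

Choices the architecture leaves open, and what this package does:

* **Target construction.** The outcome is an admission-level label; the
  network is trained per hour against that label replicated across the
  admission's hours, with positive admissions' inputs truncated at
  shock onset (hours after onset would leak the diagnosis into the
  input). Per-hour outputs are what give first-alarm (HBO) semantics; the
  truncation makes "predict before it happens" the actual training task.
* **Loss.** Class-weighted binary cross-entropy, normalized by total
  weight over the batch. Variable-length sequences are handled by
  processing each sequence at its own length (no padding is ever scored).
* **Optimizer.** Adam (beta1 0.9, beta2 0.999) with global L2
  gradient-norm clipping at 5. The learning rate and clip are recorded in
  the training log together with loss and periodic train/validation
  AUROC (every `validation_interval` epochs, default 10 at full scale).
* **Dropout variant.** Inverted dropout on the non-recurrent (inter-layer
  and input) connections only, one mask per sequence, active only during
  training — the standard adaptation of dropout to recurrent networks.
  Recurrent connections are never dropped.
* **Determinism.** Initialization (Glorot-uniform, forget-gate bias 1),
  batch sampling and dropout masks all draw from R's RNG under the
  configuration seed, so a training run is exactly reproducible.

The recurrence and backpropagation-through-time are implemented in
compiled code (RcppArmadillo); an independent, naive pure-R
transcription of the same equations (`lstm_cell_step()`,
`lstm_forward_naive()`) is kept solely as an oracle, and the test suite
holds the two implementations together to 1e-10 and the analytic
gradients to finite differences. Numerical safeguards: the loss is
computed from logits via a stable softplus; probabilities are never
clamped.

## Evaluation protocol

A stratified 5% validation holdout is set aside first; the remaining
admissions are dealt, class by class, round-robin into six folds, so fold
sizes and class proportions are as even as possible. Six model instances
are trained, each on five folds with population statistics computed on
exactly those five folds, and each scores only its held-out fold — every
admission is scored by the one model that never saw it.

* **Admission score**: the maximum per-hour probability over the
  (onset-truncated) stay, matching first-alarm semantics.
* **AUROC**: rank (Wilcoxon) formulation with ties counted one half;
  equal to the trapezoidal area under the empirical ROC, and
  cross-checked in the tests against both brute-force pair counting and
  pROC. Confidence intervals are percentile bootstraps over the six
  fold-level AUROCs (the fold, i.e. the trained instance, is the unit of
  replication); pooled-prediction bootstrap would mix model instances.
* **HBO**: for each correctly predicted positive, onset hour minus the
  first hour whose probability reaches the operating threshold;
  admissions never alarmed at or before onset are excluded from the
  median/IQR. The operating threshold is chosen per fold on the
  validation holdout as the largest threshold reaching a target
  sensitivity (default 0.85); the target, thresholds and exclusion count
  are all recorded in the report.
* **Pre-onset AUROC curve**: for each offset h = 1..48, positives are
  scored by their probability at exactly h hours before onset and
  compared against negatives' admission scores; positives with less than
  h hours of pre-onset history are skipped for that offset and counted.
  Scoring at the single offset hour (rather than a running maximum over
  the last h hours) is what makes the curve answer "how reliable is a
  prediction made h hours out": a window maximum would be dominated by
  the hour closest to onset at every offset and flatten the curve by
  construction. Per-offset CIs bootstrap the six fold-level curves.

The report object retains the pooled predictions, per-admission scores,
fold assignment and per-fold thresholds, so every summary in it can be
recomputed from its own contents (the test suite does exactly that), and
`write_report()` emits the JSON/CSV forms.

## Synthetic cohort generator

The generator exists so that every rule branch and every evaluation
statistic can be exercised on data with known ground truth. Positive
trajectories are built compositionally, mirroring the nesting of the
criteria: a deterioration ramp (8-16 h) raises temperature, heart and
respiratory rate inside an infection-suspicion interval (SIRS + sepsis);
lactate crosses 2 mmol/L in the last ~4 pre-onset hours (organ
dysfunction); three 500 mL boluses in the three pre-onset hours cross the
1,200 mL adequacy total; and systolic pressure, held at or above 92 mmHg
before onset, drops below 90 at the intended onset hour. The generator
then runs the package's own labeler and requires the labeled onset to
equal the intended hour exactly (bounded resampling on failure — in
practice the construction virtually always verifies on the first
attempt). Negative admissions keep SBP at or above 95 mmHg, so they can
transiently reach sepsis or severe sepsis (30% receive infection
intervals, some receive small boluses) but can never satisfy the shock
rule. Positives are drawn by count, so realized prevalence is exact.

Default conditions: stays of 24-96 h, 30% missingness applied per
feature-hour (MCAR), admission-hour measurements always present, urine
output charted hourly, and the deterioration-critical vitals always
recorded once deterioration starts (as they would be in practice for a
patient under concern). A block-missingness mode draws labs only every
k hours instead, because zero-order hold behaves differently under
scheduled sampling. Values are clamped into the clinical ranges;
out-of-range values exist only via `inject_outliers()`, which corrupts a
seeded, exactly-counted subset of events for testing the outlier filter.

What the generator does *not* emulate: real physiology (no pharmacology,
no organ-system coupling, no treatment feedback), informative missingness,
measurement error structure, or the covariate distributions of any real
ICU population. Passing tests on synthetic data therefore demonstrate
the correctness of the machinery — labeling, imputation, training,
evaluation bookkeeping — and the recoverability of a planted
deterioration signal; they say nothing about clinical performance on
real cohorts, which is exactly why the evaluation harness treats real
EHR extracts as a first-class input format.

## Problem sizes and runtime

The shipped study conditions for the end-to-end checks are 300
admissions at 30% prevalence under the desk-scale preset with six-fold
cross-validation; this runs in roughly half a minute on a single core,
and the whole test suite in about a minute. The pooled AUROC on these
conditions sits well above 0.9 (the planted ramp is strongly separable),
HBO medians land within the 8-16 h ramp — alarms fire once deterioration
begins, as designed — and the pre-onset AUROC curve rises toward onset,
reproducing the qualitative signature expected of a model whose
predictions become more reliable as the event approaches. The numbers
themselves are computed fresh by `scripts/acceptance.R` and the test
suite on every run; none are hard-coded.

## Known limitations

* The SIRS-based definitions are outdated relative to Sepsis-3; they are
  retained for comparability with the early-warning literature built on
  them.
* Infection suspicion, chronic-condition flags and weight must be
  supplied; the package performs no ICD-9 or order-based inference.
* The clinical range table and the ~30-feature set are documented
  defaults, not a canonical list.
* `fluids_total` uses an unbounded window by default (see above).
* The full-scale 4x100/1,000-epoch configuration is supported but not
  routinely executed in tests; training at that scale on a large cohort
  is a multi-hour single-core computation.
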