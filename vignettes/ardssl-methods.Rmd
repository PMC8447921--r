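---
title: "Methods: semisupervised attention-GRU prediction of ARDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semisupervised attention-GRU prediction of ARDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute respiratory distress syndrome (ARDS) is an inflammatory lung injury
that progresses to hypoxemic respiratory failure. Early warning matters:
hours separate the first subtle deterioration in routine vitals from overt
failure. `ardssl` implements a complete pipeline for predicting, at the
moment a patient's peripheral oxygen saturation (SpO2) first drops below
the normal range (< 97%), whether that patient will go on to develop
ARDS-level respiratory failure during the remainder of the stay — together
with a semisupervised teacher–student scheme that exploits encounters whose
outcome labels are withheld, and a synthetic cohort generator so that every
stage is testable without access to patient data.

## Gold-standard labels

Seven binary outcomes are derived per encounter from timestamped ICD codes
and physiologic time series (`label_outcomes()`; order in
`outcome_names()`):

1. **Primary — ARDS with verified respiratory failure**: a *new* ARDS ICD
   code (J80, J96.0, J96.2, J96.9, 518.81) together with physiologic
   respiratory failure, both at or after the prediction time.
2. ARDS ICD code alone; 3. COVID-19; 4. acute kidney injury;
5. thrombosis; 6. sepsis (each from its published code list);
7. mechanical ventilation strictly after the SpO2 drop.

Three time anchors:

* **Prediction time** — first SpO2 measurement strictly below 97%.
* **Respiratory-failure onset** — first SpO2 < 92%, or first
  PaO2/FiO2 < 300, whichever is earlier. The FiO2 paired with a PaO2 value
  is the last FiO2 recorded at or before that measurement, defaulting to
  0.21 (room air) when none exists; the pairing rule is ours, since
  asynchronous blood-gas charting admits no unique convention.
* **ARDS ICD onset** — earliest post-admission ARDS code, provided no code
  from the family appears in the 1000 hours before admission (the
  *novelty rule*, applied to all ICD-defined outcomes).

Deliberate readings of ambiguous points, all strict:

* thresholds use strict inequalities (< 97, < 92, < 300); a measurement at
  exactly the threshold never triggers;
* ICD matching is dot-insensitive prefix matching (J96.01 matches J96.0),
  the conservative reading of printed code lists across ICD dialects;
* the primary label requires both qualifying events at/after the
  prediction time, so information arriving before the model's scoring
  moment can never leak into a positive label;
* inclusion requires a stay of at least 3 hours (boundary inclusive) and a
  prediction time.

## Feature encoding

`build_matrix()` produces a fixed 49 x 32 matrix per encounter
(machine-readable schema in `inst/extdata/feature_layout.json`):

* rows 1–6: constants — z-scored age, male, female, antibiotics before the
  prediction time, supplemental oxygen before the prediction time,
  heart-failure history (replicated across real columns);
* 21 (mask, value) row pairs, one per time-varying feature (vitals and
  routine labs). A mask of 1 marks the feature as measured at that step;
  values are z-scored with training-set statistics (`fit_stats()`), and a
  masked-out cell carries 0 — the training mean in normalized space;
* one time-delta row: minutes since the previous kept step, z-scored, 0
  for the first kept step and padded columns.

Columns are *update steps*: distinct observation times up to and including
the prediction time. Only the 32 most recent steps are kept; shorter
sequences are left-padded with all-zero columns so the most recent step is
always adjacent to the sequence end that the GRU summarizes. The
prediction-time measurement itself (the triggering sub-97 SpO2) is
included as the final step — it is the most recent information available
when the score is issued; this is an interpretive choice, flagged for
sensitivity analysis. Observations sharing a timestamp merge into one
column. Normalization statistics are unbiased means/SDs over all
pre-prediction-time observations of the designated training split, with
SDs floored at 1e-6 for degenerate features.

## Model

The classifier (`model_forward()`) is, in order:

1. **Learned normalization** of each input column
   (`normalize()`): `n(v) = a ⊙ (v − μ)/(σ + ε) + b`, with all four
   vectors learned and ε = 1e-7. Because inputs are already z-scored by
   the feature encoder, the layer initializes to the identity
   (μ = 0, σ = 1, a = 1, b = 0); composed with the encoder it therefore
   *starts* as a plain training-set z-score and may drift as it learns.
2. A **2-layer GRU**, 64 hidden units per layer (32 in the desk-scale
   benchmark).
3. **Soft attention** over the deepest layer's hidden states. With `l` the
   final deepest hidden state and `h` any deepest hidden state,
   `score(l, h) = K · tanh(A · prelu(B · n([l, h])))`. The inner `n(·)` is
   an independent learned-normalization instance (whether it shares
   parameters with the input layer is not pinned down by the published description; an
   independent instance is the more expressive reading). The prelu slope
   is a single learned scalar initialized at 0.25. Scores pass through a
   temperature-1 softmax over all 32 steps; the **context vector** is the
   weight-sum of deepest hidden states.
4. A 2-layer **feed-forward classifier** on `[l, context]`
   (64 + 64 = 128 inputs), a 64-dimensional ReLU penultimate embedding,
   and 7 sigmoid outputs.

The loss is masked multitask binary cross-entropy: the mean, over outcomes
whose mask is 1, of the per-outcome BCE. Gold-labeled samples use all-ones
masks; pseudolabeled samples mask everything but the primary ARDS outcome.

Forward pass and analytic backpropagation are implemented natively
(RcppArmadillo) with all per-step projections batched into single matrix
products; gradients are verified against central finite differences to
better than 1e-4 relative error in the test suite.

## Training

`train_supervised()` runs minibatch Adam (lr 0.001) for at most
`max_epochs` epochs (40 by default). Output biases initialize at the
training-set base-rate logits (`init_output_bias`), the standard
stabilizer for rare outcomes: at 2–5% prevalence a symmetric random start
intermittently leaves the optimizer stuck at the base-rate solution. The learning rate is multiplied by
0.9 after the *validation* multitask loss increases over 2 consecutive
epochs — the published description does not say whether the scheduler watched
training or validation loss; validation matches the checkpointing
criterion, and checkpointing itself watches the ARDS outcome alone —
overfitting control is deliberately blind to the auxiliary outcomes. The returned checkpoint is the
epoch with minimal ARDS validation loss. An optional early stop
(`stop_patience`, default 6 epochs without ARDS validation improvement)
implements training to validation convergence and keeps desk-scale
budgets; it never changes which checkpoint is returned, only
how long the search runs. The default batch size is 256 (the reference
configuration used 2048 across 4 GPUs; 2048 remains available).

`split_cohort()` reproduces the published partition arithmetic: test =
all patients of held-out hospitals; then round-half-up(10% of N) to
validation; then floor(30% of M) to labeled — the only rounding pair
consistent with both printed splits (2567 of 25,670 and 6930 of 23,103).
Splits are plain uniform seeded draws, unstratified.

## Semisupervised loop

`ssl_train()` implements confidence-banded self-training. With `m` the
mean teacher probability for the primary outcome over the unlabeled pool:
probability > 2m ⇒ pseudo-positive, < m ⇒ pseudo-negative, the closed
band in between ⇒ unconfident and unused this cycle (both comparisons
strict: a probability exactly at either threshold stays unconfident). Each cycle: a *freshly initialized*
student trains on labeled + confident-pseudolabeled samples, is fine-tuned
on the labeled set (fresh scheduler state at one tenth of the base
learning rate — at the full rate the small labeled set simply overwrites
what was learned from the pool; a reduced rate is the conventional meaning
of fine-tuning, whose settings are otherwise unstated), is scored by
validation AUROC on the primary outcome, and becomes the next teacher; `m` is recomputed each cycle over the full pool. The best cycle's
checkpoint is returned (4 cycles by default). Pseudolabeled samples
contribute only the ARDS loss: inventing auxiliary pseudolabels is the
alternative reading, not implemented here: pseudolabelling is defined on
the ARDS outcome only, and inventing auxiliary pseudolabels would import
teacher noise into six extra loss terms.

True labels of the unlabeled pool sit behind an access guard
(`guard_labels()`); only `train_all_data_ceiling()` may open it, with an
explicit purpose string, and every access is counted so the test suite
can assert that SSL never peeked.

## Evaluation

`auroc()` is the rank-based Mann–Whitney statistic (ties counted half);
`auprc()` integrates precision stepwise over recall at every distinct
score cut. Both are checked exactly against brute-force oracles
(all-pairs counting; exhaustive threshold sweep). Operating points
(`confusion_metrics()`) use score ≥ threshold; the threshold is chosen on
validation data to achieve a target sensitivity (default 0.78, the
reference SSL operating point; no explicit thresholding rule is ever
stated). `attention_heatmap()` extracts each encounter's
maximally attended non-padded step (earliest on ties) and averages the
z-scored values of features actually measured there (mask 1 only), with a
min-max rendering across features. `embed_project()` projects penultimate
embeddings onto two principal components; t-SNE is deliberately omitted
(nondeterministic, untestable) in favour of PCA.

## The synthetic cohort: what it is and is not

`generate_cohort()` draws a latent deterioration indicator at the
configured prevalence (default 0.02). Deteriorating encounters receive a
planned decline: SpO2 crosses 97% (lognormal onset, median 12 h into the
stay), reaches failure (< 92%) after a lognormal gap of median 21 h, and
an ARDS ICD code follows after a lognormal lag of median 38 h — so the
prediction-to-ICD gap has median near 59 h, echoing the reference
look-ahead medians (21 h / 59 h). Both crossings are inserted explicitly,
so the labeler's strict scans are guaranteed to find them. Before the
decline, deteriorating patients draw SpO2 from the *same* baseline
distribution as controls; the realized prediction time may therefore be an
earlier noise dip, exactly as in real cohorts, and `sim_truth` records the
realized crossings. Respiratory rate, heart rate and the other drifting
features shift linearly toward failure over a 24-hour prodrome, scaled by
`deterioration_signal_strength` (0 removes all informative drift; the
recorded SpO2 label structure remains). Deteriorating patients belong to
one of four latent presentation subtypes (cardiorespiratory, febrile,
renal/coagulopathic, hepatic) that select which feature groups drift, with
per-patient magnitude jitter: heterogeneous presentations keep the task
learnable while ensuring a small labeled set genuinely undersamples the
positive class — without this, a few dozen positives saturate the
achievable AUROC and the semisupervised comparison degenerates. Hospitals impose small random
per-feature mean shifts (site effect, supporting the by-hospital
hold-out); auxiliary outcomes are conditionally independent given ARDS
status; a configurable fraction of patients carries pre-admission ICD
history in the 1000-hour window, occasionally including outcome-family
codes so the novelty rule is exercised.

Defaults were fixed once from clinical plausibility: vitals sampled about
every 2 h and labs ~12x sparser; adult age and vital/lab baselines at
textbook values; lognormal stay length with median 60 h. What a green test
establishes: the pipeline's mechanics — labeling, encoding, optimization,
pseudolabel bookkeeping, metric computation — and the *direction* of the
semisupervised effect on a learnable task. What it does not establish:
real-world discrimination, calibration, site transportability, or any of
the reference cohort's absolute metric values, which came from private
hospital data and are not reproducible here.

## Numerical and engineering choices

* Times are float hours from admission, snapped to a whole-second grid so
  ISO-8601 CSV round trips are exact; minutes appear only in the
  time-delta feature.
* ε = 1e-7 in both normalization layers; SD floors at 1e-6; BCE computed
  in the numerically stable log1p form; softmax with max subtraction.
* All randomness flows through explicit integer seeds (generator, splits,
  weight initialization, batch shuffling); two runs with one config are
  bit-identical on the same BLAS.
* The desk-scale SSL benchmark (`ssl_benchmark()`) uses batch size 64
  rather than 256: with 1500 labeled encounters and a 15-epoch cap, 256
  would allow only ~90 optimizer steps, too few for the GRU to converge at
  lr 0.001; this is an optimizer-budget consideration, not a change to the
  generated world.
* Checkpoints and runtime artifacts persist as RDS files and JSON/CSV
  reports; the feature-layout schema ships as JSON. (HDF5 and YAML
  carriers were considered but no suitable R packages are available in the
  supported environment.)

## Known limitations

* The generator's physiology is rank-signal realistic only; it has no
  waveforms, notes, treatment feedback loops, or informative missingness
  beyond per-feature sampling rates (per-feature missingness rates are
  config knobs, deliberately uncalibrated).
* Pseudolabeled samples never receive teacher-derived auxiliary labels;
  the alternative reading is documented but not implemented.
* ICD-9 code 518.81 is matched only as printed; sibling ICD-9 codes are
  not admitted.
* No calibration analysis, decision-curve analysis, or prospective
  evaluation.
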