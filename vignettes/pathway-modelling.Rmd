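---
title: "Modelling coded EHR pathways to diagnosis"
author: "codepaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coded EHR pathways to diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lung cancer is usually diagnosed late, and the coded primary-care record
of the three years before diagnosis — symptoms, tests, referrals,
medications, encounter sites — carries predictive signal that classic
regression models discard, because they aggregate the record into a bag
of features and ignore *when* and *in what order* things happened. This
package implements an end-to-end framework for

1. deriving each patient's **pathway to diagnosis**: the temporally
   ordered sequence of curated clinical code groups observed in a
   lookback window before an index date;
2. modelling pathways with a small **shared-parameter transformer
   encoder** pretrained by masked-code prediction and fine-tuned with a
   logistic classification head;
3. comparing it against a **bag-of-codes logistic regression** on exactly
   the same patients;
4. evaluating at clinically meaningful operating points and probing the
   sensitivity of the result to pre-index trimming; and
5. interpreting the fitted model through attention profiles and k-means
   clustering of pathway embeddings.

Because real primary-care extracts cannot be shared, the package ships a
**synthetic coded-EHR generator** whose ground truth is known, so every
stage of the pipeline is testable end to end.

## Pathways to diagnosis

For a case, the index date is the date of the **first** lung-cancer
diagnostic code; lung cancer takes precedence when several cancers are
coded. Controls with another cancer index at their first such code; other
controls index at their **most recent** diagnostic code. The pathway then
contains the curated tokens of all events dated in

$$[\text{index} - \text{lookback},\ \text{index} - \text{trim})$$

with calendar-month arithmetic (same day-of-month, clamped to month end),
closed below and open above. Defaults are a 36-month lookback and a
1-month trim; trimming exists because diagnoses are often coded with
delay and post-referral findings can leak into the immediate pre-index
record, inflating apparent performance.

Decisions the window logic takes where the underlying convention is
genuinely open, fixed here for determinism:

* same-day events order by (date, group id, input row order);
* duplicate codes are kept — repeat presentations carry signal;
* the "at least 10 curated codes" eligibility filter is applied to the
  full 36-month curated pathway, before trimming;
* sequences longer than the model's maximum length keep the most
  *recent* tokens (recent events are the most predictive).

Raw codes are curated by a many-to-one map onto ~450 higher-level groups
with purely administrative codes dropped. The clinical content of a real
curation table is input data, not code: the package ships the format and
a 450-group synthetic demonstration map. Unmapped codes are dropped by
default (the curated vocabulary is closed); an option keeps them as an
`[UNK]` token instead.

## The sequence model

The encoder is a BERT-family transformer in the "lite" parameterisation:
factorized embeddings (vocabulary × E, then E × hidden) and one encoder
block shared across all layers, which cuts parameters several-fold at
equal depth. Inputs are flat `[CLS]`-prefixed token sequences with
learned absolute position embeddings; GELU feed-forward blocks (tanh
approximation); post-block layer normalisation. Position embeddings are
initialised to a small-amplitude sinusoidal pattern rather than noise:
they remain fully learned, but positional structure is then linearly
salient from the first optimisation step, which at reduced model scale
shortens the initial plateau before order-dependent signal is picked up
by roughly an order of magnitude. The study-scale
configuration is 6 layers × 12 heads, hidden size 768, embedding size
128, maximum length 512, vocabulary 454 (450 groups + 4 specials). A
first-class `"desk"` preset (2 layers × 4 heads, hidden 64, embedding
32, maximum length 128) is used by the test-suite and examples so that
every property of the full architecture is exercised at laptop scale.

Pretraining is masked-code prediction: 15% of group-token positions are
selected; of those 80% become `[MASK]`, 10% a uniformly random group
token, 10% stay unchanged — marginally 12% of codes masked and 1.5%
randomised. `[CLS]` and `[PAD]` are never selected. Pretraining pathways
keep their endpoint diagnostic code, so the relation between the final
diagnosis and the preceding codes is embedded.

Fine-tuning layers a logistic head on the final-layer `[CLS]` state
(`sigmoid(C·W + b)`; the bias is a calibration aid and can be disabled
for the strict form) and jointly trains all parameters under binary
cross-entropy, after stripping lung and other-cancer diagnostic codes
from the inputs so the label cannot be read off the sequence. Because
fine-tuning is unstable at small scale, several random restarts differing
in data order and head initialisation are run and the restart with the
best evaluation-set AUROC is kept.

All forward and backward passes are implemented twice: a base-R
reference in matrix algebra with analytically derived gradients, and a
compiled (RcppArmadillo) fast path that stacks each training batch so
projections and feed-forward blocks run as single large matrix products
(its GELU computes tanh through the exponential identity, which is
substantially faster at identical double precision). The two paths agree
to ~1e-14 and are verified against finite differences to 1e-4 relative
error in the test-suite; the R path also serves attention-map
extraction. Optimisation is Adam with 10%
linear warm-up. Reference learning rates at study scale are 1e-4
(pretrain) and 2e-5 (fine-tune); the desk preset trains with 1e-3, the
usual scaling when a model is several orders of magnitude smaller.

## The comparator

The bag-of-codes comparator destroys order information by construction:
each pathway becomes a vector of per-group occurrence counts (a binary
presence option exists), fed to an L2-penalised logistic regression with
the penalty chosen by 5-fold cross-validation. Sequence model and
comparator are always trained and evaluated on identical patients, and
their AUROCs compared with DeLong's test for correlated curves.

## Evaluation stack

The decision rule is `score >= threshold`, default threshold 0.4 —
documented as the operating point meeting the NICE fast-track convention
of accepting a positive predictive value of at least 3%. Reports cover
per-class precision/recall/F1, specificity, NPV and AUROC
(rank/Mann-Whitney estimator, ties at 1/2); confidence intervals are
patient-level nonparametric percentile bootstraps (1000 resamples by
default; resamples where a metric is undefined are redrawn and counted).
The threshold sweep grid is 0.40–0.70 in steps of 0.05. The
bias-sensitivity grid re-derives pathways, retrains and re-evaluates per
cell over lookback {12, 24, 36} months × trim {0, 1, 3} months, flagging
(36, 1) as the selected configuration; cells with too few cases are
flagged, never silently dropped. Subgroup reports (e.g. by sex and
ethnicity) are descriptive, with no multiplicity adjustment.

## Interpretability

The pathway embedding is the final-layer `[CLS]` hidden vector — the
same vector the classifier consumes. The attention profile of a pathway
is the final-layer `[CLS]` attention row averaged over heads, with
special-token positions dropped and the rest renormalised to 1 ("the
final layer" is the natural reading of the shared-layer architecture;
a `layer` argument allows overriding). Clustering is k-means with
restarts on the embeddings, never on the 2-D layout; embedding
dimensions are standardised before clustering (a few high-variance
directions unrelated to patient content otherwise dominate the
Euclidean metric and k-means splits along them), and the default k = 6
is made auditable by an inertia + silhouette scan over k = 2..10.
Cluster content is summarised by per-group prevalence (fraction of
member pathways containing the group) and mean attention mass. The 2-D
layout is an exact t-SNE (perplexity-calibrated Gaussian affinities,
Student-t low-dimensional kernel, momentum gradient descent, PCA
initialisation) implemented in-package and used for plotting only.

## The synthetic generator

The generator emulates the structural features of the study cohort:

* ~3-year event histories ending at an index date; no events after the
  index; one diagnostic anchor code at the index (lung for cases, other
  cancer / chronic respiratory / other chronic for the control strata,
  over-sampled per the study's composition 2932 : 2030 : 2279);
* a 450-group curated vocabulary reached through 3 raw codes per group,
  plus administrative noise that curation must remove;
* a target mean of 170 curated codes per pathway, drawn from a
  homogeneous background process over the window;
* latent patient subgroups with distinct background code profiles
  (8 anchor groups at 20× weight by default);
* ordered progression motifs planted in case pathways: each motif
  instance draws its month from a hazard profile rising toward the index
  (exponential decay, 4-month scale by default, ~2 instances per case)
  and lays its tokens down in motif order.

Two signal regimes matter for what the models can learn. In
`marginal_shift` (default), only cases receive motifs, so case/control
code *frequencies* differ and both model families can learn. In
`order_only`, every control receives the exact window token multiset of
a case of the same subgroup, re-dated uniformly over its own window:
marginal code frequencies are then identical by construction — a
bag-of-codes model is blind by design, honest cross-validated AUROC ~0.5
— while the planted signal (motif tokens concentrated late and in
order) remains available to a sequence model. This isolates the central
qualitative claim: temporal structure carries predictive information
beyond code frequencies.

What the generator does **not** emulate: real Read-code content and
hierarchy, realistic demographics, coding-practice artefacts,
informative missingness, inter-practice variation. Passing tests on
synthetic cohorts therefore demonstrates that the machinery works and
that the models separate order signal from frequency signal — not that
any particular clinical performance level would be attained on real
records.

## Numerical and scale choices

* Layer-norm epsilon 1e-12; BERT-family N(0, 0.02²) initialisation;
  classifier weights start at 0 so a fresh model scores 0.5.
* Attention masks give padded keys zero mass, making outputs invariant
  to padding length (asserted to 1e-9 in tests).
* The test-suite and the bundled configurations run the desk preset on
  cohorts of 600–3,000 patients with short training plans (1–2 epochs of
  masked-code pretraining, 4–6 fine-tuning epochs, 1–2 restarts, desk
  learning rate 1e-3); these sizes were chosen so the whole suite
  completes on a single CPU while every scientific property remains
  measurable.
  Study-scale plans (batch 2 / ~60 epochs pretraining; batch 8 / 4
  epochs fine-tuning; 5 restarts) are the documented defaults of
  `trainPlan()` and the pipeline configuration.
* All randomness is routed through named seeds derived from one run
  seed; identical configuration + seed reproduces byte-identical
  synthetic data and bit-identical model checkpoints.

## Known limitations

* At reduced scale, prolonged training — masked-code pretraining at
  desk learning rates as much as supervised fine-tuning — collapses the
  between-patient variance of the `[CLS]` embedding onto the
  task/frequency directions, erasing latent subgroup structure that a
  lightly pretrained encoder (one epoch at the reference pretraining
  rate) retains. The clustering demonstrations therefore use the lightly
  pretrained encoder; at study scale (hidden size 768, tens of epochs on
  >10^4 real pathways) a fine-tuned model can retain much richer
  structure, but that regime is not reproducible at desk scale.
* Static covariates (age, sex, smoking) enter subgroup reporting but are
  not model inputs, mirroring the sequence-only design.
* Time enters only through event *order* (position embeddings), not as
  inter-event durations.
* The exact t-SNE is O(n²) and intended for cohorts up to a few thousand
  pathways.
* Desk-scale training runs are short; they demonstrate direction and
  mechanism, not converged performance.
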