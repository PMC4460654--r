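---
title: "Classifying injury narratives by matrix factorization: models and design choices"
author: "narrafact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying injury narratives by matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narrafact)
```

## The problem

Emergency-department injury surveillance systems record, for each
presentation, a short free-text *narrative* ("fell off ladder cleaning
gutters, laceration to scalp") together with two coded fields assigned by
trained staff: the **external cause** (the event producing the injury:
fall, motor vehicle, cutting, ...) and the **major injury factor** (the
object or substance involved: furnishing, tool, chemical substance, ...).
Manual coding is slow and expensive; narrafact implements a pipeline that
learns to assign both codes from the narrative alone, built around latent
semantic representations of the document-term matrix.

The narratives are short (tens of tokens), noisy (misspellings, variant
abbreviations), high-dimensional and sparse as bags of words, and heavily
class-imbalanced — a couple of external-cause classes can account for ~70%
of presentations. The pipeline's stages respond to exactly these features.

## The preprocessing chain

`preprocessDocument()` applies, in a fixed order: lowercasing, punctuation
removal, tokenization, abbreviation canonicalization, phrase protection,
soundalike spelling correction, stop-word removal, Porter stemming. Two
ordering constraints matter:

* **Punctuation before stop words/stemming.** In "fall (from the high
  chair)", the token "(from" would escape a stop list; stripping
  punctuation to spaces first restores "from".
* **Phrase protection before stop-word removal.** "fall off" would lose
  "off" to the stop list and collapse into bare "fall", destroying the
  class signal; protected phrases become single underscore-joined tokens
  that the stop-word stage skips.

Spelling correction is self-contained: an unknown token is matched against
dictionary words sharing its Soundex key, and the candidate with the
smallest Levenshtein distance wins, subject to a distance bound
(`maxEditDistance`, default 2; ties break lexicographically, so the
corrector is deterministic and idempotent). Tokens on the stop-word list,
tokens containing digits, and protected phrase tokens are never
"corrected". Correction runs after abbreviation canonicalization so that
canonical abbreviations are not corrupted into dictionary look-alikes.
The Porter stemmer is implemented in full from the original algorithm
(no installed package provides one) and is tested against the algorithm's
published example outputs.

Design choices the source material left open: lowercasing is applied first
(stemming and dictionary lookup need a case convention); numerals are
retained (speeds such as "60 kph" carry signal).

## Vocabulary cutoff by a two-component mixture

Very rare terms (mostly typos and one-off words) are useless for
classification. `fitFrequencyMixture()` fits an equal-prior two-component
Gaussian mixture to the term frequencies by EM — E-step responsibilities
proportional to the component densities, M-step responsibility-weighted
mean and standard deviation — iterating until the componentwise parameter
change falls below `epsilon` (default 1e-6). Terms whose posterior favours
the low-mean component form the *infrequent* cluster and are dropped by
`reduceVocabulary()`.

Numerical choices:

* **Log scale.** Term-frequency histograms are extremely right-skewed; the
  fit is on ln(frequency) by default (`logScale = FALSE` restores raw
  counts), where the two-Gaussian model is sensible.
* **Weighted mean, not half of it.** The standard EM fixed point uses the
  responsibility-weighted mean; a variant with a leading 1/2 factor would
  halve a component's mean even when fitted to its own data and is
  inconsistent with the standard E-step and variance update, so the
  standard update is implemented.
* **Initialization** is deterministic (means at the 25th/75th frequency
  percentiles, pooled sd), so fits are reproducible without seeds; a
  sd floor of 1e-8 prevents collapse on duplicated values; fitting demands
  at least two distinct frequency values.
* **Frequent tail.** Both tails are in principle removable, but removing
  top-N frequent terms indiscriminately is known to hurt precision on
  injury narratives, where frequent terms ("fall") are class markers. The
  default removes only the infrequent cluster; a curated top-N list can be
  supplied explicitly and triggers a warning.

## Document-term matrices and weighting

`buildDtm()` produces a sparse docs-by-terms matrix under `binary`
(presence), `tf` (within-document count) or `tfidf`
(tf x ln(m/df)) weighting. On short narratives binary weighting tends to
work best — term repetition within a 12-token text carries little
information — and is the pipeline default. IDF statistics are fitted on
the training split and reused for test documents, one of several places
where the package is strict about fitting only on training data.

## Latent representations

**Truncated SVD** (`svdTruncate()`) gives the best rank-k approximation
D_k = U_k S_k V_k'. Test documents are projected through the training
basis: coordinates D_new V_k, smoothed representation D_new V_k V_k'
(`svdProject()`), which coincides with U_k S_k V_k' on the training matrix
because V_k has orthonormal columns. Each right singular vector's sign is
fixed (largest-magnitude entry positive) for reproducibility.

**NNMF** (`nnmfFit()`) factorizes D ~ AH with both factors non-negative,
by Lee-Seung multiplicative updates under squared Frobenius loss (default)
or generalized KL divergence. Topics combine additively, which suits text
better than orthogonal factors. The objective trace is recorded and must
be non-increasing — this is asserted in the tests. Initial factors are
absolute values of seeded Gaussian draws scaled to the data magnitude;
iteration stops when the relative objective change drops below `tol`
(default 1e-5) or at `maxIter` (500).

A subtlety decided here: factorizing the test matrix independently would
place test documents in an incomparable latent space (the factors of an
NNMF are not identified across runs). `nnmfTransform()` therefore fixes
H at the training value and solves only for the non-negative test
coordinates, so train/test cosine similarities are well-defined. Zero
documents map to exactly zero coordinates.

## Classifiers

*Memory-based* (`memoryClassify()`): cosine 1-nearest-neighbour in the
chosen representation. Ties break to the lowest training index; zero-norm
rows have similarity 0 to everything, and a zero-norm test document
receives the majority training class. Per-class scores (for ROC) are the
maximum similarity to any training document of the class; memory
classifiers produce similarities, not probabilities, and this is the
defensible score choice.

*Model-based* (`modelTrain()`/`modelPredict()`): a pluggable registry of
downstream families. The default is a multi-class max-margin classifier
with RBF kernel (one-vs-rest probability scores) via e1071; a `knn1`
family routes the traditional 1-NN baseline through the same contract, and
`registerClassifierFamily()` accepts further families (trees, boosting,
...) without any change to the pipeline.

*Learning enhancement* (`enhancedClassify()`): the two codes are
correlated (burns with hot objects, lacerations with sharp objects), so
when classifying one code the other is appended as p one-hot supplementary
features. Training always uses gold auxiliary labels. At prediction time
the auxiliary labels are either predicted by a stage-1 unaugmented
classifier (`auxSource = "predicted"`, the deployable default) or taken as
gold (`auxSource = "gold"`, the oracle upper bound). Which variant the
original experiments used is not documented; both are provided, and the
information ordering (gold at least as accurate as predicted on coupled
corpora) is part of the test suite.

## Evaluation battery

Designed for imbalanced medical data: per-class one-vs-rest sensitivity
TP/(TP+FN), specificity TN/(FP+TN) and PPV TP/(TP+FP) (0/0 cases are
reported as NA with a flag, never silently 0); overall accuracy;
Cohen's kappa K = (I_o - I_e)/(1 - I_e) with multiclass observed/expected
agreement that reduces exactly to the binary formulas for two classes; and
one-vs-rest ROC AUC by trapezoidal threshold sweep, equivalent to the
Mann-Whitney rank statistic under ties, macro-averaged over classes having
both positives and negatives (micro averaging is a deliberate non-default).
Kappa matters here because on a 70%-majority corpus a majority-class
predictor scores high accuracy but K near 0.

`crossValidate()` runs stratified k-fold CV (stratification is justified
by the documented imbalance; within each class, documents are dealt
round-robin after a seeded shuffle, so fold sizes differ by at most one).
Every learned component — vocabulary cutoff, IDF, factorization basis,
classifier — is refitted inside each training fold. A label-shuffle probe
(permuting held-out labels must leave fold-fitted artifacts bit-identical)
is part of the acceptance tests.

## The synthetic-corpus generator

Real surveillance data cannot be redistributed, so `generateCorpus()`
emulates its documented structure: ~20 external-cause classes with two
majors holding 70% of the mass and ~10 injury-factor classes with two
majors holding 50%; short documents (truncated geometric length, mean 12
tokens, maximum 40 — document "length" is standardized as whitespace
tokens); per-class signature vocabularies drawn from a packaged
injury-domain lexicon over a shared background; single-edit misspellings
and abbreviation variants at configurable rates, with full ground-truth
corruption records; and code-code coupling: each document draws its injury
class from the marginal and its external class from
gamma * onehot(map(injury)) + (1 - gamma) * base marginal, so gamma = 1 is
a deterministic injury-to-external map and gamma = 0 independence. The
default gamma = 0.6 reflects the moderate-to-strong association observed
between real code pairs. Under strong coupling the external marginal is
necessarily pulled toward the injury-induced one; checks of the 70% skew
target therefore run at gamma = 0, where the stated multinomial is
sampled directly.

What the generator does *not* emulate: grammar, negation, clinical
abbreviation ambiguity, multi-cause narratives, coder disagreement.
Passing tests on synthetic corpora validate the machinery — not clinical
performance on real narratives.

## Experiment designs and problem sizes

Two canned experiments back the package's headline property checks; their
conditions were fixed at design time and are deliberately desk-scale so
the whole suite runs in minutes on one core.

**Enhancement contrast** (`enhancementExperiment()`): 300 documents (200
train / 100 test) per replicate, mean length 16 tokens, binary weighting,
RBF-SVM, target external cause, auxiliary injury factor, gold
augmentation, 10 replicate seeds. Gold augmentation is used because under
a deterministic gamma = 1 coupling the external task is a relabeling of
the injury task, so a stage-1 *predicted* auxiliary label adds no
information beyond the shared features — empirically the two routes give
identical predictions — whereas the design question ("does knowing one
code help predict the other?") is about the value of the code itself. The
narrative length matters at the other end: with very short documents the
p irrelevant dummy columns measurably distort RBF distances at gamma = 0,
biasing the null contrast negative; at mean length 16 the null contrast
centres on zero, which is the behaviour a correct implementation should
show.

**Planted-rank sweep** (`plantedRankSweep()`): 100-document corpora with
five equiprobable classes, each with a saturated 4-word signature (long
enough documents that effectively every document contains its full
signature, making the expected document-term matrix exactly rank 5), a
60-word background, *no* misspellings (misspelled signature tokens are
class-correlated and would leak signal into extra dimensions), tf
weighting, SVD + SVM, 5-fold CV, accuracy averaged over 5 replicate
corpora. Cross-validated accuracy rises from k = 2 (five classes cannot
separate in two dimensions) to k = 5 and falls at k = 10, where the extra
dimensions carry only background noise.

## Known limitations

* The spelling corrector handles single-token, edit-distance-bounded
  errors; run-together words and context-dependent errors are out of
  scope, as are statistical error models.
* NNMF multiplicative updates converge to local optima; different seeds
  give different (equally valid) factorizations. Same-seed runs are
  bit-reproducible.
* Kappa and AUC are reported per run; no confidence intervals or paired
  significance tests between classifier families are provided.
* The generator's class structure is far cleaner than real triage text;
  absolute accuracies on synthetic corpora say nothing about accuracies
  on real data.
```{r session}
sessionInfo()
```
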