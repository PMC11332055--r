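---
title: "Words versus rating scales: methods behind qcla"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Words versus rating scales: methods behind qcla}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Standardized rating scales (PHQ-9 for depression, GAD-7 for anxiety, SWLS
for life satisfaction, HILS for harmony in life) are the default way to
quantify emotional states, but the four instruments are strongly correlated
within valence: a rater scoring a depression narrative tends to give high
scores on *both* the depression and the anxiety scale. An alternative is a
single open-ended question answered with five descriptive words, quantified
as word embeddings. `qcla` implements the full evaluation pipeline for
comparing the two measurement routes on a common, scale-independent
criterion: which emotion (harmony, satisfaction, depression, or anxiety) a
narrative was written about. The study design it emulates has two phases -
authors who write a narrative about a self-experienced emotional episode
(Phase 1) and readers who evaluate those narratives (Phase 2), each
narrative being read once or twice.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic experiments do and do not show.

## The synthetic-data generator

Real study data live in an external repository and real embeddings require
a pretrained encoder, so every stage here is exercised on synthetic data
whose *statistical structure* matches what the analysis assumes. The
generator (`generator_config()` + `generate_dataset()`) emulates:

* **Four equally frequent emotions.** Phase-1 labels are balanced to
  within one record; defaults are 297 authors and 434 readers, the final
  sample sizes of the emulated study.
* **Emotion lexicons with controllable overlap.** Each emotion owns a
  lexicon (default 40 words) seeded with emotion-indicative English words
  (*sad*, *anxious*, *calm*, *hopeful*, ...) and padded with synthetic
  tokens. A `lexicon_overlap` fraction (default 0.2) of each lexicon is
  shared within the two confusable pairs (depression/anxiety,
  satisfaction/harmony) - mirroring words like *happy* that indicate more
  than one state - and never across valences. Responses draw five words
  without replacement; each word is off-lexicon with probability
  `word_noise` (default 0.2).
* **Correlated rating scales.** Item scores come from a latent-Gaussian
  copula: a 4-vector of latent scale scores with correlation matrix
  `scale_corr` (defaults: 0.85 between the PHQ-9 and GAD-7 latents, 0.80
  between SWLS and HILS, -0.60 across valences) is perturbed per item with
  noise (`item_noise_sd = 0.3` latent SD), linearly mapped into item units,
  rounded and clipped to each instrument's legal range. Because per-item
  noise and discretization error largely average out over a scale's items,
  the empirical correlation matrix of the *totals* converges to
  `scale_corr` (the suite checks max deviation < 0.05 at n = 5,000 for
  mid-range profiles). When a profile sits near a scale's floor - minimal
  PHQ-9 scores for satisfaction narratives, say - censoring attenuates the
  affected correlations by a few hundredths more, exactly as bounded
  instruments do on real data.
* **Confusable mean profiles.** The per-emotion target totals
  (`default_scale_mean_profile()`) put depression narratives at
  PHQ-9 ≈ 17, GAD-7 ≈ 13 and anxiety narratives at PHQ-9 ≈ 15,
  GAD-7 ≈ 14: high on *both* negative scales, like real raters. The
  negative pair's profiles are deliberately closer than the positive
  pair's, so the rating-scale classifier's dominant error is
  depression-versus-anxiety - the error structure the comparison is about.
* **Phase-2 pairing.** Every narrative is read at least once; the
  `n_phase2 - n_phase1` second reads are assigned at random, and a
  configurable fraction (default 34/434) of readers is flagged
  "professional".

Choices the generator does **not** model: narrative text bodies,
demographics, response styles (acquiescence, central tendency), and
participant-level correlation between word choice and scale scores beyond
what the shared emotion label induces. Consequently, passing synthetic
recovery says the *pipeline* recovers planted structure at realistic sizes
and noise levels; it says nothing about how accurate real raters or real
embeddings are.

All randomness flows from one master seed; each stage (labels, pairing,
roles, words, scales) draws from its own derived stream, so a change in one
stage leaves the others' draws untouched.

## The mock encoder

`mock_encoder()` maps a token to a deterministic pseudo-random unit vector
(seeded by a hash of the token) plus, for lexicon members, a class
component: the mean of orthonormal per-emotion directions of the emotions
owning the token, scaled by `class_weight` (default 1; token noise weight
0.4). Responses are encoded as the unweighted mean of their word vectors -
the convention adopted because the emulated analysis does not state whether
words were encoded jointly, and mean pooling keeps the geometry analyzable.
With disjoint lexicons and zero word noise the classes are linearly
separable by construction; a shared token carries *both* owners' directions,
which is why the separability ceiling is only guaranteed for
`lexicon_overlap = 0`. The default embedding width is 768, matching the
pretrained uncased transformer the design is a stand-in for; real
embeddings can be served offline from a token-vector TSV via
`tsv_encoder()`.

No vector is length-normalized before classification; unit normalization
happens only inside the semantic t-test, where the method specifies it.

## Cleaning

`clean_records()` reproduces a deterministic version of the manual
procedure: lowercase and trim; reject multi-token entries (single words
were enforced at collection); drop "n/a"/"na" placeholders; collapse
*successively* repeated words (adjacent duplicates only - the literal
reading; non-adjacent repeats are retained); drop records that failed the
embedded control questions, or that end with no surviving word. The
spelling pass is off by default because the original was human-in-the-loop;
when enabled it replaces a word only on a unique edit-distance-1 dictionary
match, otherwise the original form is retained. Cleaning is idempotent and
its report balances input = retained + dropped exactly.
`forbid_target_word()` flags (never deletes) Phase-1 uses of the
condition's own name; Phase-2 raters did not know the condition, so their
records are never flagged.

## Classification

The categorization model is multinomial logistic regression evaluated by
narrative-grouped 10-fold cross-validation: fold assignment is constrained
so that the one-or-two evaluations of a narrative always share a fold -
otherwise a narrative rated by two readers could sit in both train and
test, and the suite asserts this never happens rather than assuming it.

Within each outer fold:

1. **Compression.** An SVD is fitted on the training rows only (no column
   centering by default; a `center` switch exists) and both splits are
   projected onto its leading right singular vectors.
2. **Dimension selection.** The number of leading dimensions is chosen
   from the fixed ladder 1, 2, 3, 5, 7, 10, 14, 19, 26, 35, 46, 61, 80,
   105, 137, 179, 234, 305, 397, 517, 768 (truncated at the feature count,
   which is appended - so scale totals use 1-4) by a 5-fold grouped
   cross-validation *inside* the training partition, minimizing
   miscategorizations with ties broken toward the smaller count. Inner
   validation, not training error, is used because training error is
   non-increasing in the dimension count and would always saturate the
   ladder. The inner folds reuse the outer-training SVD: the compressor is
   unsupervised and fitted entirely on training rows, so refitting it per
   inner fold would change nothing about test-set hygiene while costing
   fifty more large decompositions per run.
3. **Fit and predict.** A full-softmax multinomial model with a tiny ridge
   (1e-6, for identifiability and stability on separable data) is fitted
   by L-BFGS on the exact penalized likelihood, warm-started along the
   ladder; features are standardized internally for conditioning (a pure
   reparameterization at this penalty). The held-out 10% is predicted;
   argmax ties break by the fixed class order harmony, satisfaction,
   depression, anxiety.

Every record thus receives exactly one prediction from a model that never
saw its narrative, and `percent_correct = 100 * correct / n`.
`regress_scale_scores()` applies the same protocol with multiple linear
regression (closed-form ridge least squares, squared-error inner
criterion) to predict the four continuous totals, supplying the word-based
predictions used in the matched-correlation comparison.

The four feature sets are `words` (768 embedding columns), `scales` (4
totals - also SVD-compressed, to keep the routes comparable), `combined`
(768 + 4), and `items` (all 26 individual items).

## The semantic t-test

To score individual words without fitting a classifier, each emotion's word
occurrences are summed into a unit aggregate vector and contrasted with the
complement's aggregate through a unit-normalized difference vector; a
word's similarity is the dot product of its unit embedding with that
difference direction (the cosine). A 10-fold leave-out scheme keeps the
measured word out of its own yardstick: occurrences are split into ten
folds and, for each fold, the measured word's occurrences in that fold are
removed from both aggregates before its similarities are computed. A
one-sample, one-sided t-test (is the mean similarity > 0?) is Bonferroni
corrected over the number of unique words tested per contrast. The test's
sampling unit is the word *occurrence* (a word contributes once per use),
the reading adopted where the procedure is ambiguous. Zero-variance
similarity sets take the t = ±Inf convention with p ∈ {0, 1}; singletons
are reported with missing statistics and never surface in clouds.
`top_words()` keeps at most 25 Bonferroni-significant words per emotion,
sorted by t, with occurrence frequency as the cloud weight; a word may
appear in several emotions' clouds. Both phases' words are pooled by
default.

## Comparative statistics

* **Two-proportion chi-square.** The emulated reports compare percentages
  on equal groups; the closed form
  `chi2 = N (p1 - p2)^2 / (4 p̄ (1 - p̄))` with `p̄ = (p1 + p2)/2` on 1 df
  equals the cell-wise Pearson chi-square of the corresponding 2x2 table
  whenever the implied counts are integral (property-tested over all
  margins up to 30). No continuity correction. Effect size
  `phi = sqrt(chi2 / N)`; its confidence interval is a seeded 2,000-draw
  binomial bootstrap percentile interval of the *signed* phi, since the
  reported intervals straddle zero for null effects and no interval method
  is stated in the source material.
* **Accuracy / precision.** Per class: accuracy `(TP + TN) / total`,
  precision `TP / (TP + FP)`, as percentages; precision is reported
  missing (not zero) for a never-predicted class.
* **Inter-rater agreement.** Over all unordered pairs of categorizations
  of the same narrative: percentage identical, and percentage identical
  *and* correct.
* **Coefficient correlations.** Pearson correlations between the four
  classes' multinomial coefficient vectors (high absolute values indicate
  a model that cannot tell the classes apart), with Fisher-z 95% CIs.
* **Matched correlations.** Phase-1 versus Phase-2 scale scores, and
  Phase-1 scale scores versus Phase-2 word-based predictions, matched on
  narrative; the two correlations are compared two-sided with
  `z = (atanh r2 - atanh r1) / sqrt(2 / (n - 3))`.

## Problem sizes and degenerate inputs

The packaged experiments use the emulated study's own sizes: 297 + 434 =
731 records for the recovery run, 400 records for the label-permutation
chance control, 180 for the noise-free separability ceiling, and n = 5,000
draws for copula-fidelity checks. Degenerate cases are defined, not
patched: a pooled proportion of 0 or 1 is a refusal in the chi-square; an
all-zero matrix is a refusal in the SVD; identical aggregates make the
difference vector an error; a constant regression target warns that
downstream correlations are undefined; fewer unique narratives than folds
is an error.

## Known limitations

* The mock encoder's class geometry is far cleaner than real embeddings;
  synthetic words-route accuracies (≈ 94% at default noise) are therefore
  optimistic relative to the ≈ 64% reported for real data, and only the
  *ordering and error structure* of the routes - words above scales, with
  rating-scale errors concentrated in the depression/anxiety block - is
  the claim under test.
* The latent inter-scale correlations are plausible rather than
  calibrated; the emulated study does not report its empirical values.
* One printed statistic in the source material (the anxiety contrast,
  chi-square 45.63 with a 0% cell) is not reproduced by the adopted closed
  form (which gives ≈ 49.25); its exact construction is unknown and the
  phi relation is verified against it instead.
* `matched_correlations()` uses the independent-samples r-to-z contrast on
  what are dependent correlations (both involve Phase 1), matching the
  emulated analysis rather than a dependent-correlation test.
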