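---
title: "Weakly supervised symptom extraction: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised symptom extraction: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Progress notes describe symptoms in free text, but supervised note
classifiers need labels, and manual annotation of clinical text is slow,
expensive, and restricted by privacy. `symptomweak` implements two
programmatic labeling strategies for the ten ICD-10 symptom categories
R00–R09 (symptoms and signs of the circulatory and respiratory systems)
and the machinery to measure what classifiers trained on such
pseudolabels can and cannot do:

* **ICD pseudolabels.** An encounter's diagnosis codes are truncated to
  their three-character category; a note is labeled positive for a
  category iff its own encounter carries a matching code. The key
  asymmetry: symptom codes are entered rarely, so a present code is good
  evidence for the symptom but an absent code says almost nothing.
  Operationally this is a low-sensitivity, high-specificity label
  channel.
* **Weak labels.** A rule system reads the note text itself: dictionary
  mention detection, a 20-token context window (10 tokens before and 10
  after the mention), three trigger-lexicon labeling functions
  (negation, history, family/experiencer), a resolution rule, and
  any-positive aggregation to the note level. Much higher sensitivity
  than the codes, at the cost of lexicon-dependent noise.
* **Hybrid labels** give every note exactly one source: encounter-coded
  notes keep their ICD vector, all others take their weak vector.

Downstream, one-vs-all classifiers (L2-penalized logistic regression
fitted by L-BFGS, or a 100-tree random forest) are trained per category
on one of four document representations: bag-of-words counts, TF-IDF,
averaged word embeddings (CBOW), or PV-DBOW paragraph vectors.

# Preprocessing

Notes are lowercased; digits, punctuation and all other non-alphabetic
characters are removed; the text is whitespace-tokenized; stop words are
removed **except** the negation attributes `no` and `not` (they carry
the signal the negation labeling function needs); tokens are Porter-
stemmed. There is no sentence segmentation and no sectioning — the
whole note is one token stream, consumed identically by the weak
labeler and by featurization.

Two details are worth stating plainly:

* **Numbers are removed before tokenization**, so `"2/2"` disappears
  entirely rather than leaving fragments.
* **Porter stemming is not idempotent.** The classic single-pass
  algorithm maps `agreed → agre` but `agre → agr`, and stacked suffixes
  (`…itiation`) lose one layer per pass. This is why lexicons here are
  stored as natural surface forms and stemmed *once at load time* by the
  same pipeline the notes go through: pre-stemmed lexicon files would
  silently drift out of the once-stemmed token space. The test suite
  asserts the properties that actually hold: stems never grow, at least
  99.9% of generator-style vocabulary is a fixed point, and iteration
  converges after a second pass.

# The weak labeling chain

1. **Mention detection** is a dictionary matcher: longest n-gram first,
   left to right, non-overlapping. The packaged concept dictionary
   (`inst/extdata/concept_dictionary_synthetic.csv`) is a small
   synthetic stand-in authored for this package — it is *not* a UMLS
   extract — and is meant to be replaced by a site dictionary for real
   data. The detector is pluggable: any function emitting
   (note, span, concept, category) rows can replace it, so a learned
   NER model can slot in without touching the rest of the chain.
   A fuzzy mapper (`map_to_category()`) resolves non-exact surfaces by
   token-set Jaccard similarity, ties broken toward the
   lexicographically smallest concept id.
2. **Context windows** are 10 stemmed tokens on each side of the
   mention, clipped at note boundaries, never crossing notes, ignoring
   sentence structure. Windows are computed on the preprocessed stream;
   trigger phrases are normalized the same way, so matching is exact.
3. **Labeling functions.** Negation, historical and family trigger sets
   ship as editable one-phrase-per-line files seeded with standard
   clinical cue words (`no`, `denies`, `without`, `history of`,
   `father`, …). Each LF fires iff one of its phrases occurs in the
   window, recording the distance to the nearest firing occurrence.
4. **Resolution.** No fire → `positive`. One fire → that label
   (`absent` / `history` / `family`). Several → the nearest trigger
   wins; distance ties resolve by the precedence
   absent > history > family. The precedence is this package's rule
   (conservative: prefer suppressing a mention over asserting it); the
   multi-trigger case is otherwise underdetermined.
5. **Aggregation.** A note is positive for a category iff at least one
   of its mentions resolved positive; negated, historical and family
   mentions count as non-evidence, matching the definition that a
   positive label means current, patient-experienced, non-negated.

The deterministic rule system *is* the default labeler. For settings
with many, partially conflicting labeling functions, `fit_label_model()`
offers a generative combiner: a latent per-mention state (positive vs
modified) with prior `class_prior`, conditionally independent LFs, and
a per-LF accuracy `a_j` (an LF fires on a modified mention with
probability `a_j`, on a positive one with probability `1 - a_j`).
Accuracies are estimated by EM with the prior held fixed; the
log-likelihood is non-decreasing by construction and rows where every
LF abstained are assigned the prior (abstention is treated as
uninformative by contract, not inferred from the model). A labeling
function that never fires has no estimable accuracy and is reported
`NA` with a warning.

# Featurization

* **BOW / TF-IDF** use a train-fitted vocabulary (lexicographic order,
  document-frequency floor `min_df = 2` by default). TF-IDF uses the
  smooth convention `idf(t) = ln((1+N)/(1+df(t))) + 1` followed by L2
  row normalization — the dominant convention, adopted because no
  variant is otherwise pinned down. Test documents are weighted with
  training-corpus statistics.
* **CBOW document vectors** are unweighted means over token occurrences
  (duplicates counted) of word vectors; out-of-table tokens are
  skipped, and an all-OOV document is the zero vector. The word table
  can be any pretrained matrix in the standard text format
  (`read_embeddings()`), or trained locally with
  `train_word_embeddings()` (dimension 200 by default).
* **PV-DBOW paragraph vectors** (dimension 300 by default, independent
  of corpus size) are trained by single-threaded negative-sampling SGD
  (5 negatives, initial learning rate 0.025 with linear decay, unigram^0.75
  sampling table). Identical seeds give bitwise-identical vectors — the
  price is that training never parallelizes. New documents are inferred
  by freezing the word output vectors and optimizing a fresh document
  vector. The SGD kernel is compiled C++; both trainers live behind the
  same interface as the other featurizers.

# Classification and evaluation

One binary probabilistic classifier per category. Logistic regression
minimizes the summed binomial deviance plus an L2 penalty
(`lambda = 1`, intercept unpenalized — the common library default,
recorded in model metadata) with L-BFGS, `max_iter = 1000`;
non-convergence is reported, not fatal. Hard labels use threshold 0.5
(a score equal to the threshold predicts positive). No class
rebalancing is performed: the design premise is that scale, not
resampling, compensates for imbalance. Categories with a single
training class are skipped with a warning and predict a constant 0.

`compute_metrics()` reports per-category and macro recall, precision,
F1, average precision (threshold-sum PR integral, invariant under
monotone score transforms) and AUROC (rank statistic, ties count one
half), plus ROC/PR point lists. Categories without both classes in the
test set are excluded from macro averages and listed explicitly rather
than imputed. `score_delta()` subtracts two reports on the same test
set; `mentions_to_note_label()` majority-votes mention-level
annotations into note labels for external-validation style evaluation —
a note is positive only if positive mentions strictly outnumber
negative *and uncertain* ones together (uncertain counts against
positivity, and ties go negative; both are deliberate conservative
choices).

# The synthetic corpus

Real encounter data with known per-note symptom truth cannot be
shipped, so the generator builds corpora whose every property the
pipeline assumes is planted by construction:

* Filler text is drawn from a 2,000-word pseudo-clinical vocabulary
  with Zipfian frequencies (so TF-IDF and embeddings see realistic
  skew), constructed to be disjoint — also after stemming — from stop
  words, trigger phrases and dictionary surfaces.
* Per note and category, a mention group appears at the rate implied by
  the configured prevalence; each mention renders a dictionary surface
  inside a context template (trigger-free reporting phrase for
  positive; a negation/history/family trigger within the 10-token
  window otherwise). A category is *truly* positive iff at least one
  mention is in positive context, which makes the empirical prevalence
  an exact Bernoulli draw at the configured rate. Default context mix:
  0.60 positive, 0.25 negated, 0.10 historical, 0.05 family.
* Mention groups are separated by at least 12 filler tokens, so one
  mention's trigger can never invade another's window. With matched
  lexicons and `paraphrase_rate = 0` the weak labeler therefore
  recovers the truth essentially exactly — the perfect-oracle regime
  used to validate the chain end to end.
* With probability `paraphrase_rate` (default 0.1) a surface is
  replaced by an out-of-dictionary synonym, creating the realistic
  failure mode of dictionary labelers (missed mentions).
* Encounter codes are the truth passed through a noisy channel:
  a truly positive cell emits its code with probability
  `coding_sensitivity` (default 0.4), a negative cell with
  `1 - coding_specificity` (default 0.01), plus non-R distractor codes.
  Defaults encode the under-coding premise: codes are scarce and
  incomplete, never anti-informative.
* Notes are 80–160 tokens (comfortably above the 350-character cohort
  filter), grouped 1–3 per patient; everything is byte-deterministic
  given the config seed.

What the generator does **not** emulate: real clinical prose (syntax,
abbreviations, misspellings, section headers), mention-level ambiguity,
cross-sentence phenomena, and lexicon incompleteness beyond the single
paraphrase mechanism. Passing the synthetic checks therefore validates
the *mechanics* of the pipeline and the *direction* of the label-noise
effects, not clinical-grade extraction accuracy; results on real data
remain lexicon-relative.

# Experiment designs

Two standing experiments ship with the package and are re-run by
`scripts/acceptance.R` and the test suite.

**Label-source comparison** (`compare_label_sources()`): one 20,000-note
corpus (categories R05/R06/R07 at prevalence 0.10/0.05/0.02, coding
sensitivity 0.4/specificity 0.99, paraphrase rate 0.1), patient-split
60:20:20, TF-IDF features, logistic regression trained separately on
ICD, weak, and hybrid labels, evaluated against ground truth on the
test partition. The expected direction — substantially higher macro
recall for weak- and hybrid-trained models than for ICD-trained ones —
follows from the sensitivity gap between the two label channels (≈0.9
vs 0.4), and the experiment confirms it with a wide margin.

**Prevalence–recall scaling** (`size_scaling_experiment()`): nested
subsets of 1,000 / 5,000 / 20,000 notes, PV-DBOW features, weak-label
training, and per-category recall versus log-prevalence summarized by a
least-squares slope per size. This is a *controlled* experiment, and
two design choices matter:

* Each of the five categories is rendered with exactly **one two-token
  surface form** (`surface_bank` option of the generator). Development
  showed that with the full heterogeneous dictionary, per-category
  recall is dominated by mention footprint — a three-token surface is
  learnable at 1.7% prevalence while a one-token surface may not be at
  4% — which confounds the prevalence axis the experiment is about.
  Homogenizing the footprint makes prevalence the only factor that
  varies across categories.
* The model configuration is **identical at every size** (dimension
  300, 20 epochs, same seed policy), so training-set size is the only
  factor that varies across sizes. Twenty epochs sits where the
  smallest corpus yields a trained-but-data-limited model; far fewer
  epochs leave the 1,000-note model degenerate (all-zero recall, slope
  meaninglessly flat), far more let even the smallest corpus saturate.

Under this design the absolute slope collapses as the corpus grows
(roughly 0.5 → 0.05 → 0.02 across the three sizes), i.e. low-prevalence
symptoms stop being penalized once training is large enough — the
scaling behavior the pseudolabeling strategy relies on. Problem sizes
were chosen so the full suite trains dozens of models in minutes on one
core; they are stated here as the package's standing experiment
configuration.

# Numerical and degenerate-input choices

* Largest-remainder patient splitting: floor each partition share, hand
  leftover slots to the largest fractional remainders, ties toward the
  *later* partition — 717 patients at 60:20:20 gives 430/143/144.
* EM: accuracies initialized just above 0.7 (with a small seeded
  jitter) to break the label-swap symmetry; probabilities clamped away
  from 0/1; stopping at log-likelihood improvement `< 1e-8` or 200
  iterations.
* TF-IDF: all-zero rows stay all-zero (no division blow-up).
* Thresholding: `score >= threshold` predicts positive.
* Empty corpora, empty dictionaries, all-OOV documents, encounters
  without codes, and notes with unresolvable encounters (dropped with a
  warning by default — EHR extracts routinely contain orphans) all have
  defined, tested behavior.

# Known limitations

* The mention detector is lexicon-bound; recall on real text is a
  property of the dictionary, not of the package. The pluggable
  detector interface is the intended escape hatch.
* The weak labeler has no uncertainty class at mention level, no
  cross-sentence coreference, and windows count preprocessed tokens
  (raw-token distances may differ after stop-word removal).
* PV-DBOW/CBOW training is single-threaded by design (bitwise
  reproducibility); corpora far beyond 10^5 notes would need to
  relax this.
* Hybrid assembly trusts encounter coding wherever a target-category
  code exists; a site with *anti*-informative coding would violate the
  premise baked into that rule.
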