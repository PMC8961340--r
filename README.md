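# symptomweak

Training a clinical-note symptom classifier normally requires labels
nobody has: chart review is slow, and de-identified annotated corpora
are small and access-controlled. `symptomweak` implements and evaluates
two programmatic alternatives for the ten ICD-10 symptom categories
R00–R09 (symptoms and signs involving the circulatory and respiratory
systems — e.g. R05 cough, R06 abnormalities of breathing, R07 pain in
throat and chest):

1. **ICD pseudolabels** — truncate an encounter's diagnosis codes to
   their 3-character category and mark the note positive for every
   category coded on its own encounter. Since symptom codes are entered
   only sporadically, this channel has high specificity but low
   sensitivity: `y_icd ~ truth` with `P(code | symptom) ≈ 0.4`,
   `P(code | no symptom) ≈ 0.01` in the package's reference conditions.
2. **Weak supervision** — label the text directly: dictionary mention
   detection, a 20-token context window (±10 tokens), three
   trigger-lexicon labeling functions (negation, history,
   family/experiencer), nearest-trigger resolution with precedence
   absent > history > family, and any-positive aggregation per note.
   A conditionally-independent-accuracy label model fitted by EM
   (`fit_label_model()`) is available for combining many labeling
   functions.

Downstream, **one-vs-all** classifiers — L2-penalized logistic
regression fitted with L-BFGS, or random forests (100 trees) — are
trained per category on bag-of-words, TF-IDF
(`idf(t) = ln((1+N)/(1+df_t)) + 1`, L2-normalized rows), averaged word
embeddings (CBOW, 200-d), or PV-DBOW paragraph vectors (300-d,
corpus-size independent), and scored with recall, F1, average
precision, AUROC and full ROC/PR curves. A seeded synthetic-EHR
generator with known per-note ground truth makes every stage testable
without protected data, including the two standing experiments: the
weak-vs-ICD training comparison and the prevalence–recall flattening
analysis.

Intended users: clinical NLP and biomedical informatics researchers who
want to prototype pseudolabeling strategies, and anyone needing a
fully-seeded benchmark of label-noise effects on multi-label text
classifiers.

## Worked example

Generate a 20,000-note synthetic cohort (three symptom classes at 2–10%
prevalence, encounter coding sensitivity 0.4 / specificity 0.99, 10% of
mentions paraphrased out of the dictionary), then train logistic
regression on TF-IDF features twice — once on ICD pseudolabels, once on
weak labels — and evaluate both against ground truth on the held-out
patients:

```r
library(symptomweak)

sim <- generate_corpus(generator_config(
  n_patients = 20000, notes_per_patient = c(1, 1),
  categories = c("R05", "R06", "R07"),
  prevalence = c(R05 = 0.10, R06 = 0.05, R07 = 0.02),
  coding_sensitivity = 0.4, coding_specificity = 0.99,
  paraphrase_rate = 0.1, seed = 42))

exp <- compare_label_sources(sim, feature = "tfidf",
                             train_sources = c("icd", "weak"),
                             test_labels = "truth",
                             split_seed = 1, seed = 1)
exp$reports$icd$truth
exp$reports$weak$truth
score_delta(exp$reports$weak$truth, exp$reports$icd$truth)
```

```
<metrics_report> vs truth labels
 category prevalence recall precision    f1 average_precision auroc
      R05      0.110  0.075         1 0.139             0.949 0.994
      R06      0.059  0.009         1 0.017             0.932 0.996
      R07      0.020  0.024         1 0.048             0.880 0.995
macro: recall=0.036 precision=1.000 f1=0.068 average_precision=0.920 auroc=0.995
<metrics_report> vs truth labels
 category prevalence recall precision    f1 average_precision auroc
      R05      0.110  0.707     0.951 0.811             0.961 0.996
      R06      0.059  0.532     0.962 0.685             0.938 0.997
      R07      0.020  0.427     0.921 0.583             0.886 0.997
macro: recall=0.555 precision=0.945 f1=0.693 average_precision=0.928 auroc=0.997
<delta_report> (a - b)
 category recall precision    f1 average_precision auroc
      R05  0.633    -0.049 0.672             0.012 0.001
      R06  0.523    -0.038 0.668             0.005 0.001
      R07  0.402    -0.079 0.536             0.005 0.002
macro: recall=+0.519 precision=-0.055 f1=+0.625 average_precision=+0.008 auroc=+0.002
```

Reading it: both models rank notes almost perfectly (AUROC ≈ 0.995),
but the ICD-trained model, starved of positive labels (sensitivity
0.4), almost never crosses the 0.5 decision threshold — macro recall
0.036. Training on weak labels lifts macro recall to 0.555 (+0.52) at a
modest precision cost: the central trade-off of pseudolabeling, in one
table.

The staged file-based pipeline (simulate → filter → split → label-icd →
label-weak → featurize → train → evaluate → report, with a YAML config
and an md5 manifest) is available through `run_pipeline()` or the thin
CLI at `inst/cli/symptomweak`.

## Package layout

| Where | What |
|---|---|
| `R/corpus.R` | note/encounter containers, cohort filter (≥350 chars, R-coded encounters), patient-level 60:20:20 splits, CSV I/O |
| `R/preprocess.R`, `R/porter.R` | normalization and Porter stemming |
| `R/icd_labeling.R` | code truncation and ICD label vectors |
| `R/terminology.R`, `R/weak_labeling.R`, `R/label_model.R` | lexicons, mention detection, context windows, labeling functions, EM label model |
| `R/featurization.R`, `R/embeddings_train.R`, `src/embeddings.cpp` | BOW/TF-IDF, embedding tables, CBOW and PV-DBOW trainers |
| `R/classification.R` | label assembly (icd/weak/hybrid), one-vs-all training, prediction |
| `R/evaluation.R` | metric battery, deltas, prevalence profiles, standoff/BRAT readers, majority voting |
| `R/synthetic.R` | the corpus generator and coding-noise model |
| `R/pipeline.R`, `R/stages.R` | experiments, staged runner, manifest |
| `vignettes/symptomweak-methods.Rmd` | models, assumptions, design choices, limitations |

The packaged concept dictionary
(`inst/extdata/concept_dictionary_synthetic.csv`) is a synthetic mini
stand-in authored for this package, not a UMLS extract; the trigger
lexicons are editable seed lists of standard clinical cue phrases. Both
are configuration, meant to be replaced for production use.
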