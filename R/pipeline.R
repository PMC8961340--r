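#' Featurize train and test token streams with one method
#'
#' Fits the featurizer on the training stream only (vocabulary,
#' embedding tables, paragraph vectors) and applies it to both streams,
#' so no test-set statistics leak into training features.
#'
#' @param train_tokens,test_tokens `tokenized_notes` lists
#'   (`test_tokens` may be `NULL`).
#' @param method One of `"bow"`, `"tfidf"`, `"cbow"`, `"pvdbow"`.
#' @param min_df Vocabulary document-frequency floor for bow/tfidf
#'   (default 2).
#' @param dimension Embedding dimension; defaults to 200 for cbow and
#'   300 for pvdbow.
#' @param epochs Training epochs for the embedding methods (default 10).
#' @param seed Integer seed for embedding training.
#' @return List with `train`, `test` (matrices; `NULL` test passes
#'   through) and `artifacts` (fitted vocabulary/table/model).
#' @export
featurize <- function(train_tokens, test_tokens = NULL,
                      method = c("tfidf", "bow", "cbow", "pvdbow"),
                      min_df = 2L, dimension = NULL, epochs = 10L, seed = 1L) {
  method <- match.arg(method)
  out <- list(train = NULL, test = NULL, artifacts = list(method = method))
  if (method %in% c("bow", "tfidf")) {
    vocab <- fit_vocabulary(train_tokens, min_df = min_df)
    tr <- bow_matrix(train_tokens, vocab)
    te <- if (!is.null(test_tokens)) bow_matrix(test_tokens, vocab)
    if (method == "tfidf") {
      tr <- tfidf_transform(tr, vocab)
      if (!is.null(te)) te <- tfidf_transform(te, vocab)
    }
    out$train <- tr; out$test <- te; out$artifacts$vocab <- vocab
  } else if (method == "cbow") {
    if (is.null(dimension)) dimension <- 200L
    table <- train_word_embeddings(train_tokens, dimension = dimension,
                                   epochs = epochs, seed = seed)
    out$train <- cbow_doc_vectors(train_tokens, table)
    if (!is.null(test_tokens)) out$test <- cbow_doc_vectors(test_tokens, table)
    out$artifacts$table <- table
  } else {
    if (is.null(dimension)) dimension <- 300L
    model <- train_doc_embeddings(train_tokens, dimension = dimension,
                                  epochs = epochs, seed = seed)
    out$train <- model$doc_vectors
    if (!is.null(test_tokens)) {
      out$test <- infer_doc_vectors(model, test_tokens, seed = seed + 1L)
    }
    out$artifacts$model <- model
  }
  out
}

#' Run the label-source comparison experiment on one corpus
#'
#' The package's central experiment: starting from a corpus with
#' encounters (and, for synthetic corpora, ground truth), it
#' preprocesses once, splits by patient, derives ICD and weak labels,
#' featurizes with one method, trains a one-vs-all model per requested
#' training label source, and evaluates every model on the test
#' partition against each requested test label reference.
#'
#' @param corpus List with `notes`, `encounters` and optionally `truth`
#'   (as returned by [generate_corpus()]).
#' @param feature Featurization method (see [featurize()]).
#' @param train_sources Label sources to train with, subset of
#'   `c("icd", "weak", "hybrid", "truth")` (`"truth"` is available for
#'   synthetic corpora only and serves as a clean-label reference).
#' @param test_labels Test references to score against, subset of
#'   `c("truth", "icd", "weak")` (`"truth"` requires `corpus$truth`).
#' @param algorithm,threshold Classifier settings (see [train_config()]
#'   and [threshold_predict()]).
#' @param split_ratios,split_seed Patient-split settings.
#' @param min_df,dimension,epochs,seed Featurizer settings.
#' @param dict,terminology Weak-labeling resources (defaults: packaged).
#' @return List of class `label_experiment`: `reports` (nested list
#'   `reports[[train_source]][[test_label]]`), `labels`, `split`,
#'   `models`, `categories`.
#' @export
compare_label_sources <- function(corpus,
                                  feature = "tfidf",
                                  train_sources = c("icd", "weak"),
                                  test_labels = "truth",
                                  algorithm = "logistic_regression",
                                  threshold = 0.5,
                                  split_ratios = c(0.6, 0.2, 0.2),
                                  split_seed = 1L,
                                  min_df = 2L, dimension = NULL,
                                  epochs = 10L, seed = 1L,
                                  dict = read_concept_dictionary(),
                                  terminology = read_terminology()) {
  train_sources <- match.arg(train_sources, c("icd", "weak", "hybrid", "truth"),
                             several.ok = TRUE)
  if ("truth" %in% train_sources && is.null(corpus$truth)) {
    stop("training on truth labels requires corpus$truth")
  }
  test_labels <- match.arg(test_labels, c("truth", "icd", "weak"),
                           several.ok = TRUE)
  notes <- corpus$notes
  categories <- if (!is.null(corpus$truth)) colnames(corpus$truth)
                else target_categories()

  tokenized <- preprocess_notes(notes)
  split <- split_by_patient(notes$patient_id, split_ratios, seed = split_seed)
  part <- note_partition(notes, split)
  tr_ids <- notes$note_id[part == "train"]
  te_ids <- notes$note_id[part == "test"]

  labels <- list(icd = icd_label_notes(notes, corpus$encounters, categories),
                 weak = weak_label_notes(tokenized, dict, terminology,
                                         categories = categories))
  if (!is.null(corpus$truth)) labels$truth <- corpus$truth

  feats <- featurize(tokenized[tr_ids], tokenized[te_ids], method = feature,
                     min_df = min_df, dimension = dimension, epochs = epochs,
                     seed = seed)

  reports <- list(); models <- list()
  for (src in train_sources) {
    y_train <- if (src == "truth") labels$truth
               else assemble_training_labels(labels$icd, labels$weak, mode = src)
    cfg <- train_config(algorithm = algorithm, seed = seed,
                        label_source = src)
    model <- train_ova(feats$train, y_train, cfg)
    scores <- predict_scores(model, feats$test)
    preds <- threshold_predict(scores, threshold)
    reports[[src]] <- list()
    for (ref in test_labels) {
      y_ref <- unclass(labels[[ref]])[te_ids, , drop = FALSE]
      reports[[src]][[ref]] <- compute_metrics(y_ref, scores, preds,
                                               test_label_source = ref)
    }
    models[[src]] <- model
  }
  structure(list(reports = reports, labels = labels, split = split,
                 models = models, categories = categories,
                 feature = feature),
            class = "label_experiment")
}

#' Delta grid across label sources, mirroring the enrichment analysis
#'
#' Runs [compare_label_sources()] over the full grid of training label
#' sources and test references and reports, for every test reference,
#' the signed score differences of each non-baseline training source
#' against the ICD baseline (hybrid - icd and weak - icd), the
#' comparison behind the hybrid/weak enrichment figures.
#'
#' @inheritParams compare_label_sources
#' @return List of class `experiment_grid` with `experiment` (the
#'   underlying `label_experiment`) and `deltas`
#'   (`deltas[[test_label]][[source]]`, each a `delta_report`).
#' @export
compare_experiments <- function(corpus, feature = "pvdbow",
                                train_sources = c("icd", "weak", "hybrid"),
                                test_labels = c("truth", "icd", "weak"),
                                ...) {
  if (!("icd" %in% train_sources)) {
    stop("the comparison needs the 'icd' baseline among train_sources")
  }
  exp <- compare_label_sources(corpus, feature = feature,
                               train_sources = train_sources,
                               test_labels = test_labels, ...)
  deltas <- list()
  for (ref in test_labels) {
    deltas[[ref]] <- list()
    for (src in setdiff(train_sources, "icd")) {
      deltas[[ref]][[src]] <- score_delta(exp$reports[[src]][[ref]],
                                          exp$reports[["icd"]][[ref]])
    }
  }
  structure(list(experiment = exp, deltas = deltas),
            class = "experiment_grid")
}

#' Training-size scaling of the prevalence-recall relationship
#'
#' Trains the same configuration on nested subsets of a corpus at the
#' requested sizes (notes drawn by whole patients) and profiles
#' per-category recall against category prevalence at each size (the
#' flatness analysis: with enough training data, recall should stop
#' depending on prevalence).
#'
#' @param corpus Corpus list (needs `truth` for recall-vs-truth).
#' @param sizes Integer vector of training-corpus note counts, e.g.
#'   `c(1000, 5000, 20000)`; each size uses the first patients whose
#'   notes reach the count.
#' @param epochs Embedding training epochs; either one value for every
#'   size or a vector aligned with `sizes` (small corpora need more
#'   passes to converge, so e.g. `c(40, 20, 10)`).
#' @param feature,label_source,test_labels,... Passed through to
#'   [compare_label_sources()].
#' @return List with `profile` (see [prevalence_recall_profile()]) and
#'   `reports` (per size).
#' @export
size_scaling_experiment <- function(corpus, sizes, feature = "pvdbow",
                                    label_source = "icd",
                                    test_labels = "truth", epochs = 10L, ...) {
  notes <- corpus$notes
  sizes <- sort(sizes)
  epochs <- rep_len(epochs, length(sizes))
  reports <- list()
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    keep <- seq_len(min(sz, nrow(notes)))
    sub <- list(notes = notes[keep, , drop = FALSE],
                encounters = corpus$encounters,
                truth = corpus$truth[notes$note_id[keep], , drop = FALSE])
    exp <- compare_label_sources(sub, feature = feature,
                                 train_sources = label_source,
                                 test_labels = test_labels,
                                 epochs = epochs[i], ...)
    reports[[as.character(sz)]] <- exp$reports[[label_source]][[test_labels[1]]]
  }
  list(profile = prevalence_recall_profile(reports), reports = reports)
}
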