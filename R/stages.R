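# File-based stage runner: every stage reads/writes inside cfg$workdir,
# takes its seed from the config, and appends a manifest entry with md5
# hashes of its outputs, so a finished run is reproducible and auditable
# from the manifest alone.

.stage_files <- list(
  simulate = list(needs = character(),
                  makes = c("notes.csv", "encounters.csv", "labels_truth.csv")),
  filter = list(needs = c("notes.csv", "encounters.csv"),
                makes = "notes_filtered.csv"),
  split = list(needs = "notes_filtered.csv", makes = "split.csv"),
  `label-icd` = list(needs = c("notes_filtered.csv", "encounters.csv"),
                     makes = "labels_icd.csv"),
  `label-weak` = list(needs = "notes_filtered.csv", makes = "labels_weak.csv"),
  featurize = list(needs = c("notes_filtered.csv", "split.csv"),
                   makes = c("features_train.rds", "features_test.rds")),
  train = list(needs = c("features_train.rds", "labels_icd.csv",
                         "labels_weak.csv"),
               makes = "model.rds"),
  evaluate = list(needs = c("model.rds", "features_test.rds"),
                  makes = "metrics.json"),
  compare = list(needs = c("notes_filtered.csv", "encounters.csv"),
                 makes = "deltas.json"),
  report = list(needs = "metrics.json", makes = "report.md")
)

#' Read a pipeline configuration file
#'
#' YAML with top-level keys `workdir`, `seed`, and per-stage sections
#' (`generator`, `filter`, `split`, `features`, `train`, `evaluate`).
#' Missing sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return Config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$workdir)) stop("config needs a workdir")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "pipeline_config"
  cfg
}

.wpath <- function(cfg, f) file.path(cfg$workdir, f)

.manifest_append <- function(cfg, stage, outputs) {
  mpath <- .wpath(cfg, "manifest.json")
  manifest <- if (file.exists(mpath)) {
    jsonlite::read_json(mpath, simplifyVector = FALSE)
  } else list(artifact_version = as.character(utils::packageVersion("symptomweak")),
              config = cfg[setdiff(names(cfg), "workdir")], stages = list())
  entry <- list(stage = stage, timestamp = format(Sys.time(), tz = "UTC"),
                seed = cfg$seed,
                outputs = lapply(outputs, function(f) {
                  list(file = f, md5 = unname(tools::md5sum(.wpath(cfg, f))))
                }))
  manifest$stages[[length(manifest$stages) + 1L]] <- entry
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(entry)
}

# default-filled accessor for nested config values
.cfg_get <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `filter`, `split`, `label-icd`, `label-weak`,
#' `featurize`, `train`, `evaluate`, `compare`, `report`. Each stage
#' checks that its upstream outputs exist (error naming the missing
#' stage otherwise), writes its outputs to temporary files moved into
#' place on success, and appends a manifest entry.
#'
#' @param stage Stage name.
#' @param cfg A `pipeline_config` (or path to one).
#' @return Invisibly, the manifest entry of the stage.
#' @export
run_stage <- function(stage, cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stage <- match.arg(stage, names(.stage_files))
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  stage_def <- .stage_files[[stage]]
  have <- file.exists(vapply(stage_def$needs, .wpath, character(1), cfg = cfg))
  if (!all(have)) {
    producer <- vapply(stage_def$needs[!have], function(f) {
      names(.stage_files)[vapply(.stage_files, function(s) f %in% s$makes,
                                 logical(1))][1]
    }, character(1))
    stop("stage '", stage, "' is missing input(s) ",
         paste(stage_def$needs[!have], collapse = ", "),
         "; run stage(s) first: ", paste(unique(producer), collapse = ", "))
  }
  switch(stage,
    simulate = .stage_simulate(cfg),
    filter = .stage_filter(cfg),
    split = .stage_split(cfg),
    `label-icd` = .stage_label_icd(cfg),
    `label-weak` = .stage_label_weak(cfg),
    featurize = .stage_featurize(cfg),
    train = .stage_train(cfg),
    evaluate = .stage_evaluate(cfg),
    compare = .stage_compare(cfg),
    report = .stage_report(cfg))
  .manifest_append(cfg, stage, stage_def$makes)
}

#' Run a sequence of pipeline stages
#'
#' @param cfg Config (or path); `stages` defaults to the full chain.
#' @param stages Character vector of stage names, executed in order.
#' @return Invisibly, the list of manifest entries.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "filter", "split",
                                         "label-icd", "label-weak",
                                         "featurize", "train", "evaluate",
                                         "report")) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  invisible(lapply(stages, run_stage, cfg = cfg))
}

.gen_cfg_from <- function(cfg) {
  g <- cfg$generator
  defaults <- generator_config(seed = cfg$seed)
  for (nm in names(g)) defaults[[nm]] <- g[[nm]]
  if (!is.null(g$prevalence)) {
    defaults$prevalence <- unlist(g$prevalence)
  }
  validate_generator_config(defaults)
}

.stage_simulate <- function(cfg) {
  sim <- generate_corpus(.gen_cfg_from(cfg))
  write_corpus(sim$notes, sim$encounters, .wpath(cfg, "notes.csv"),
               .wpath(cfg, "encounters.csv"))
  write_labels(sim$truth, .wpath(cfg, "labels_truth.csv"))
}

.stage_filter <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes.csv"))
  encs <- read_encounters(.wpath(cfg, "encounters.csv"))
  prefix <- .cfg_get(cfg, "filter", "required_category_prefix", NULL)
  out <- filter_cohort(notes, encs,
                       min_chars = .cfg_get(cfg, "filter", "min_chars", 350),
                       required_category_prefix = prefix)
  write.csv(as.data.frame(out), .wpath(cfg, "notes_filtered.csv"),
            row.names = FALSE)
}

.stage_split <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes_filtered.csv"))
  sp <- split_by_patient(notes$patient_id,
                         ratios = unlist(.cfg_get(cfg, "split", "ratios",
                                                  c(0.6, 0.2, 0.2))),
                         seed = .cfg_get(cfg, "split", "seed", cfg$seed))
  write.csv(as.data.frame(sp), .wpath(cfg, "split.csv"), row.names = FALSE)
}

.categories_from <- function(cfg) {
  cats <- .cfg_get(cfg, "generator", "categories", target_categories())
  unlist(cats)
}

.stage_label_icd <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes_filtered.csv"))
  encs <- read_encounters(.wpath(cfg, "encounters.csv"))
  write_labels(icd_label_notes(notes, encs, .categories_from(cfg)),
               .wpath(cfg, "labels_icd.csv"))
}

.stage_label_weak <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes_filtered.csv"))
  toks <- preprocess_notes(notes)
  labels <- weak_label_notes(toks, read_concept_dictionary(),
                             read_terminology(),
                             categories = .categories_from(cfg))
  write_labels(labels, .wpath(cfg, "labels_weak.csv"))
}

.stage_featurize <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes_filtered.csv"))
  sp <- read.csv(.wpath(cfg, "split.csv"), colClasses = "character")
  toks <- preprocess_notes(notes)
  part <- sp$partition[match(notes$patient_id, sp$patient_id)]
  fe <- featurize(toks[notes$note_id[part == "train"]],
                  toks[notes$note_id[part == "test"]],
                  method = .cfg_get(cfg, "features", "method", "tfidf"),
                  min_df = .cfg_get(cfg, "features", "min_df", 2L),
                  dimension = .cfg_get(cfg, "features", "dimension", NULL),
                  epochs = .cfg_get(cfg, "features", "epochs", 10L),
                  seed = cfg$seed)
  saveRDS(fe$train, .wpath(cfg, "features_train.rds"))
  saveRDS(fe$test, .wpath(cfg, "features_test.rds"))
}

.stage_train <- function(cfg) {
  feats <- readRDS(.wpath(cfg, "features_train.rds"))
  icd <- read_labels(.wpath(cfg, "labels_icd.csv"))
  weak <- read_labels(.wpath(cfg, "labels_weak.csv"))
  mode <- .cfg_get(cfg, "train", "label_source", "icd")
  labels <- assemble_training_labels(icd, weak, mode = mode)
  conf <- train_config(
    algorithm = .cfg_get(cfg, "train", "algorithm", "logistic_regression"),
    rf_trees = .cfg_get(cfg, "train", "rf_trees", 100L),
    max_iter = .cfg_get(cfg, "train", "max_iter", 1000L),
    seed = cfg$seed, label_source = mode)
  model <- train_ova(feats, labels, conf)
  saveRDS(list(model = model, package_version =
                 as.character(utils::packageVersion("symptomweak"))),
          .wpath(cfg, "model.rds"))
}

.stage_evaluate <- function(cfg) {
  model <- readRDS(.wpath(cfg, "model.rds"))$model
  feats <- readRDS(.wpath(cfg, "features_test.rds"))
  ref_name <- .cfg_get(cfg, "evaluate", "test_labels", "truth")
  ref_file <- paste0("labels_", ref_name, ".csv")
  if (!file.exists(.wpath(cfg, ref_file))) {
    stop("evaluate: missing reference labels ", ref_file)
  }
  ref <- read_labels(.wpath(cfg, ref_file))
  scores <- predict_scores(model, feats)
  preds <- threshold_predict(scores,
                             .cfg_get(cfg, "train", "threshold", 0.5))
  y <- unclass(ref)[rownames(feats), model$categories, drop = FALSE]
  rep <- compute_metrics(y, scores, preds, test_label_source = ref_name)
  jsonlite::write_json(list(per_class = rep$per_class,
                            macro = as.list(rep$macro),
                            test_label_source = ref_name),
                       .wpath(cfg, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_compare <- function(cfg) {
  notes <- read_notes(.wpath(cfg, "notes_filtered.csv"))
  encs <- read_encounters(.wpath(cfg, "encounters.csv"))
  corpus <- list(notes = notes, encounters = encs)
  tf <- .wpath(cfg, "labels_truth.csv")
  if (file.exists(tf)) {
    tr <- read_labels(tf)
    corpus$truth <- tr[notes$note_id, , drop = FALSE]
  }
  grid <- compare_experiments(
    corpus,
    feature = .cfg_get(cfg, "features", "method", "pvdbow"),
    test_labels = intersect(c("truth", "icd", "weak"),
                            if (is.null(corpus$truth)) c("icd", "weak")
                            else c("truth", "icd", "weak")),
    split_seed = .cfg_get(cfg, "split", "seed", cfg$seed),
    dimension = .cfg_get(cfg, "features", "dimension", NULL),
    epochs = .cfg_get(cfg, "features", "epochs", 10L),
    seed = cfg$seed)
  out <- lapply(grid$deltas, function(per_ref) {
    lapply(per_ref, function(d) {
      list(per_class = d$per_class, macro = as.list(d$macro))
    })
  })
  jsonlite::write_json(out, .wpath(cfg, "deltas.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_report <- function(cfg) {
  metrics <- jsonlite::read_json(.wpath(cfg, "metrics.json"),
                                 simplifyVector = TRUE)
  fmt <- function(x) {
    if (is.null(x) || length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
      "NA"
    } else sprintf("%.3f", x)
  }
  md <- c("# Evaluation report", "",
          sprintf("Test labels: %s", metrics$test_label_source), "",
          "| category | prevalence | recall | precision | F1 | AP | AUROC |",
          "|---|---|---|---|---|---|---|")
  pc <- metrics$per_class
  for (i in seq_len(nrow(pc))) {
    md <- c(md, paste("|", paste(c(
      pc$category[i],
      vapply(c("prevalence", "recall", "precision", "f1",
               "average_precision", "auroc"),
             function(cn) fmt(pc[[cn]][i]), character(1))),
      collapse = " | "), "|"))
  }
  md <- c(md, "",
          sprintf("Macro: recall %s, F1 %s, AP %s, AUROC %s",
                  fmt(metrics$macro$recall), fmt(metrics$macro$f1),
                  fmt(metrics$macro$average_precision),
                  fmt(metrics$macro$auroc)))
  writeLines(md, .wpath(cfg, "report.md"))
}
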