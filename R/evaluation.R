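# rank-based AUROC (Mann-Whitney, ties count 1/2)
.auroc <- function(y, s) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# threshold-sum average precision: AP = sum_k (R_k - R_{k-1}) P_k over
# descending unique score thresholds
.average_precision <- function(y, s) {
  n1 <- sum(y == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each score block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

.roc_points <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / max(1, sum(y == 0))),
             tpr = c(0, tp[last] / max(1, sum(y == 1))))
}

.pr_points <- function(y, s) {
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(threshold = s[last],
             recall = tp[last] / max(1, sum(y == 1)),
             precision = tp[last] / (tp[last] + fp[last]))
}

#' Compute the full metric battery for a multi-label prediction
#'
#' Per category and macro-averaged: recall, precision, F1, average
#' precision (threshold-sum PR integral) and AUROC (probability that a
#' random positive outscores a random negative, ties counting one half),
#' plus ROC and PR curve point lists and test-set prevalence. A category
#' with no positive test instance has undefined recall/AP (and no
#' AUROC): it is reported as `NA` with a warning and excluded from the
#' macro averages, which are unweighted means over the remaining
#' categories.
#'
#' @param y_true 0/1 matrix of reference labels (notes x categories).
#' @param scores Probability matrix, same shape.
#' @param y_pred Optional 0/1 prediction matrix; default thresholds
#'   `scores` at 0.5.
#' @param test_label_source Tag recording which label route produced
#'   `y_true` (e.g. `"truth"`, `"icd"`, `"weak"`).
#' @return List of class `metrics_report`: `per_class` data.frame,
#'   `macro` named vector, `curves` (per-category ROC/PR points),
#'   `test_label_source`, `degenerate` (categories excluded from the
#'   macro).
#' @export
compute_metrics <- function(y_true, scores, y_pred = NULL,
                            test_label_source = "truth") {
  y_true <- as.matrix(y_true)
  stopifnot(all(dim(y_true) == dim(scores)))
  if (is.null(y_pred)) y_pred <- threshold_predict(scores)
  stopifnot(all(dim(y_pred) == dim(y_true)))
  cats <- colnames(y_true)
  if (is.null(cats)) cats <- paste0("C", seq_len(ncol(y_true)))

  rows <- lapply(seq_along(cats), function(k) {
    y <- y_true[, k]; s <- scores[, k]; p <- y_pred[, k]
    tp <- sum(y == 1 & p == 1); fn <- sum(y == 1 & p == 0)
    fp <- sum(y == 0 & p == 1)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0) {
      2 * precision * recall / (precision + recall)
    } else if (!is.na(recall) && !is.na(precision)) 0 else NA_real_
    data.frame(category = cats[k], prevalence = mean(y), recall = recall,
               precision = precision, f1 = f1,
               average_precision = .average_precision(y, s),
               auroc = .auroc(y, s), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  degenerate <- cats[is.na(per_class$recall) | is.na(per_class$auroc)]
  if (length(degenerate)) {
    warning("degenerate categories excluded from macro averages: ",
            paste(degenerate, collapse = ", "))
  }
  ok <- !(per_class$category %in% degenerate)
  macro <- c(recall = mean(per_class$recall[ok]),
             precision = mean(per_class$precision[ok]),
             f1 = mean(per_class$f1[ok]),
             average_precision = mean(per_class$average_precision[ok]),
             auroc = mean(per_class$auroc[ok]))
  curves <- setNames(lapply(seq_along(cats), function(k) {
    list(roc = .roc_points(y_true[, k], scores[, k]),
         pr = .pr_points(y_true[, k], scores[, k]))
  }), cats)
  structure(list(per_class = per_class, macro = macro, curves = curves,
                 test_label_source = test_label_source,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> vs %s labels\n", x$test_label_source))
  print(cbind(x$per_class[1], round(x$per_class[-1], digits)), row.names = FALSE)
  cat("macro:", paste(sprintf("%s=%.3f", names(x$macro), x$macro),
                      collapse = " "), "\n")
  if (length(x$degenerate)) {
    cat("degenerate (excluded):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signed metric differences between two reports
#'
#' Computes `report_a - report_b` per category and per metric, the
#' comparison behind the hybrid-vs-baseline and weak-vs-baseline delta
#' figures. Both reports must cover the same categories (same test set).
#' Metrics missing (`NA`) in either report give `NA` deltas, flagged in
#' the `missing` element.
#'
#' @param report_a,report_b `metrics_report` objects.
#' @return List of class `delta_report` with `per_class` (signed
#'   differences), `macro`, and `missing`.
#' @export
score_delta <- function(report_a, report_b) {
  if (!identical(report_a$per_class$category, report_b$per_class$category)) {
    stop("reports cover different category sets")
  }
  metrics <- c("recall", "precision", "f1", "average_precision", "auroc")
  d <- report_a$per_class[, metrics] - report_b$per_class[, metrics]
  d <- cbind(report_a$per_class["category"], d)
  miss <- d$category[rowSums(is.na(d[metrics])) > 0]
  structure(list(per_class = d,
                 macro = report_a$macro - report_b$macro,
                 missing = miss),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, digits = 3, ...) {
  cat("<delta_report> (a - b)\n")
  print(cbind(x$per_class[1], round(x$per_class[-1], digits)), row.names = FALSE)
  cat("macro:", paste(sprintf("%s=%+.3f", names(x$macro), x$macro),
                      collapse = " "), "\n")
  invisible(x)
}

#' Recall against prevalence across training sizes
#'
#' Long-format table of per-category recall versus test-set prevalence
#' for a family of experiments differing in training-set size, with a
#' per-size flatness summary: the least-squares slope of recall on
#' log(prevalence). A slope near zero means low-prevalence symptoms are
#' predicted as well as common ones.
#'
#' @param reports Named list of `metrics_report` objects; names are the
#'   training sizes.
#' @return List with `table` (size, category, prevalence, recall) and
#'   `slopes` (named per-size slope of recall vs log-prevalence).
#' @export
prevalence_recall_profile <- function(reports) {
  stopifnot(length(reports) >= 1L)
  cats <- reports[[1]]$per_class$category
  for (r in reports) stopifnot(identical(r$per_class$category, cats))
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    pc <- reports[[nm]]$per_class
    data.frame(size = nm, category = pc$category, prevalence = pc$prevalence,
               recall = pc$recall, stringsAsFactors = FALSE)
  }))
  slopes <- vapply(names(reports), function(nm) {
    pc <- reports[[nm]]$per_class
    ok <- !is.na(pc$recall) & pc$prevalence > 0
    if (sum(ok) < 2L || length(unique(pc$prevalence[ok])) < 2L) return(NA_real_)
    unname(coef(lm(pc$recall[ok] ~ log(pc$prevalence[ok])))[2])
  }, numeric(1))
  list(table = tab, slopes = slopes)
}

#' Majority-vote a note label from mention annotations
#'
#' External-validation adapter: mention-level polarity annotations for
#' one note and one category are reduced to a note label by majority
#' vote. The note is positive iff positive mentions strictly outnumber
#' the negative and uncertain ones together (uncertain counts against
#' positivity); ties and empty annotation lists give 0.
#'
#' @param polarity Character vector of mention polarities, each one of
#'   `"positive"`, `"negative"`, `"uncertain"`.
#' @return Integer 0 or 1.
#' @export
mentions_to_note_label <- function(polarity) {
  if (!length(polarity)) return(0L)
  bad <- setdiff(unique(polarity), c("positive", "negative", "uncertain"))
  if (length(bad)) stop("unknown polarity value(s): ", paste(bad, collapse = ", "))
  as.integer(sum(polarity == "positive") > sum(polarity != "positive"))
}

#' Read mention annotations in standoff format
#'
#' One record per mention: `note_id, start, end, polarity, category`
#' (CSV). [read_brat_ann()] adapts a BRAT-style `.ann` file, where each
#' `T` line's type encodes category and polarity as
#' `<category>_<polarity>` (e.g. `R05_negative`).
#'
#' @param path File path.
#' @return `data.frame` with columns `note_id`, `start`, `end`,
#'   `polarity`, `category`.
#' @export
read_standoff <- function(path) {
  df <- read.csv(path, colClasses = c("character", "integer", "integer",
                                      "character", "character"))
  check_required_fields(df, c("note_id", "polarity", "category"), path)
  df
}

#' @rdname read_standoff
#' @param note_id Note identifier the `.ann` file belongs to.
#' @export
read_brat_ann <- function(path, note_id) {
  lines <- readLines(path, warn = FALSE)
  tlines <- lines[startsWith(lines, "T")]
  out <- lapply(tlines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    ann <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    type <- strsplit(ann[1], "_", fixed = TRUE)[[1]]
    data.frame(note_id = note_id, start = as.integer(ann[2]),
               end = as.integer(ann[3]), polarity = tolower(type[2]),
               category = type[1], stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(note_id = character(), start = integer(),
                      end = integer(), polarity = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Note-level labels from a standoff annotation table
#'
#' Applies [mentions_to_note_label()] per note and category over an
#' annotation table, yielding a [label_matrix()] usable as test
#' reference (`source = "truth"`).
#'
#' @param annotations `data.frame` from [read_standoff()].
#' @param note_ids Notes to cover (notes without annotations get 0s).
#' @param categories Ordered target categories.
#' @return A [label_matrix()] with `source = "truth"`.
#' @export
annotations_to_labels <- function(annotations, note_ids,
                                  categories = target_categories()) {
  m <- matrix(0L, nrow = length(note_ids), ncol = length(categories),
              dimnames = list(note_ids, categories))
  if (nrow(annotations)) {
    grp <- split(annotations$polarity,
                 list(annotations$note_id, annotations$category), drop = TRUE)
    for (key in names(grp)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      nid <- paste(parts[-length(parts)], collapse = ".")
      cat <- parts[length(parts)]
      if (nid %in% note_ids && cat %in% categories) {
        m[nid, cat] <- mentions_to_note_label(grp[[key]])
      }
    }
  }
  label_matrix(m, note_ids = note_ids, categories = categories, source = "truth")
}
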