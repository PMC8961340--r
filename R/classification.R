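#' Training configuration for the one-vs-all classifiers
#'
#' @param algorithm `"logistic_regression"` (L2-penalized, fitted with
#'   the limited-memory BFGS solver) or `"random_forest"` (100 trees by
#'   default).
#' @param rf_trees Number of random-forest trees (default 100).
#' @param max_iter Maximum optimizer iterations (default 1000).
#' @param lambda L2 penalty weight for logistic regression (default 1;
#'   the intercept is unpenalized). Recorded in model metadata.
#' @param seed Integer seed.
#' @param label_source Which label route trained this model
#'   (`icd`/`weak`/`hybrid`, or `truth` for synthetic-reference runs),
#'   carried as metadata.
#' @return List of class `train_config`.
#' @export
train_config <- function(algorithm = c("logistic_regression", "random_forest"),
                         rf_trees = 100L, max_iter = 1000L, lambda = 1,
                         seed = 1L,
                         label_source = c("icd", "weak", "hybrid", "truth")) {
  algorithm <- match.arg(algorithm)
  label_source <- match.arg(label_source)
  stopifnot(rf_trees >= 1L, max_iter >= 1L)
  structure(list(algorithm = algorithm, rf_trees = as.integer(rf_trees),
                 max_iter = as.integer(max_iter), lambda = lambda,
                 seed = as.integer(seed), label_source = label_source),
            class = "train_config")
}

#' Assemble per-note training labels from one or two label sources
#'
#' `mode = "icd"` or `"weak"` passes the corresponding matrix through
#' unchanged. `mode = "hybrid"` gives each note exactly one source:
#' notes listed in `icd_coded_ids` keep their ICD vector (even if a weak
#' vector exists), all remaining notes take their weak vector; a note
#' covered by neither source is an error.
#'
#' @param icd_labels,weak_labels [label_matrix()] objects (either may be
#'   `NULL` when unused by the mode).
#' @param mode Label source: `"icd"`, `"weak"` or `"hybrid"`.
#' @param icd_coded_ids For hybrid mode, the note ids whose encounters
#'   actually carry target-category codes (defaults to notes with a
#'   nonzero ICD row, the encounter-coded notes).
#' @return A [label_matrix()] tagged with the effective source.
#' @export
assemble_training_labels <- function(icd_labels = NULL, weak_labels = NULL,
                                     mode = c("icd", "weak", "hybrid"),
                                     icd_coded_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "icd") return(icd_labels)
  if (mode == "weak") return(weak_labels)
  stopifnot(!is.null(icd_labels), !is.null(weak_labels))
  if (is.null(icd_coded_ids)) {
    icd_coded_ids <- rownames(icd_labels)[rowSums(icd_labels) > 0]
  }
  ids <- union(rownames(icd_labels), rownames(weak_labels))
  cats <- colnames(icd_labels)
  stopifnot(identical(cats, colnames(weak_labels)))
  m <- matrix(0L, nrow = length(ids), ncol = length(cats),
              dimnames = list(ids, cats))
  from_icd <- ids %in% intersect(icd_coded_ids, rownames(icd_labels))
  from_weak <- !from_icd & ids %in% rownames(weak_labels)
  orphan <- !from_icd & !from_weak
  if (any(orphan)) {
    stop("notes with neither ICD nor weak labels in hybrid mode: ",
         paste(head(ids[orphan], 5L), collapse = ", "))
  }
  m[from_icd, ] <- unclass(icd_labels)[ids[from_icd], , drop = FALSE]
  m[from_weak, ] <- unclass(weak_labels)[ids[from_weak], , drop = FALSE]
  out <- label_matrix(m, note_ids = ids, categories = cats, source = "hybrid")
  attr(out, "per_note_source") <- ifelse(from_icd, "icd", "weak")
  out
}

# L2-penalized binary logistic regression by L-BFGS; X may be sparse
.fit_logistic <- function(X, y, lambda = 1, max_iter = 1000L) {
  p <- ncol(X)
  nll <- function(theta) {
    eta <- as.numeric(X %*% theta[-1L]) + theta[1L]
    # log(1 + exp(eta)) - y*eta, computed stably
    ll <- sum(pmax(eta, 0) - y * eta + log1p(exp(-abs(eta))))
    ll + 0.5 * lambda * sum(theta[-1L]^2)
  }
  grd <- function(theta) {
    eta <- as.numeric(X %*% theta[-1L]) + theta[1L]
    r <- 1 / (1 + exp(-eta)) - y
    g <- as.numeric(Matrix::crossprod(X, r)) + lambda * theta[-1L]
    c(sum(r), g)
  }
  fit <- optim(rep(0, p + 1L), nll, grd, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  if (fit$convergence != 0L) {
    message("logistic regression did not fully converge (code ",
            fit$convergence, "); using the final iterate")
  }
  list(intercept = fit$par[1L], coef = fit$par[-1L],
       converged = fit$convergence == 0L)
}

#' Train one-vs-all symptom classifiers
#'
#' Fits one independent binary probabilistic classifier per target
#' category on a shared feature matrix. Categories with no positive
#' training instance (or no negative one) cannot be trained: they are
#' marked skipped with a warning and later predict a constant score 0.
#'
#' @param features Numeric matrix (dense or sparse), one row per note,
#'   rownames = note ids.
#' @param labels A [label_matrix()] row-aligned with `features` (matched
#'   by note id).
#' @param config A [train_config()].
#' @return An `ova_model`: per-category fits plus training metadata.
#' @export
train_ova <- function(features, labels, config = train_config()) {
  idx <- match(rownames(features), rownames(labels))
  if (anyNA(idx)) stop("feature rows and label rows are misaligned")
  y_all <- unclass(labels)[idx, , drop = FALSE]
  cats <- colnames(labels)
  fits <- setNames(vector("list", length(cats)), cats)
  for (k in seq_along(cats)) {
    y <- y_all[, k]
    if (length(unique(y)) < 2L) {
      warning("category ", cats[k], " has a single training class; skipped")
      fits[[k]] <- list(skipped = TRUE)
      next
    }
    if (config$algorithm == "logistic_regression") {
      f <- .fit_logistic(features, y, lambda = config$lambda,
                         max_iter = config$max_iter)
      fits[[k]] <- c(f, list(skipped = FALSE))
    } else {
      rf <- withr::with_seed(config$seed + k, randomForest::randomForest(
        x = as.matrix(features), y = factor(y, levels = c(0, 1)),
        ntree = config$rf_trees))
      fits[[k]] <- list(rf = rf, skipped = FALSE)
    }
  }
  structure(list(fits = fits, config = config, categories = cats,
                 n_features = ncol(features), n_train = nrow(features),
                 prevalence = colMeans(y_all)),
            class = "ova_model")
}

#' @export
print.ova_model <- function(x, ...) {
  skipped <- vapply(x$fits, function(f) isTRUE(f$skipped), logical(1))
  cat(sprintf("<ova_model> %s on %d notes x %d features (labels: %s)\n",
              x$config$algorithm, x$n_train, x$n_features,
              x$config$label_source))
  cat(sprintf("  categories: %d trained, %d skipped\n",
              sum(!skipped), sum(skipped)))
  invisible(x)
}

#' Predict per-category probabilities
#'
#' @param model An `ova_model`.
#' @param features Feature matrix with the training dimensionality.
#' @return Matrix of probabilities in `[0, 1]`, one column per category;
#'   skipped categories give constant 0.
#' @export
predict_scores <- function(model, features) {
  if (ncol(features) != model$n_features) {
    stop("feature dimension ", ncol(features),
         " does not match training dimension ", model$n_features)
  }
  out <- matrix(0, nrow = nrow(features), ncol = length(model$categories),
                dimnames = list(rownames(features), model$categories))
  if (!nrow(features)) return(out)
  for (k in seq_along(model$categories)) {
    f <- model$fits[[k]]
    if (isTRUE(f$skipped)) next
    if (model$config$algorithm == "logistic_regression") {
      eta <- as.numeric(features %*% f$coef) + f$intercept
      out[, k] <- 1 / (1 + exp(-eta))
    } else {
      out[, k] <- predict(f$rf, newdata = as.matrix(features),
                          type = "prob")[, "1"]
    }
  }
  out
}

#' Threshold probabilities into hard labels
#'
#' @param scores Probability matrix from [predict_scores()].
#' @param threshold Decision threshold; a score equal to the threshold
#'   predicts positive (default 0.5).
#' @return Integer 0/1 matrix of the same shape.
#' @export
threshold_predict <- function(scores, threshold = 0.5) {
  out <- (scores >= threshold) + 0L
  dimnames(out) <- dimnames(scores)
  out
}
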