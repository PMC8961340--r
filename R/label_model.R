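#' Fit the generative label model by expectation-maximization
#'
#' Combines the fire/abstain votes of several labeling functions into a
#' posterior probability that each mention is positive. The model: a
#' latent state per mention, positive with prior probability
#' `class_prior`; conditionally on the state, labeling functions act
#' independently, each with its own accuracy `a_j` — an LF fires on a
#' modified (non-positive) mention with probability `a_j` and on a
#' positive mention with probability `1 - a_j`. EM alternates posterior
#' computation with accuracy re-estimation; the class prior is held
#' fixed. The observed-data log-likelihood is non-decreasing across
#' iterations, and iteration stops when the improvement falls below
#' `tol` or after `max_iter` steps.
#'
#' Rows where every labeling function abstained are assigned the prior
#' as their posterior. A labeling function that never fires has no
#' estimable accuracy: it is reported as `NA` with a warning and ignored
#' in the likelihood.
#'
#' @param lf_matrix 0/1 matrix, mentions in rows, labeling functions in
#'   columns (1 = fire, 0 = abstain).
#' @param class_prior Prior probability of the positive state, in (0,1).
#' @param max_iter,tol EM stopping controls (defaults 200, 1e-8).
#' @param seed Integer seed for the accuracy initialization jitter.
#' @return List of class `label_model`: `accuracies` (per LF, `NA` for
#'   degenerate columns), `posterior` (per-mention probability of
#'   positive), `log_likelihood` (trace, one entry per iteration),
#'   `converged`, `class_prior`.
#' @export
fit_label_model <- function(lf_matrix, class_prior = 0.5, max_iter = 200L,
                            tol = 1e-8, seed = 1L) {
  lf_matrix <- as.matrix(lf_matrix)
  storage.mode(lf_matrix) <- "double"
  if (!nrow(lf_matrix)) stop("empty labeling-function matrix")
  if (class_prior <= 0 || class_prior >= 1) stop("class_prior must lie in (0,1)")
  lf_names <- colnames(lf_matrix)
  if (is.null(lf_names)) lf_names <- paste0("lf", seq_len(ncol(lf_matrix)))

  dead <- colSums(lf_matrix) == 0
  if (any(dead)) {
    warning("labeling function(s) never fire, accuracy undefined: ",
            paste(lf_names[dead], collapse = ", "))
  }
  F <- lf_matrix[, !dead, drop = FALSE]
  pi1 <- class_prior
  out_acc <- setNames(rep(NA_real_, length(lf_names)), lf_names)

  if (ncol(F) == 0L) {
    post <- rep(pi1, nrow(lf_matrix))
    return(structure(list(accuracies = out_acc, posterior = post,
                          log_likelihood = numeric(), converged = TRUE,
                          class_prior = pi1), class = "label_model"))
  }

  # init above 0.5 to break the label-swap symmetry: fires mean "modified"
  a <- withr::with_seed(as.integer(seed),
                        0.7 + runif(ncol(F), -0.05, 0.05))
  ll_trace <- numeric(0)
  converged <- FALSE
  eps <- 1e-12
  for (it in seq_len(max_iter)) {
    # E-step: log P(votes | state) under conditional independence
    l1 <- F %*% log(pmax(1 - a, eps)) + (1 - F) %*% log(pmax(a, eps))
    l0 <- F %*% log(pmax(a, eps)) + (1 - F) %*% log(pmax(1 - a, eps))
    m <- pmax(l1, l0)
    lik1 <- pi1 * exp(l1 - m)
    lik0 <- (1 - pi1) * exp(l0 - m)
    post <- as.numeric(lik1 / (lik1 + lik0))
    ll <- sum(log(lik1 + lik0) + m)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && ll - ll_trace[it - 1L] < tol) { converged <- TRUE; break }
    # M-step: accuracy = expected rate of correct behavior
    # (fire on modified, abstain on positive)
    correct <- colSums((1 - post) * F + post * (1 - F))
    a <- pmin(pmax(correct / nrow(F), eps), 1 - eps)
  }

  post[rowSums(F) == 0] <- pi1   # all-abstain rows carry no evidence
  out_acc[!dead] <- as.numeric(a)
  structure(list(accuracies = out_acc, posterior = post,
                 log_likelihood = ll_trace, converged = converged,
                 class_prior = pi1),
            class = "label_model")
}

#' @export
print.label_model <- function(x, ...) {
  cat("<label_model> EM over", length(x$accuracies), "labeling functions\n")
  cat("  accuracies:", paste(sprintf("%s=%.3f", names(x$accuracies), x$accuracies),
                             collapse = " "), "\n")
  cat(sprintf("  iterations: %d (converged: %s)\n",
              length(x$log_likelihood), x$converged))
  invisible(x)
}
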