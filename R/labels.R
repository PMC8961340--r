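#' Note-level multi-hot label container
#'
#' A thin matrix class holding one 0/1 row per note over an ordered
#' category set (default R00..R09), tagged with its label source. All
#' labeling routes (`icd`, `weak`, `hybrid`, ground `truth`) emit this
#' container so downstream training and evaluation are source-agnostic.
#'
#' @param x Integer/numeric matrix of 0/1 values, notes in rows.
#' @param note_ids Character row identifiers.
#' @param categories Ordered category names (columns).
#' @param source One of `"icd"`, `"weak"`, `"hybrid"`, `"truth"`.
#' @return An integer matrix of class `label_matrix` with `source`
#'   attribute, rownames = note ids, colnames = categories.
#' @export
label_matrix <- function(x, note_ids, categories = target_categories(),
                         source = c("icd", "weak", "hybrid", "truth")) {
  source <- match.arg(source)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) != length(note_ids)) stop("note_ids length must match rows")
  if (ncol(x) != length(categories)) stop("categories length must match columns")
  if (length(x) && !all(x %in% c(0L, 1L))) stop("labels must be 0/1")
  dimnames(x) <- list(as.character(note_ids), categories)
  attr(x, "source") <- source
  class(x) <- c("label_matrix", class(x))
  x
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d notes x %d categories, source=%s\n",
              nrow(x), ncol(x), attr(x, "source")))
  if (nrow(x)) {
    prev <- colMeans(x)
    cat("  prevalence:", paste(sprintf("%s=%.3f", colnames(x), prev), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`[.label_matrix` <- function(x, i, j, ..., drop = FALSE) {
  src <- attr(x, "source")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "source") <- src
    class(out) <- c("label_matrix", class(out))
  }
  out
}

#' Source tag of a label matrix
#' @param x A `label_matrix`.
#' @return Character scalar.
#' @export
label_source <- function(x) attr(x, "source")
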