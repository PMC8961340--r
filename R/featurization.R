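#' Fit a vocabulary over a tokenized corpus
#'
#' Collects the tokens appearing in at least `min_df` documents, ordered
#' lexicographically, together with their document frequencies. The
#' vocabulary defines the column space of the bag-of-words and TF-IDF
#' matrices.
#'
#' @param tokenized A `tokenized_notes` list (or any list of token
#'   vectors).
#' @param min_df Minimum document frequency (default 1).
#' @return List of class `vocabulary`: `terms` (sorted), `df` (document
#'   frequencies), `n_docs`.
#' @export
fit_vocabulary <- function(tokenized, min_df = 1L) {
  if (!length(tokenized)) stop("cannot fit a vocabulary on an empty corpus")
  df <- table(unlist(lapply(tokenized, unique), use.names = FALSE))
  keep <- df >= min_df
  if (!any(keep)) warning("no token reaches min_df = ", min_df,
                          "; vocabulary is empty")
  terms <- sort(names(df)[keep])
  structure(list(terms = terms,
                 df = setNames(as.integer(df[terms]), terms),
                 n_docs = length(tokenized)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms over %d documents\n",
              length(x$terms), x$n_docs))
  invisible(x)
}

#' Bag-of-words count matrix
#'
#' One row per document, one column per vocabulary term; cell values are
#' raw within-document counts. Out-of-vocabulary tokens are ignored.
#'
#' @param tokenized List of token vectors (named by note id).
#' @param vocab A [fit_vocabulary()] result.
#' @return A sparse `dgCMatrix` (documents x terms) with dimnames.
#' @export
bow_matrix <- function(tokenized, vocab) {
  lens <- lengths(tokenized)
  flat <- unlist(tokenized, use.names = FALSE)
  doc <- rep.int(seq_along(tokenized), lens)
  j <- match(flat, vocab$terms)
  keep <- !is.na(j)
  # duplicated (i, j) triplets are summed on coercion to column-compressed
  # form, turning per-occurrence 1s into counts
  Matrix::sparseMatrix(i = doc[keep], j = j[keep], x = 1,
                       dims = c(length(tokenized), length(vocab$terms)),
                       dimnames = list(names(tokenized), vocab$terms))
}

#' TF-IDF weighting of a count matrix
#'
#' Reweights bag-of-words counts by smoothed inverse document frequency,
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, then L2-normalizes each
#' document row. A term present in every document gets the minimal
#' weight `idf = 1`; idf never increases with document frequency.
#' All-zero rows stay all-zero.
#'
#' @param counts Document-by-term count matrix from [bow_matrix()].
#' @param vocab The vocabulary the counts were built from; its stored
#'   document frequencies and corpus size define the idf (so test
#'   documents are weighted with training-corpus statistics).
#' @return Sparse matrix of the same shape, rows L2-normalized.
#' @export
tfidf_transform <- function(counts, vocab) {
  stopifnot(ncol(counts) == length(vocab$terms))
  idf <- log((1 + vocab$n_docs) / (1 + as.numeric(vocab$df))) + 1
  w <- counts %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(w^2))
  norms[norms == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / norms) %*% w
  dimnames(out) <- dimnames(counts)
  methods::as(out, "CsparseMatrix")
}

#' Average word embeddings into document vectors
#'
#' The continuous-bag-of-words featurization: each in-table token
#' contributes its word vector and the document vector is the unweighted
#' arithmetic mean over token occurrences (duplicates counted). Tokens
#' absent from the table are skipped; an empty or all-out-of-vocabulary
#' document yields the zero vector.
#'
#' @param tokenized List of token vectors (named by note id).
#' @param table An `embedding_table` (see [read_embeddings()] /
#'   [train_word_embeddings()]).
#' @return Dense numeric matrix, documents x embedding dimension.
#' @export
cbow_doc_vectors <- function(tokenized, table) {
  dim <- ncol(table$vectors)
  out <- matrix(0, nrow = length(tokenized), ncol = dim,
                dimnames = list(names(tokenized), NULL))
  for (d in seq_along(tokenized)) {
    j <- match(tokenized[[d]], rownames(table$vectors))
    j <- j[!is.na(j)]
    if (length(j)) out[d, ] <- colMeans(table$vectors[j, , drop = FALSE])
  }
  out
}

#' Read and write word embeddings in the standard text format
#'
#' The format is the plain-text word-vector convention: a header line
#' `"<vocab size> <dimension>"`, then one token followed by its
#' whitespace-separated coordinates per line. [read_embeddings()] accepts
#' any such file (e.g. externally pretrained biomedical vectors).
#'
#' @param path File path.
#' @return An `embedding_table`: list with `vectors` (matrix, tokens in
#'   rownames) and `dim`.
#' @export
read_embeddings <- function(path) {
  header <- scan(path, what = integer(), n = 2, quiet = TRUE)
  dat <- read.table(path, skip = 1, header = FALSE,
                    colClasses = c("character", rep("numeric", header[2])),
                    quote = "", comment.char = "")
  m <- as.matrix(dat[, -1, drop = FALSE])
  if (any(!is.finite(m))) stop(path, ": non-finite embedding entries")
  rownames(m) <- dat[[1]]
  colnames(m) <- NULL
  embedding_table(m)
}

#' @rdname read_embeddings
#' @param table An `embedding_table`.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(table$vectors), ncol(table$vectors)), con)
  apply_rows <- vapply(seq_len(nrow(table$vectors)), function(i) {
    paste(c(rownames(table$vectors)[i],
            formatC(table$vectors[i, ], format = "g", digits = 8)),
          collapse = " ")
  }, character(1))
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname read_embeddings
#' @param vectors Numeric matrix with tokens as rownames.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            all(is.finite(vectors)))
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d tokens, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Write a document-feature matrix to disk
#'
#' Sparse matrices (bag-of-words, TF-IDF) are written in MatrixMarket
#' format; dense embedding matrices as CSV. Row identifiers go to a
#' side file `<path>.rownames` for MatrixMarket output.
#'
#' @param m Feature matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_features <- function(m, path) {
  if (methods::is(m, "sparseMatrix")) {
    Matrix::writeMM(m, path)
    writeLines(rownames(m), paste0(path, ".rownames"))
  } else {
    write.csv(data.frame(note_id = rownames(m), m, check.names = FALSE),
              path, row.names = FALSE)
  }
  invisible(path)
}
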