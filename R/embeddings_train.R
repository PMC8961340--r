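# shared corpus flattening for the embedding trainers
.flatten_corpus <- function(tokenized, min_count) {
  flat <- unlist(tokenized, use.names = FALSE)
  if (!length(flat)) stop("empty corpus: nothing to train embeddings on")
  freq <- table(flat)
  keep <- names(freq)[freq >= min_count]
  if (!length(keep)) {
    stop("no token reaches min_count = ", min_count,
         "; corpus too small for embedding training")
  }
  keep <- sort(keep)
  ids <- match(flat, keep)            # NA for dropped tokens
  lens <- lengths(tokenized)
  doc <- rep.int(seq_along(tokenized), lens)
  ok <- !is.na(ids)
  ids <- ids[ok]; doc <- doc[ok]
  doc_start <- c(0L, cumsum(tabulate(doc, nbins = length(tokenized))))
  list(words = ids - 1L, doc_start = as.integer(doc_start),
       terms = keep, freq = as.numeric(freq[keep]))
}

#' Train PV-DBOW paragraph vectors on a corpus
#'
#' Distributed bag-of-words paragraph-vector training: each document owns
#' a trainable vector that is optimized (by negative-sampling SGD) to
#' predict the words the document contains. Document vectors have a
#' fixed dimension (default 300) independent of corpus size. Training is
#' single-threaded and seeded, so identical seeds give bitwise-identical
#' vectors.
#'
#' @param tokenized A `tokenized_notes` list.
#' @param dimension Document-vector length (default 300).
#' @param epochs Training passes over the corpus (default 20).
#' @param min_count Minimum corpus frequency for a word to participate
#'   (default 2).
#' @param negative Negative samples per positive pair (default 5).
#' @param alpha Initial learning rate (default 0.025, linear decay).
#' @param seed Integer seed.
#' @return A `pvdbow_model`: `doc_vectors` (matrix, note ids in
#'   rownames), plus frozen word output vectors and vocabulary needed by
#'   [infer_doc_vectors()].
#' @export
train_doc_embeddings <- function(tokenized, dimension = 300L, epochs = 20L,
                                 min_count = 2L, negative = 5L,
                                 alpha = 0.025, seed = 1L) {
  fc <- .flatten_corpus(tokenized, min_count)
  fit <- cpp_pvdbow_train(fc$words, fc$doc_start, length(fc$terms), fc$freq,
                          as.integer(dimension), as.integer(epochs), alpha,
                          as.integer(negative), as.integer(seed))
  dv <- fit$doc_vectors
  rownames(dv) <- names(tokenized)
  structure(list(doc_vectors = dv, output_vectors = fit$output_vectors,
                 terms = fc$terms, freq = fc$freq,
                 dimension = as.integer(dimension),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, seed = as.integer(seed)),
            class = "pvdbow_model")
}

#' @export
print.pvdbow_model <- function(x, ...) {
  cat(sprintf("<pvdbow_model> %d documents, dimension %d, vocab %d\n",
              nrow(x$doc_vectors), x$dimension, length(x$terms)))
  invisible(x)
}

#' Infer PV-DBOW vectors for new documents
#'
#' Freezes the trained word output vectors and optimizes a fresh
#' document vector per input note with the same negative-sampling
#' objective. Out-of-vocabulary tokens are skipped.
#'
#' @param model A `pvdbow_model` from [train_doc_embeddings()].
#' @param tokenized List of token vectors for the new documents.
#' @param epochs Inference passes per document (default: the model's
#'   training epochs).
#' @param seed Integer seed.
#' @return Dense matrix, documents x dimension, note ids in rownames.
#' @export
infer_doc_vectors <- function(model, tokenized, epochs = NULL, seed = 1L) {
  if (is.null(epochs)) epochs <- model$epochs
  flat <- unlist(tokenized, use.names = FALSE)
  ids <- match(flat, model$terms)
  lens <- lengths(tokenized)
  doc <- rep.int(seq_along(tokenized), lens)
  ok <- !is.na(ids)
  ids <- ids[ok]; doc <- doc[ok]
  doc_start <- c(0L, cumsum(tabulate(doc, nbins = length(tokenized))))
  dv <- cpp_pvdbow_infer(ids - 1L, as.integer(doc_start),
                         model$output_vectors, model$freq, model$dimension,
                         as.integer(epochs), model$alpha, model$negative,
                         as.integer(seed))
  rownames(dv) <- names(tokenized)
  dv
}

#' Train CBOW word embeddings on a corpus
#'
#' Standard continuous-bag-of-words word2vec with negative sampling,
#' used to build a local [embedding_table()] when no pretrained
#' biomedical matrix is supplied. Deterministic for a fixed seed.
#'
#' @inheritParams train_doc_embeddings
#' @param dimension Word-vector length (default 200).
#' @param window Maximum context half-window (default 5).
#' @return An `embedding_table` over the retained vocabulary.
#' @export
train_word_embeddings <- function(tokenized, dimension = 200L, epochs = 10L,
                                  window = 5L, min_count = 2L, negative = 5L,
                                  alpha = 0.025, seed = 1L) {
  stopifnot(window >= 1L)
  fc <- .flatten_corpus(tokenized, min_count)
  wv <- cpp_cbow_train(fc$words, fc$doc_start, length(fc$terms), fc$freq,
                       as.integer(dimension), as.integer(epochs), alpha,
                       as.integer(window), as.integer(negative),
                       as.integer(seed))
  rownames(wv) <- fc$terms
  embedding_table(wv)
}
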