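test_that("vocabulary fitting honors min_df and sorts terms", {
  docs <- as_tokenized(list(d1 = c("a", "b"), d2 = c("a")))
  v1 <- fit_vocabulary(docs, min_df = 1)
  expect_identical(v1$terms, c("a", "b"))
  expect_identical(unname(v1$df), c(2L, 1L))
  v2 <- fit_vocabulary(docs, min_df = 2)
  expect_identical(v2$terms, "a")
  expect_warning(v3 <- fit_vocabulary(docs, min_df = 3), "empty")
  expect_length(v3$terms, 0)
  expect_error(fit_vocabulary(list()), "empty corpus")
})

test_that("bag-of-words counts are exact and OOV-silent", {
  vocab <- fit_vocabulary(as_tokenized(list(d = c("a", "b", "c"))))
  m <- bow_matrix(list(x = c("a", "b", "a"), y = character(), z = "q"), vocab)
  expect_identical(as.numeric(m["x", ]), c(2, 1, 0))
  expect_identical(Matrix::rowSums(m)[c("y", "z")], c(y = 0, z = 0))
  expect_identical(dim(m), c(3L, 3L))
})

test_that("tfidf applies the smoothed-idf formula with L2 rows", {
  docs <- as_tokenized(list(d1 = c("a", "b"), d2 = c("a")))
  vocab <- fit_vocabulary(docs)
  counts <- bow_matrix(docs, vocab)
  w <- tfidf_transform(counts, vocab)
  # hand evaluation: idf(a) = ln(3/3)+1 = 1 (present everywhere -> minimal),
  # idf(b) = ln(3/2)+1; d1 pre-normalization = (1, ln(3/2)+1)
  idf_b <- log(3 / 2) + 1
  raw <- c(1, idf_b)
  expect_equal(as.numeric(w["d1", ]), raw / sqrt(sum(raw^2)), tolerance = 1e-12)
  expect_equal(as.numeric(w["d2", ]), c(1, 0))
  expect_equal(Matrix::rowSums(w^2), c(d1 = 1, d2 = 1), tolerance = 1e-12)
  # idf is non-increasing in document frequency
  idf <- log((1 + vocab$n_docs) / (1 + as.numeric(vocab$df))) + 1
  expect_true(idf[1] <= idf[2])
  # all-zero row survives normalization untouched
  z <- bow_matrix(list(zz = "oov"), vocab)
  expect_identical(sum(tfidf_transform(z, vocab)), 0)
})

test_that("single-document tfidf is proportional to its counts", {
  docs <- as_tokenized(list(d = c("a", "a", "b", "c")))
  vocab <- fit_vocabulary(docs)
  w <- as.numeric(tfidf_transform(bow_matrix(docs, vocab), vocab))
  counts <- c(2, 1, 1)
  expect_equal(w, counts / sqrt(sum(counts^2)), tolerance = 1e-12)
})

test_that("embedding averages honor the unweighted-mean and OOV rules", {
  tab <- embedding_table(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                                dimnames = list(c("a", "b"), NULL)))
  m <- cbow_doc_vectors(list(x = c("a", "b"), y = c("a", "a"), z = "q",
                             e = character()), tab)
  expect_equal(m["x", ], c(0.5, 0.5))
  expect_equal(m["y", ], c(1, 0))
  expect_equal(m["z", ], c(0, 0))
  expect_equal(m["e", ], c(0, 0))
})

test_that("embedding tables round-trip through the text format", {
  withr::with_seed(7, {
    tab <- embedding_table(matrix(rnorm(12), 3, 4,
                                  dimnames = list(c("ab", "cd", "ef"), NULL)))
  })
  p <- file.path(withr::local_tempdir(), "vecs.txt")
  write_embeddings(tab, p)
  back <- read_embeddings(p)
  expect_identical(rownames(back$vectors), rownames(tab$vectors))
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-6)
})

make_embed_corpus <- function(n_docs = 60, seed = 5) {
  withr::with_seed(seed, {
    filler <- filler_words(20)
    docs <- lapply(seq_len(n_docs), function(i) {
      base <- sample(filler, 30, replace = TRUE)
      if (i %% 3 == 0) base <- c(base, rep(c("cough", "sputum"), 4))
      sample(base)
    })
    names(docs) <- sprintf("d%03d", seq_len(n_docs))
    as_tokenized(docs)
  })
}

test_that("paragraph vectors have fixed dimension and are seed-stable", {
  docs <- make_embed_corpus()
  m1 <- train_doc_embeddings(docs, dimension = 32, epochs = 3, seed = 7)
  m2 <- train_doc_embeddings(docs, dimension = 32, epochs = 3, seed = 7)
  expect_identical(m1$doc_vectors, m2$doc_vectors)     # bitwise
  expect_identical(dim(m1$doc_vectors), c(60L, 32L))
  m3 <- train_doc_embeddings(docs, dimension = 32, epochs = 3, seed = 8)
  expect_false(identical(m1$doc_vectors, m3$doc_vectors))
  # inference: same dimension, deterministic, OOV-robust
  new <- list(a = c("cough", "sputum", "zzz"), b = character())
  v1 <- infer_doc_vectors(m1, new, seed = 3)
  v2 <- infer_doc_vectors(m1, new, seed = 3)
  expect_identical(v1, v2)
  expect_identical(dim(v1), c(2L, 32L))
  expect_error(train_doc_embeddings(as_tokenized(list(a = "x")),
                                    min_count = 2), "min_count")
})

test_that("documents sharing injected vocabulary cluster in embedding space", {
  docs <- make_embed_corpus(n_docs = 90, seed = 11)
  m <- train_doc_embeddings(docs, dimension = 48, epochs = 12, seed = 2)
  grp <- seq_len(90) %% 3 == 0
  v <- m$doc_vectors / sqrt(rowSums(m$doc_vectors^2))
  cos <- tcrossprod(v)
  within <- mean(cos[grp, grp][upper.tri(cos[grp, grp])])
  between <- mean(cos[grp, !grp])
  expect_gt(within, between)
})

test_that("embedding dimensions are corpus-size independent", {
  for (n in c(10, 100)) {
    docs <- make_embed_corpus(n_docs = n, seed = n)
    m <- train_doc_embeddings(docs, dimension = 16, epochs = 2, seed = 1)
    expect_identical(ncol(m$doc_vectors), 16L)
    tab <- train_word_embeddings(docs, dimension = 12, epochs = 2, seed = 1)
    expect_identical(ncol(tab$vectors), 12L)
  }
})

test_that("cbow training is deterministic under a fixed seed", {
  docs <- make_embed_corpus()
  t1 <- train_word_embeddings(docs, dimension = 16, epochs = 3, seed = 5)
  t2 <- train_word_embeddings(docs, dimension = 16, epochs = 3, seed = 5)
  expect_identical(t1$vectors, t2$vectors)
})
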