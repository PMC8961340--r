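# pairwise-counting AUROC oracle: ties count one half
auroc_brute <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("AUROC handles perfect, inverted, and tied rankings", {
  y <- matrix(c(1, 0, 1, 0), ncol = 1)
  s <- matrix(c(0.9, 0.1, 0.8, 0.2), ncol = 1)
  suppressWarnings(r <- compute_metrics(y, s))
  expect_identical(r$per_class$auroc, 1)
  expect_identical(r$per_class$recall, 1)
  suppressWarnings(r2 <- compute_metrics(matrix(c(1, 0), ncol = 1),
                                         matrix(c(0.2, 0.9), ncol = 1)))
  expect_identical(r2$per_class$auroc, 0)
  # all-tied scores: AUROC 1/2 by the tie convention
  suppressWarnings(r3 <- compute_metrics(y, matrix(0.5, 4, 1)))
  expect_identical(r3$per_class$auroc, 0.5)
})

test_that("AUROC equals the pairwise-counting oracle on fuzz data", {
  withr::with_seed(2024, {
    for (i in 1:30) {
      n <- sample(10:200, 1)
      y <- matrix(rbinom(n, 1, runif(1, 0.1, 0.9)), ncol = 1)
      s <- matrix(round(runif(n), sample(c(1, 2, 6), 1)), ncol = 1)
      if (sum(y) == 0 || sum(y) == n) next
      r <- compute_metrics(y, s)
      expect_equal(r$per_class$auroc, auroc_brute(y[, 1], s[, 1]),
                   tolerance = 1e-10)
    }
  })
})

test_that("recall, precision and F1 match a hand-computed contingency", {
  # 6 test notes: TP=2, FN=1, FP=1, TN=2
  y <- matrix(c(1, 1, 1, 0, 0, 0), ncol = 1, dimnames = list(NULL, "R05"))
  p <- matrix(c(1, 1, 0, 1, 0, 0), ncol = 1)
  s <- matrix(c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1), ncol = 1)
  r <- compute_metrics(y, s, p)
  expect_equal(r$per_class$recall, 2 / 3)
  expect_equal(r$per_class$precision, 2 / 3)
  expect_equal(r$per_class$f1, 2 / 3)
  expect_equal(r$per_class$prevalence, 0.5)
  # average precision by hand over descending thresholds:
  # ranks: 0.9(+) 0.8(+) 0.7(-) 0.3(+) -> AP = 1/3*1 + 1/3*1 + 1/3*(3/4)
  expect_equal(r$per_class$average_precision, 1 / 3 + 1 / 3 + 1 / 4)
})

test_that("average precision is invariant under monotone score transforms", {
  withr::with_seed(5, {
    for (i in 1:10) {
      y <- matrix(rbinom(80, 1, 0.3), ncol = 1)
      if (sum(y) %in% c(0, 80)) next
      s <- matrix(runif(80), ncol = 1)
      a <- compute_metrics(y, s)$per_class$average_precision
      b <- compute_metrics(y, plogis(5 * s - 1))$per_class$average_precision
      expect_equal(a, b, tolerance = 1e-12)
    }
  })
})

test_that("macro metrics equal the mean over non-degenerate classes", {
  withr::with_seed(8, {
    y <- cbind(a = rbinom(60, 1, 0.4), b = rbinom(60, 1, 0.3), c = 0L)
    s <- matrix(runif(180), 60, 3)
    suppressWarnings(r <- compute_metrics(y, s))
    expect_identical(r$degenerate, "c")
    expect_equal(r$macro[["recall"]], mean(r$per_class$recall[1:2]))
    expect_equal(r$macro[["auroc"]], mean(r$per_class$auroc[1:2]))
  })
})

test_that("score deltas subtract metric-wise with NA propagation", {
  withr::with_seed(9, {
    y <- cbind(a = rbinom(50, 1, 0.5), b = rbinom(50, 1, 0.3))
    sa <- matrix(runif(100), 50); sb <- matrix(runif(100), 50)
    ra <- compute_metrics(y, sa); rb <- compute_metrics(y, sb)
    d0 <- score_delta(ra, ra)
    expect_true(all(as.matrix(d0$per_class[, -1]) == 0))
    d <- score_delta(ra, rb)
    expect_equal(d$per_class$recall,
                 ra$per_class$recall - rb$per_class$recall)
    rc <- compute_metrics(y[, 1, drop = FALSE], sa[, 1, drop = FALSE])
    expect_error(score_delta(ra, rc), "different category")
    # degenerate class in one report -> flagged missing delta
    y2 <- cbind(a = y[, 1], b = 0L)
    suppressWarnings(rd <- compute_metrics(y2, sb))
    dm <- score_delta(ra, rd)
    expect_identical(dm$missing, "b")
    expect_true(is.na(dm$per_class$recall[2]))
  })
})

test_that("majority voting follows the strict-majority and tie rules", {
  expect_identical(mentions_to_note_label(c("positive", "positive",
                                            "negative")), 1L)
  expect_identical(mentions_to_note_label(c("positive", "negative")), 0L)
  expect_identical(mentions_to_note_label(character()), 0L)
  # uncertain counts against positivity
  expect_identical(mentions_to_note_label(c("positive", "uncertain")), 0L)
  expect_identical(mentions_to_note_label(c("positive", "positive",
                                            "uncertain")), 1L)
  expect_error(mentions_to_note_label("maybe"), "unknown polarity")
})

test_that("standoff and BRAT annotations reduce to note labels", {
  td <- withr::local_tempdir()
  sp <- file.path(td, "ann.csv")
  writeLines(c("note_id,start,end,polarity,category",
               "n1,0,5,positive,R05",
               "n1,10,15,positive,R05",
               "n1,20,25,negative,R05",
               "n1,3,9,negative,R06",
               "n2,1,4,positive,R07"), sp)
  ann <- read_standoff(sp)
  lab <- annotations_to_labels(ann, note_ids = c("n1", "n2", "n3"))
  expect_identical(unname(unclass(lab)["n1", c("R05", "R06")]), c(1L, 0L))
  expect_identical(unname(unclass(lab)["n2", "R07"]), 1L)
  expect_identical(sum(lab["n3", ]), 0L)
  expect_identical(label_source(lab), "truth")
  bp <- file.path(td, "doc.ann")
  writeLines(c("T1\tR05_Positive 10 15\tcough",
               "T2\tR06_Negative 30 47\tshortness of breath",
               "#1\tAnnotatorNotes T1\tcomment"), bp)
  brat <- read_brat_ann(bp, note_id = "doc1")
  expect_identical(nrow(brat), 2L)
  expect_identical(brat$polarity, c("positive", "negative"))
  expect_identical(brat$category, c("R05", "R06"))
})

test_that("prevalence-recall profiles summarize flatness by slope", {
  mk_report <- function(recalls, prevs) {
    y <- do.call(cbind, lapply(prevs, function(p) {
      as.integer(seq_len(200) <= round(200 * p))
    }))
    colnames(y) <- names(prevs)
    s <- matrix(runif(length(y)), nrow(y))
    r <- compute_metrics(y, s)
    r$per_class$recall <- recalls
    r
  }
  prevs <- c(R05 = 0.1, R06 = 0.05, R07 = 0.02)
  withr::with_seed(3, {
    flat <- mk_report(c(0.8, 0.8, 0.8), prevs)
    steep <- mk_report(c(0.9, 0.5, 0.1), prevs)
  })
  prof <- prevalence_recall_profile(list(`1000` = steep, `20000` = flat))
  expect_identical(nrow(prof$table), 6L)
  expect_equal(prof$slopes[["20000"]], 0)
  expect_gt(abs(prof$slopes[["1000"]]), 0)
  single <- prevalence_recall_profile(list(only = flat))
  expect_identical(nrow(single$table), 3L)
})
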