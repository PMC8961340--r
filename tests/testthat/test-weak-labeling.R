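dict <- toy_dictionary()
term <- toy_terminology()

test_that("dictionary matching is longest-first, leftmost, non-overlapping", {
  m <- detect_mentions(c("no", "cough", "today"), dict, note_id = "x")
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$start, m$end), c(2L, 2L))
  expect_identical(m$category, "R05")

  # longest-match precedence: "chest pain" wins over a 1-gram subset
  d2 <- concept_dictionary(c("chest pain", "pain"), c("C-A", "C-B"),
                           c("R07", "R07"))
  m2 <- detect_mentions(c("chest", "pain"), d2)
  expect_identical(nrow(m2), 1L)
  expect_identical(c(m2$start, m2$end), c(1L, 2L))
  expect_identical(m2$concept_id, "C-A")

  # non-overlap: overlapping shorter candidate suppressed, later one kept
  m3 <- detect_mentions(c("chest", "pain", "pain"), d2)
  expect_identical(m3$start, c(1L, 3L))

  expect_identical(nrow(detect_mentions(character(), dict)), 0L)
  expect_identical(nrow(detect_mentions(c("a", "b"), dict[0, ])), 0L)
})

test_that("fuzzy concept mapping maximizes Jaccard with stated tie-breaks", {
  d <- concept_dictionary(c("shortness of breath", "chest pain"),
                          c("C-R06", "C-R07"), c("R06", "R07"))
  expect_identical(map_to_category("cough", toy_dictionary())$similarity, 1)
  hit <- map_to_category(c("short", "breath"), d, min_similarity = 0.1)
  expect_identical(hit$category, "R06")
  # threshold boundary: exact-only matching at 1.0
  expect_null(map_to_category("chest", d, min_similarity = 1.0))
  # tie resolves to the lexicographically smallest concept_id
  dt <- concept_dictionary(c("cough fit", "cough spell"),
                           c("C-B", "C-A"), c("R05", "R05"))
  expect_identical(map_to_category("cough", dt, min_similarity = 0.1)$concept_id,
                   "C-A")
})

test_that("context windows clip at boundaries and exclude the mention", {
  toks <- paste0("t", 1:30)
  w <- extract_context(toks, 13, 13, width = 10)
  expect_identical(w$before, paste0("t", 3:12))
  expect_identical(w$after, paste0("t", 14:23))
  w2 <- extract_context(paste0("t", 1:5), 5, 5, width = 10)
  expect_identical(w2$before, paste0("t", 1:4))
  expect_identical(w2$after, character())
  w3 <- extract_context(toks, 1, 1, width = 10)
  expect_identical(w3$before, character())
})

test_that("labeling functions fire on their triggers with distances", {
  v <- apply_labeling_functions(list(before = c("patient", "deni"),
                                     after = character()), term)
  expect_identical(v$fired, c(TRUE, FALSE, FALSE))
  expect_identical(v$distance[1], 1L)
  v2 <- apply_labeling_functions(list(before = c("father", "visit"),
                                      after = character()), term)
  expect_identical(v2$fired, c(FALSE, FALSE, TRUE))
  expect_identical(v2$distance[3], 2L)
  v3 <- apply_labeling_functions(list(before = character(),
                                      after = character()), term)
  expect_false(any(v3$fired))
  # multi-token trigger in the after window
  v4 <- apply_labeling_functions(list(before = character(),
                                      after = c("but", "no", "evid")), term)
  expect_identical(v4$distance[1], 2L)
})

test_that("mention labels resolve by nearest trigger then precedence", {
  mk <- function(neg = NA, hist = NA, fam = NA) {
    data.frame(lf = c("negation", "historical", "family"),
               fired = !is.na(c(neg, hist, fam)),
               distance = as.integer(c(neg, hist, fam)))
  }
  expect_identical(resolve_mention_label(mk()), "positive")
  expect_identical(resolve_mention_label(mk(neg = 2)), "absent")
  expect_identical(resolve_mention_label(mk(hist = 4)), "history")
  expect_identical(resolve_mention_label(mk(fam = 1)), "family")
  # nearest wins
  expect_identical(resolve_mention_label(mk(neg = 3, hist = 1)), "history")
  # distance tie: absent > history > family
  expect_identical(resolve_mention_label(mk(neg = 2, hist = 2)), "absent")
  expect_identical(resolve_mention_label(mk(hist = 5, fam = 5)), "history")
})

test_that("note aggregation is any-positive and adding positives is monotone", {
  ml <- data.frame(category = c("R05", "R05"),
                   label = c("positive", "absent"))
  v <- aggregate_note_labels(ml, "n1")
  expect_identical(unname(unclass(v)[1, "R05"]), 1L)
  v2 <- aggregate_note_labels(data.frame(category = "R06", label = "history"),
                              "n1")
  expect_identical(sum(v2), 0L)
  expect_identical(sum(aggregate_note_labels(
    data.frame(category = character(), label = character()), "n1")), 0L)
  withr::with_seed(5, {
    for (i in 1:30) {
      labs <- sample(c("positive", "absent", "history", "family"), 6, TRUE)
      cats <- sample(c("R05", "R06", "R07"), 6, TRUE)
      base <- data.frame(category = cats, label = labs)
      more <- rbind(base, data.frame(category = sample(c("R05", "R06"), 1),
                                     label = "positive"))
      expect_true(all(aggregate_note_labels(more, "n") >=
                        aggregate_note_labels(base, "n")))
    }
  })
})

test_that("pipeline labels agree with the brute-force reference on snippets", {
  battery <- snippet_battery()
  expect_gte(length(battery), 200L)
  for (sn in battery) {
    got <- pipeline_label(sn$tokens, sn$dict, sn$term)
    want <- brute_force_label(sn$tokens, sn$start, sn$end, sn$term)
    expect_identical(got, want, label = sn$case)
  }
})

test_that("triggers beyond the 10-token window never affect the label", {
  for (side in c(1, -1)) {
    for (d in c(1L, 5L, 10L)) {
      sn <- build_snippet("cough", n_tokens = 40, mention_at = 15,
                          triggers = list(list(phrase = "deni",
                                               distance = side * d)))
      expect_identical(pipeline_label(sn$tokens, dict, term), "absent")
    }
    sn11 <- build_snippet("cough", n_tokens = 40, mention_at = 15,
                          triggers = list(list(phrase = "deni",
                                               distance = side * 11L)))
    expect_identical(pipeline_label(sn11$tokens, dict, term), "positive")
  }
})

test_that("a custom detector can replace the dictionary matcher", {
  toks <- list(n1 = c("x", "cough", "y"))
  det <- function(tokens, note_id) {
    data.frame(note_id = note_id, start = 2L, end = 2L, surface = "cough",
               concept_id = "EXT-1", category = "R09",
               stringsAsFactors = FALSE)
  }
  lab <- weak_label_notes(as_tokenized(toks), dict, term, detector = det)
  expect_identical(unname(unclass(lab)[1, "R09"]), 1L)
  expect_identical(sum(lab), 1L)
})
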