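test_that("generation is byte-deterministic under a fixed config", {
  cfg <- generator_config(n_patients = 40, seed = 123,
                          categories = c("R05", "R06"))
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$notes$text, s2$notes$text)
  expect_identical(s1$encounters$icd_codes, s2$encounters$icd_codes)
  expect_identical(unclass(s1$truth), unclass(s2$truth))
  td <- withr::local_tempdir()
  write_corpus(s1$notes, s1$encounters, file.path(td, "a.csv"),
               file.path(td, "b.csv"))
  write_corpus(s2$notes, s2$encounters, file.path(td, "c.csv"),
               file.path(td, "d.csv"))
  expect_identical(tools::md5sum(file.path(td, "a.csv"))[[1]],
                   tools::md5sum(file.path(td, "c.csv"))[[1]])
  s3 <- generate_corpus(generator_config(n_patients = 40, seed = 124,
                                         categories = c("R05", "R06")))
  expect_false(identical(s1$notes$text, s3$notes$text))
})

test_that("an all-negated context mix yields mention text but zero truth", {
  cfg <- generator_config(n_patients = 60, seed = 5,
                          categories = c("R05", "R06"),
                          prevalence = c(R05 = 0.3, R06 = 0.2),
                          context_mix = c(positive = 0, negated = 1,
                                          historical = 0, family = 0))
  sim <- generate_corpus(cfg)
  expect_identical(sum(sim$truth), 0L)
  expect_gt(nrow(sim$mentions), 0)
  expect_true(all(sim$mentions$context == "negated"))
})

test_that("empirical truth prevalence stays inside the 99% binomial band", {
  prev <- c(R05 = 0.10, R06 = 0.05, R07 = 0.02)
  cfg <- generator_config(n_patients = 10000, notes_per_patient = c(1, 1),
                          categories = names(prev), prevalence = prev,
                          seed = 31)
  sim <- generate_corpus(cfg)
  n <- nrow(sim$truth)
  for (k in names(prev)) {
    ci <- qbinom(c(0.005, 0.995), n, prev[[k]]) / n
    emp <- mean(unclass(sim$truth)[, k])
    expect_gte(emp, ci[1])
    expect_lte(emp, ci[2])
  }
})

test_that("rendered mentions respect their context contract", {
  term <- read_terminology()
  withr::with_seed(44, {
    for (i in 1:20) {
      neg <- normalize_phrase(paste(
        render_mention("R05", "negated"), collapse = " "))
      toks <- strsplit(neg, " ")[[1]]
      men <- detect_mentions(toks, read_concept_dictionary())
      expect_gte(nrow(men), 1)
      # a negation trigger within 10 tokens of the mention
      win <- extract_context(toks, men$start[1], men$end[1], 10)
      v <- apply_labeling_functions(win, term)
      expect_true(v$fired[v$lf == "negation"])
      pos <- normalize_phrase(paste(
        render_mention("R06", "positive"), collapse = " "))
      vp <- apply_labeling_functions(
        list(before = strsplit(pos, " ")[[1]], after = character()), term)
      expect_false(any(vp$fired))
      fam <- normalize_phrase(paste(
        render_mention("R07", "family"), collapse = " "))
      tf <- strsplit(fam, " ")[[1]]
      mf <- detect_mentions(tf, read_concept_dictionary())
      wf <- extract_context(tf, mf$start[1], mf$end[1], 10)
      expect_true(apply_labeling_functions(wf, term)$fired[3])
    }
  })
  expect_error(render_mention("R99", "positive"), "unknown category")
})

test_that("corrupt_codes reproduces exact and degenerate regimes", {
  truth <- label_matrix(matrix(c(1L, 0L, 1L, 0L), 2,
                               dimnames = list(c("n1", "n2"), NULL)),
                        note_ids = c("n1", "n2"),
                        categories = c("R05", "R06"), source = "truth")
  exact <- corrupt_codes(truth, sensitivity = 1, specificity = 1, seed = 2)
  got <- lapply(exact, function(cd) sort(unique(substr(
    cd[startsWith(cd, "R")], 1, 3))))
  expect_identical(got$n1, c("R05", "R06"))
  expect_identical(got$n2, character())
  none <- corrupt_codes(truth, sensitivity = 0, specificity = 1, seed = 2)
  expect_false(any(startsWith(unlist(none), "R")))
})

test_that("coding noise matches configured sensitivity and specificity", {
  n <- 12500
  truth <- label_matrix(
    matrix(c(rep(1L, 10000), rep(0L, 2500), rbinom(n, 1, 0.5)), ncol = 2),
    note_ids = sprintf("n%05d", 1:n), categories = c("R05", "R06"),
    source = "truth")
  codes <- corrupt_codes(truth, sensitivity = 0.4, specificity = 0.99,
                         seed = 77)
  cats <- lapply(codes, function(cd) substr(cd[startsWith(cd, "R")], 1, 3))
  emitted <- vapply(cats, function(x) "R05" %in% x, logical(1))
  tp_cells <- which(unclass(truth)[, "R05"] == 1L)
  tn_cells <- which(unclass(truth)[, "R05"] == 0L)
  sens_hat <- mean(emitted[tp_cells])
  fpr_hat <- mean(emitted[tn_cells])
  ci_s <- qbinom(c(0.005, 0.995), length(tp_cells), 0.4) / length(tp_cells)
  ci_f <- qbinom(c(0.005, 0.995), length(tn_cells), 0.01) / length(tn_cells)
  expect_gte(sens_hat, ci_s[1]); expect_lte(sens_hat, ci_s[2])
  expect_gte(fpr_hat, ci_f[1]); expect_lte(fpr_hat, ci_f[2])
})

test_that("inconsistent generator configs are rejected before generation", {
  expect_error(generator_config(context_mix = c(positive = 0.5, negated = 0.2,
                                                historical = 0.2,
                                                family = 0.2)))
  expect_error(generator_config(prevalence = c(R05 = 0.5), categories = "R05",
                                context_mix = c(positive = 0.05, negated = 0.95,
                                                historical = 0, family = 0),
                                mentions_per_positive = c(1L, 1L)),
               "unreachable")
  expect_error(generator_config(prevalence = c(R05 = 0)))
})
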