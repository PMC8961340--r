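make_filter_fixture <- function() {
  long <- strrep("ab cd ", 100)                  # 600 chars
  exactly350 <- strrep("x", 350)
  exactly349 <- strrep("x", 349)
  notes <- toy_notes(c(long, exactly350, exactly349, long, long))
  encs <- encounters(
    encounter_id = sprintf("e%03d", 1:5),
    patient_id = sprintf("P%03d", 1:5),
    icd_codes = c("R06.02;I10", "R06", "R06", "I10;E11.9", "R05.1"))
  list(notes = notes, encs = encs)
}

test_that("cohort filter enforces length boundary and R-code requirement", {
  fx <- make_filter_fixture()
  suppressMessages(out <- filter_cohort(fx$notes, fx$encs, min_chars = 350))
  # n003 dropped (349 chars), n004 dropped (no R code); 350 chars kept
  expect_identical(out$note_id, c("n001", "n002", "n005"))
})

test_that("cohort filter handles empty input, orphans, and note types", {
  fx <- make_filter_fixture()
  empty <- fx$notes[0, ]
  suppressMessages(expect_identical(
    nrow(filter_cohort(empty, fx$encs)), 0L))
  # orphan encounter: dropped with warning by default, error on request
  orphan <- fx$notes
  orphan$encounter_id[1] <- "missing"
  expect_warning(suppressMessages(
    out <- filter_cohort(orphan, fx$encs, min_chars = 350)),
    "encounter_id")
  expect_false("n001" %in% out$note_id)
  expect_error(suppressMessages(
    filter_cohort(orphan, fx$encs, on_orphan = "error")), "unresolvable")
  # note-type filter
  typed <- fx$notes
  typed$note_type[1] <- "discharge-summary"
  suppressMessages(out2 <- filter_cohort(
    typed, fx$encs, min_chars = 350,
    allowed_note_types = "outpatient-progress"))
  expect_false("n001" %in% out2$note_id)
})

test_that("raising min_chars never enlarges the retained set", {
  fx <- make_filter_fixture()
  prev <- NULL
  for (mc in c(0, 200, 350, 400, 700)) {
    suppressMessages(kept <- filter_cohort(fx$notes, fx$encs,
                                           min_chars = mc)$note_id)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("patient split reproduces largest-remainder sizes", {
  sp <- split_by_patient(sprintf("p%02d", 1:10), c(0.6, 0.2, 0.2), seed = 3)
  expect_identical(as.integer(table(sp$partition)), c(6L, 2L, 2L))
  # 717 patients: the leftover slot goes to the test partition
  sp2 <- split_by_patient(sprintf("p%03d", 1:717), c(0.6, 0.2, 0.2), seed = 9)
  expect_identical(as.integer(table(sp2$partition)), c(430L, 143L, 144L))
  # determinism
  sp3 <- split_by_patient(sprintf("p%03d", 1:717), c(0.6, 0.2, 0.2), seed = 9)
  expect_identical(sp2, sp3)
  expect_error(split_by_patient(c("a", "b"), c(0.6, 0.2, 0.2)), "fewer")
  expect_error(split_by_patient(letters, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("partitions are patient-disjoint across many seeds", {
  ids <- sprintf("p%02d", 1:50)
  for (seed in 1:1000) {
    sp <- split_by_patient(ids, seed = seed)
    parts <- split(sp$patient_id, sp$partition)
    expect_length(intersect(parts$train, parts$validation), 0)
    expect_length(intersect(parts$train, parts$test), 0)
    expect_length(intersect(parts$validation, parts$test), 0)
    expect_setequal(sp$patient_id, ids)
  }
})

test_that("apportioned sizes stay within one of the exact shares", {
  ratios <- c(0.6, 0.2, 0.2)
  for (n in c(3:100, seq(200, 10000, by = 97))) {
    sizes <- symptomweak:::apportion_largest_remainder(n, ratios)
    expect_identical(sum(sizes), as.integer(n))
    expect_true(all(abs(sizes - n * ratios) <= 1 + 1e-9))
  }
})

test_that("corpus files round-trip field for field", {
  fx <- make_filter_fixture()
  td <- withr::local_tempdir()
  np <- file.path(td, "notes.csv"); ep <- file.path(td, "enc.csv")
  write_corpus(fx$notes, fx$encs, np, ep)
  back <- read_corpus(np, ep)
  expect_equal(as.data.frame(back$notes), as.data.frame(fx$notes))
  expect_identical(back$encounters$icd_codes, fx$encs$icd_codes)
  # labels round-trip with their source tag
  lab <- label_matrix(matrix(rbinom(50, 1, 0.3), 5, 10),
                      note_ids = fx$notes$note_id, source = "weak")
  lp <- file.path(td, "labels.csv")
  write_labels(lab, lp)
  back_lab <- read_labels(lp)
  expect_equal(unclass(back_lab), unclass(lab), ignore_attr = TRUE)
  expect_identical(label_source(back_lab), "weak")
})

test_that("malformed corpus records raise errors naming the line", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.csv")
  writeLines(c("note_id,patient_id,encounter_id,date,note_type,text",
               "n1,p1,e1,2020-01-01,prog,hello",
               ",p2,e2,2020-01-02,prog,world"), p)
  expect_error(read_notes(p), "line 3")
  writeLines(c("note_id,patient_id,date,note_type,text",
               "n1,p1,2020-01-01,prog,hello"), p)
  expect_error(read_notes(p), "missing column")
  # empty file with header -> empty collections
  writeLines("note_id,patient_id,encounter_id,date,note_type,text", p)
  expect_identical(nrow(read_notes(p)), 0L)
})
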