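#' @useDynLib symptomweak, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim predict rbinom runif setNames coef lm
#' @importFrom utils head read.csv write.csv
NULL

R_CATEGORIES <- sprintf("R%02d", 0:9)

#' Default symptom category set
#'
#' The ten ICD-10 categories covering symptoms and signs of the circulatory
#' and respiratory systems, `"R00"` through `"R09"`, in fixed order. All
#' label vectors in the package are ordered over this set (or an explicit
#' subset of it).
#'
#' @return Character vector of length 10.
#' @export
target_categories <- function() R_CATEGORIES

#' Construct a table of clinical notes
#'
#' Validates and assembles the canonical note container: one row per note
#' with its patient/encounter linkage and free text. `note_id` must be
#' unique; `text` must be non-NA (empty strings are permitted before
#' cohort filtering).
#'
#' @param note_id,patient_id,encounter_id Character identifiers.
#' @param date Calendar date (`Date` or ISO-8601 string).
#' @param note_type Note-type string, e.g. `"outpatient-progress"`.
#' @param text Free text of the note.
#' @return A `data.frame` of class `clinical_notes`.
#' @export
clinical_notes <- function(note_id, patient_id, encounter_id, date, note_type, text) {
  df <- data.frame(
    note_id = as.character(note_id),
    patient_id = as.character(patient_id),
    encounter_id = as.character(encounter_id),
    date = as.Date(date),
    note_type = as.character(note_type),
    text = as.character(text),
    stringsAsFactors = FALSE
  )
  validate_clinical_notes(df)
}

validate_clinical_notes <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("note_id", "patient_id", "encounter_id", "date", "note_type", "text")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("notes table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$note_id)) stop("note_id values must be unique within a corpus")
  if (anyNA(df$text)) stop("note text must be non-NA")
  class(df) <- unique(c("clinical_notes", class(df)))
  df
}

#' Construct a table of encounters
#'
#' One row per encounter with its ICD-10 code list. Codes arrive as a
#' semicolon-delimited string or a list column; duplicates within an
#' encounter are removed on construction, empty code strings rejected.
#'
#' @param encounter_id,patient_id Character identifiers.
#' @param icd_codes List of character vectors, or a character vector of
#'   semicolon-delimited codes.
#' @return A `data.frame` of class `encounters` with a list column
#'   `icd_codes`.
#' @export
encounters <- function(encounter_id, patient_id, icd_codes) {
  if (is.character(icd_codes)) {
    icd_codes <- lapply(strsplit(icd_codes, ";", fixed = TRUE), function(x) x[nzchar(x)])
  }
  icd_codes <- lapply(icd_codes, function(x) {
    x <- unique(as.character(x))
    if (any(!nzchar(x))) stop("ICD codes must be non-empty strings")
    x
  })
  df <- data.frame(
    encounter_id = as.character(encounter_id),
    patient_id = as.character(patient_id),
    stringsAsFactors = FALSE
  )
  df$icd_codes <- icd_codes
  if (anyDuplicated(df$encounter_id)) stop("encounter_id values must be unique")
  class(df) <- unique(c("encounters", class(df)))
  df
}

#' Filter a note corpus to the modeling cohort
#'
#' Applies the three cohort filters in sequence: note type must be allowed,
#' the linked encounter must carry at least one diagnosis code whose
#' three-character category starts with `required_category_prefix`, and the
#' raw text (before any preprocessing) must be at least `min_chars`
#' characters. Drop counts per reason are reported via `message()`.
#'
#' @param notes A `clinical_notes` table.
#' @param encs An `encounters` table.
#' @param min_chars Minimum raw text length in characters; notes strictly
#'   shorter are discarded. Default 350.
#' @param required_category_prefix Chapter prefix the encounter must carry
#'   (default `"R"`, the ICD-10 symptoms chapter). `NULL` skips this filter.
#' @param allowed_note_types Character set of retained note types; `NULL`
#'   (default) allows all.
#' @param on_orphan What to do with a note whose `encounter_id` does not
#'   resolve: `"drop"` (default, with a warning) or `"error"`.
#' @return The filtered `clinical_notes` table, input order preserved.
#' @export
filter_cohort <- function(notes, encs, min_chars = 350,
                          required_category_prefix = "R",
                          allowed_note_types = NULL,
                          on_orphan = c("drop", "error")) {
  on_orphan <- match.arg(on_orphan)
  notes <- validate_clinical_notes(notes)
  if (nrow(notes) == 0L) return(notes)

  keep <- rep(TRUE, nrow(notes))
  drops <- c(note_type = 0L, orphan = 0L, no_prefix_code = 0L, short = 0L)

  if (!is.null(allowed_note_types)) {
    bad <- !(notes$note_type %in% allowed_note_types)
    drops[["note_type"]] <- sum(bad & keep)
    keep <- keep & !bad
  }

  if (!is.null(required_category_prefix)) {
    idx <- match(notes$encounter_id, encs$encounter_id)
    orphan <- is.na(idx) & keep
    if (any(orphan)) {
      if (on_orphan == "error") {
        stop("unresolvable encounter_id for notes: ",
             paste(head(notes$note_id[orphan], 5L), collapse = ", "))
      }
      warning(sum(orphan), " note(s) dropped: encounter_id not found")
      drops[["orphan"]] <- sum(orphan)
      keep <- keep & !is.na(idx)
    }
    has_code <- vapply(seq_len(nrow(notes)), function(i) {
      if (!keep[i]) return(FALSE)
      codes <- encs$icd_codes[[idx[i]]]
      any(startsWith(toupper(substr(codes, 1L, 3L)), required_category_prefix))
    }, logical(1))
    drops[["no_prefix_code"]] <- sum(keep & !has_code)
    keep <- keep & has_code
  }

  short <- nchar(notes$text) < min_chars
  drops[["short"]] <- sum(keep & short)
  keep <- keep & !short

  message(sprintf(
    "filter_cohort: kept %d/%d notes (dropped: %d note-type, %d orphan, %d no %s-code, %d short)",
    sum(keep), nrow(notes), drops[["note_type"]], drops[["orphan"]],
    drops[["no_prefix_code"]],
    if (is.null(required_category_prefix)) "chapter" else required_category_prefix,
    drops[["short"]]))
  out <- notes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split patients into train/validation/test partitions
#'
#' Patient-level (not note-level) splitting, so all notes of one patient
#' fall in one partition and no patient leaks across partitions. Partition
#' sizes follow largest-remainder apportionment of `ratios` over the number
#' of patients: each partition receives `floor(ratio * N)` and leftover
#' slots go to the partitions with the largest fractional remainders, ties
#' resolved toward the later partition (test before validation before
#' train). For 717 patients at 60:20:20 this yields 430/143/144.
#'
#' @param patient_ids Character vector (or set) of patient identifiers.
#' @param ratios Numeric triple, positive, summing to 1 (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param seed Integer seed; the same seed always yields the same
#'   assignment.
#' @return A `split_assignment`: data.frame with columns `patient_id`,
#'   `partition` (factor train/validation/test), plus attributes `seed`
#'   and `ratios`.
#' @export
split_by_patient <- function(patient_ids, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  parts <- c("train", "validation", "test")
  if (length(ratios) != 3L || any(ratios <= 0)) stop("ratios must be three positive fractions")
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  if (n < length(parts)) stop("fewer patients (", n, ") than partitions")

  sizes <- apportion_largest_remainder(n, ratios)
  shuffled <- withr::with_seed(as.integer(seed), sample(sort(patient_ids)))
  partition <- factor(rep(parts, times = sizes), levels = parts)
  out <- data.frame(patient_id = shuffled, partition = partition,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  attr(out, "ratios") <- ratios
  class(out) <- unique(c("split_assignment", class(out)))
  out
}

# floor each share, hand leftovers to largest fractional remainders,
# ties toward the later partition (reproduces 717 -> 430/143/144)
apportion_largest_remainder <- function(n, ratios) {
  raw <- n * ratios
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    frac <- raw - sizes
    ord <- order(-frac, -seq_along(ratios))
    take <- ord[seq_len(left)]
    sizes[take] <- sizes[take] + 1L
  }
  as.integer(sizes)
}

#' Look up the partition of each note
#'
#' @param notes A `clinical_notes` table.
#' @param split A `split_assignment` from [split_by_patient()].
#' @return Factor of partitions aligned with the rows of `notes`.
#' @export
note_partition <- function(notes, split) {
  idx <- match(notes$patient_id, split$patient_id)
  if (anyNA(idx)) stop("notes reference patients absent from the split")
  split$partition[idx]
}

# ---- file I/O -------------------------------------------------------------

#' Read a note corpus from disk
#'
#' Notes are stored as CSV with columns `note_id, patient_id, encounter_id,
#' date, note_type, text` (ISO-8601 dates); encounters as CSV with
#' `encounter_id, patient_id, icd_codes` (semicolon-delimited). Malformed
#' records raise an error naming the offending line.
#'
#' @param notes_path,encounters_path CSV file paths.
#' @return List with elements `notes` and `encounters`.
#' @export
read_corpus <- function(notes_path, encounters_path) {
  list(notes = read_notes(notes_path), encounters = read_encounters(encounters_path))
}

#' @rdname read_corpus
#' @param path CSV path.
#' @export
read_notes <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) {
    return(clinical_notes(character(), character(), character(),
                          as.Date(character()), character(), character()))
  }
  check_required_fields(df, c("note_id", "patient_id", "encounter_id",
                              "date", "note_type", "text"), path)
  clinical_notes(df$note_id, df$patient_id, df$encounter_id,
                 df$date, df$note_type, df$text)
}

#' @rdname read_corpus
#' @export
read_encounters <- function(path) {
  df <- read.csv(path, colClasses = "character")
  if (nrow(df) == 0L) return(encounters(character(), character(), list()))
  # icd_codes may legitimately be empty (an encounter without diagnoses)
  check_required_fields(df, c("encounter_id", "patient_id", "icd_codes"), path,
                        allow_empty = "icd_codes")
  df$icd_codes[is.na(df$icd_codes)] <- ""
  encounters(df$encounter_id, df$patient_id, df$icd_codes)
}

check_required_fields <- function(df, fields, path, allow_empty = "text") {
  missing <- setdiff(fields, names(df))
  if (length(missing)) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  for (f in fields) {
    if (f %in% allow_empty) next
    bad <- which(is.na(df[[f]]) | !nzchar(df[[f]]))
    if (length(bad)) {
      stop(path, ": line ", bad[1] + 1L, ": empty or missing ", f)
    }
  }
  invisible(df)
}

#' Write notes and encounters to disk
#'
#' Inverse of [read_corpus()]; `read_corpus()` applied to the written files
#' reproduces the input field for field.
#'
#' @param notes,encs Tables as produced by [clinical_notes()] /
#'   [encounters()].
#' @param notes_path,encounters_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_corpus <- function(notes, encs, notes_path, encounters_path) {
  nd <- as.data.frame(notes)[, c("note_id", "patient_id", "encounter_id",
                                 "date", "note_type", "text")]
  nd$date <- format(nd$date, "%Y-%m-%d")
  write.csv(nd, notes_path, row.names = FALSE)
  ed <- data.frame(
    encounter_id = encs$encounter_id,
    patient_id = encs$patient_id,
    icd_codes = vapply(encs$icd_codes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.csv(ed, encounters_path, row.names = FALSE)
  invisible(c(notes_path, encounters_path))
}

#' Read and write label-vector files
#'
#' The shared label schema: one row per note, a 0/1 column per category,
#' and a `label_source` column in `icd`, `weak`, `hybrid` or `truth`.
#'
#' @param labels A `label_matrix` (see [label_matrix()]).
#' @param path CSV path.
#' @return `write_labels()` returns the path invisibly; `read_labels()`
#'   returns a `label_matrix`.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(note_id = rownames(labels), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(unclass(labels)[, , drop = FALSE]))
  df$label_source <- attr(labels, "source")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, colClasses = "character")
  cats <- setdiff(names(df), c("note_id", "label_source"))
  m <- as.matrix(df[, cats, drop = FALSE])
  storage.mode(m) <- "integer"
  src <- unique(df$label_source)
  if (length(src) != 1L) stop(path, ": mixed or missing label_source")
  label_matrix(m, note_ids = df$note_id, categories = cats, source = src)
}
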