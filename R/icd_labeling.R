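#' Truncate an ICD-10 code to its three-character category
#'
#' The symptom classes operate at the highest level of the ICD-10
#' hierarchy, so `"R06.02"` and `"R06.2"` both collapse to `"R06"`.
#' A well-formed code is a letter followed by two digits, optionally
#' extended by `.`-separated characters.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of uppercased 3-character categories.
#' @export
truncate_to_category <- function(code) {
  code <- toupper(as.character(code))
  ok <- grepl("^[A-Z][0-9]{2}(\\..*)?$", code)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ", paste(unique(code[!ok]), collapse = ", "))
  }
  substr(code, 1L, 3L)
}

#' Derive a category label vector from one encounter's codes
#'
#' `labels[k] = 1` iff some code on the encounter truncates to the k-th
#' target category; codes outside the target set are ignored, duplicates
#' are idempotent. This encodes the one-way assumption behind ICD
#' pseudolabels: a present code signals the symptom, an absent code
#' signals nothing.
#'
#' @param codes Character vector of ICD-10 codes for one encounter.
#' @param categories Ordered target categories (default R00..R09).
#' @return Integer 0/1 vector named by category.
#' @export
encounter_to_labels <- function(codes, categories = target_categories()) {
  if (!length(codes)) return(setNames(integer(length(categories)), categories))
  cats <- truncate_to_category(codes)
  setNames(as.integer(categories %in% cats), categories)
}

#' Label a note corpus from its encounter ICD-10 codes
#'
#' Each note inherits the codes of its own encounter only. Notes whose
#' encounter carries no code in the target set receive an all-zero row
#' and are retained as negatives for every class.
#'
#' @param notes A `clinical_notes` table.
#' @param encs An `encounters` table resolving every note's encounter.
#' @param categories Ordered target categories.
#' @return A [label_matrix()] with `source = "icd"`.
#' @export
icd_label_notes <- function(notes, encs, categories = target_categories()) {
  idx <- match(notes$encounter_id, encs$encounter_id)
  if (anyNA(idx)) {
    stop("notes with unresolvable encounter_id: ",
         paste(head(notes$note_id[is.na(idx)], 5L), collapse = ", "))
  }
  m <- matrix(0L, nrow = nrow(notes), ncol = length(categories))
  for (r in seq_along(idx)) {
    m[r, ] <- encounter_to_labels(encs$icd_codes[[idx[r]]], categories)
  }
  label_matrix(m, note_ids = notes$note_id, categories = categories, source = "icd")
}
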