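#' Load the context-trigger terminology
#'
#' Reads the three trigger lexicons — negation, historical and family
#' expressions — used by the labeling functions. Each file holds one
#' trigger phrase per line (natural surface form); every phrase is
#' normalized and stemmed through the package's own preprocessing
#' pipeline at load time, so triggers always live in the same token
#' space as preprocessed notes. The three sets must be pairwise
#' disjoint after normalization.
#'
#' @param negation_path,historical_path,family_path Trigger files; by
#'   default the lexicons shipped in `inst/extdata/`.
#' @param stop_words,negation_keep,stem Normalization settings, matching
#'   those used on the notes.
#' @return A list of class `terminology` with character-vector elements
#'   `negation`, `historical`, `family` (space-joined normalized n-grams).
#' @export
read_terminology <- function(negation_path = NULL, historical_path = NULL,
                             family_path = NULL,
                             stop_words = default_stop_words(),
                             negation_keep = c("no", "not"), stem = TRUE) {
  pick <- function(p, f) {
    if (is.null(p)) system.file("extdata", f, package = "symptomweak") else p
  }
  load1 <- function(path) {
    x <- normalize_phrase(read_token_lines(path), stop_words, negation_keep, stem)
    unique(x[nzchar(x)])
  }
  out <- list(
    negation = load1(pick(negation_path, "triggers_negation.txt")),
    historical = load1(pick(historical_path, "triggers_historical.txt")),
    family = load1(pick(family_path, "triggers_family.txt"))
  )
  overlap <- c(intersect(out$negation, out$historical),
               intersect(out$negation, out$family),
               intersect(out$historical, out$family))
  if (length(overlap)) {
    stop("trigger sets overlap after normalization: ",
         paste(unique(overlap), collapse = ", "))
  }
  class(out) <- "terminology"
  out
}

#' Build a terminology object from in-memory phrase vectors
#'
#' @param negation,historical,family Character vectors of trigger phrases
#'   (already normalized, or pass `normalize = TRUE` to run them through
#'   [normalize_phrase()]).
#' @param normalize Normalize/stem the phrases first (default TRUE).
#' @return A `terminology` list, as in [read_terminology()].
#' @export
terminology <- function(negation, historical, family, normalize = TRUE) {
  prep <- function(x) {
    if (normalize) x <- normalize_phrase(x)
    unique(x[nzchar(x)])
  }
  out <- list(negation = prep(negation), historical = prep(historical),
              family = prep(family))
  class(out) <- "terminology"
  out
}

#' Load the concept dictionary
#'
#' The dictionary maps surface-form n-grams to a concept identifier and
#' its ICD-10 category, standing in for a UMLS-scale CUI table. The CSV
#' columns are `surface_form, concept_id, icd10_category`; surfaces are
#' normalized and stemmed at load, and every category must belong to the
#' target set. The packaged default is a small *synthetic* dictionary
#' authored for this package (its filename says so); it is not derived
#' from UMLS and should be replaced with a site dictionary for real
#' data.
#'
#' @param path CSV path; default is the synthetic mini dictionary
#'   shipped in `inst/extdata/concept_dictionary_synthetic.csv`.
#' @param categories Allowed categories (default R00..R09).
#' @param stop_words,negation_keep,stem Normalization settings.
#' @return A `data.frame` of class `concept_dictionary` with columns
#'   `surface` (normalized, space-joined), `concept_id`, `category`.
#' @export
read_concept_dictionary <- function(path = NULL,
                                    categories = target_categories(),
                                    stop_words = default_stop_words(),
                                    negation_keep = c("no", "not"),
                                    stem = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "concept_dictionary_synthetic.csv",
                        package = "symptomweak")
  }
  df <- read.csv(path, colClasses = "character")
  check_required_fields(df, c("surface_form", "concept_id", "icd10_category"), path)
  concept_dictionary(df$surface_form, df$concept_id, df$icd10_category,
                     categories = categories, stop_words = stop_words,
                     negation_keep = negation_keep, stem = stem)
}

#' @rdname read_concept_dictionary
#' @param surface_form,concept_id,icd10_category Vectors defining entries.
#' @export
concept_dictionary <- function(surface_form, concept_id, icd10_category,
                               categories = target_categories(),
                               stop_words = default_stop_words(),
                               negation_keep = c("no", "not"), stem = TRUE) {
  bad <- setdiff(unique(icd10_category), categories)
  if (length(bad)) stop("dictionary categories outside target set: ",
                        paste(bad, collapse = ", "))
  surface <- normalize_phrase(surface_form, stop_words, negation_keep, stem)
  keep <- nzchar(surface)
  out <- data.frame(surface = surface[keep],
                    concept_id = as.character(concept_id)[keep],
                    category = as.character(icd10_category)[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$surface), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("concept_dictionary", class(out))
  out
}
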