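#' Default English stop list
#'
#' A standard English stop list shipped with the package (one token per
#' line in `inst/extdata/stopwords_en.txt`), with the negation tokens
#' still present; [normalize_text()] subtracts its `negation_keep` set
#' before filtering, so `"no"` and `"not"` survive by default.
#'
#' @param path Optional override file (one token per line, `#` comments).
#' @return Character vector of stop words.
#' @export
default_stop_words <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "symptomweak")
  }
  read_token_lines(path)
}

read_token_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Normalize raw note text into word tokens
#'
#' Lowercases, strips all digits, punctuation and other non-alphabetic
#' characters, splits on the resulting whitespace, and removes stop words
#' — except the negation attributes in `negation_keep` (`"no"`, `"not"`
#' by default), which carry the signal the downstream labeling functions
#' need. Token order is preserved; no sentence segmentation or sectioning
#' is performed.
#'
#' @param text Character vector of raw note texts.
#' @param stop_words Stop list (default [default_stop_words()]).
#' @param negation_keep Stop-list members to retain.
#' @return For a single text, a character vector of tokens; for several,
#'   a list of token vectors.
#' @export
normalize_text <- function(text, stop_words = default_stop_words(),
                           negation_keep = c("no", "not")) {
  active_stop <- setdiff(stop_words, negation_keep)
  out <- lapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    x <- tolower(x)
    x <- gsub("[^a-z]+", " ", x)
    toks <- strsplit(trimws(x), " +")[[1]]
    toks[!(toks %in% active_stop)]
  })
  if (length(text) == 1L) out[[1]] else out
}

#' Preprocess a note corpus into stemmed token streams
#'
#' Runs [normalize_text()] then [stem_tokens()] over every note. Both the
#' weak-labeling branch and the featurization branch consume this single
#' stream, so mention matching and document vectors always see identical
#' tokens.
#'
#' @param notes A `clinical_notes` table.
#' @param stop_words,negation_keep Passed to [normalize_text()].
#' @param stem Apply Porter stemming (default TRUE).
#' @return Named list of token vectors (names = note ids), class
#'   `tokenized_notes`.
#' @export
preprocess_notes <- function(notes, stop_words = default_stop_words(),
                             negation_keep = c("no", "not"), stem = TRUE) {
  toks <- normalize_text(notes$text, stop_words, negation_keep)
  if (nrow(notes) == 1L) toks <- list(toks)
  if (stem) {
    # stem the corpus-wide unique token set once, then remap per note
    lens <- lengths(toks)
    flat <- unlist(toks, use.names = FALSE)
    if (length(flat)) {
      flat <- stem_tokens(flat)
      toks <- split(flat, rep.int(seq_along(lens), lens))
      # notes that lost all tokens disappear from split(); restore them
      out <- vector("list", length(lens))
      out[lens > 0L] <- toks[as.character(which(lens > 0L))]
      out[lens == 0L] <- list(character())
      toks <- out
    }
  }
  names(toks) <- notes$note_id
  class(toks) <- c("tokenized_notes", class(toks))
  toks
}

#' Normalize a lexicon phrase exactly as note text is normalized
#'
#' Applies the same lowercase/strip/stem pipeline to dictionary surface
#' forms and trigger phrases, guaranteeing that lexicon entries and note
#' tokens live in the same token space. Stop words are *not* removed from
#' lexicon phrases apart from what normalization removes, except that the
#' phrase is normalized against an empty stop list (a trigger like
#' "history of" must keep its function words only if the note kept them,
#' so lexicon phrases drop the same stop words notes drop).
#'
#' @param phrase Character vector of phrases.
#' @param stop_words,negation_keep As in [normalize_text()].
#' @param stem Apply stemming (default TRUE).
#' @return Character vector of space-joined normalized phrases (empty
#'   phrases dropped by the caller).
#' @export
normalize_phrase <- function(phrase, stop_words = default_stop_words(),
                             negation_keep = c("no", "not"), stem = TRUE) {
  vapply(phrase, function(p) {
    toks <- normalize_text(p, stop_words, negation_keep)
    if (stem) toks <- stem_tokens(toks)
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
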