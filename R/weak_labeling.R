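#' Detect symptom mentions by dictionary matching
#'
#' Scans a token stream for concept-dictionary surface forms, longest
#' n-gram first, then left to right; accepted matches never overlap.
#' This dictionary matcher is the default mention detector; any function
#' with the same return shape can replace it (see `detector` in
#' [weak_label_notes()]) to plug in a learned NER component.
#'
#' @param tokens Character vector of preprocessed tokens for one note.
#' @param dict A [concept_dictionary()].
#' @param max_ngram Longest surface length, in tokens, to consider;
#'   default the longest entry in `dict`.
#' @param note_id Identifier copied onto the output rows.
#' @return `data.frame` with columns `note_id`, `start`, `end` (1-based,
#'   inclusive token positions), `surface`, `concept_id`, `category`,
#'   ordered by `start`.
#' @export
detect_mentions <- function(tokens, dict, max_ngram = NULL, note_id = NA_character_) {
  empty <- data.frame(note_id = character(), start = integer(), end = integer(),
                      surface = character(), concept_id = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (!length(tokens) || !nrow(dict)) return(empty)
  surf_len <- lengths(strsplit(dict$surface, " ", fixed = TRUE))
  if (is.null(max_ngram)) max_ngram <- max(surf_len)
  taken <- logical(length(tokens))
  hits <- list()
  for (n in seq(min(max_ngram, length(tokens)), 1L)) {
    entries <- dict[surf_len == n, , drop = FALSE]
    if (!nrow(entries)) next
    starts <- seq_len(length(tokens) - n + 1L)
    grams <- vapply(starts, function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
                    character(1))
    idx <- match(grams, entries$surface)
    for (k in which(!is.na(idx))) {
      i <- starts[k]
      span <- i:(i + n - 1L)
      if (any(taken[span])) next
      taken[span] <- TRUE
      e <- entries[idx[k], ]
      hits[[length(hits) + 1L]] <- data.frame(
        note_id = note_id, start = i, end = i + n - 1L,
        surface = grams[k], concept_id = e$concept_id, category = e$category,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a surface form to its nearest dictionary concept
#'
#' Fuzzy normalization used when a detected span is not an exact
#' dictionary entry (e.g. output of an external NER component): returns
#' the entry maximizing token-set Jaccard similarity with the surface.
#' Ties break to the lexicographically smallest `concept_id`; a maximum
#' below `min_similarity` is a no-match.
#'
#' @param surface Token n-gram, as a character vector of tokens or a
#'   space-joined string.
#' @param dict A [concept_dictionary()].
#' @param min_similarity Similarity threshold in `[0, 1]` (default 0.5).
#' @return List with `concept_id`, `category`, `similarity`, or `NULL`
#'   if nothing reaches the threshold.
#' @export
map_to_category <- function(surface, dict, min_similarity = 0.5) {
  if (length(surface) == 1L) surface <- strsplit(surface, " ", fixed = TRUE)[[1]]
  stopifnot(length(surface) > 0)
  s <- unique(surface)
  sim <- vapply(strsplit(dict$surface, " ", fixed = TRUE), function(e) {
    e <- unique(e)
    length(intersect(s, e)) / length(union(s, e))
  }, numeric(1))
  if (!length(sim) || max(sim) < min_similarity) return(NULL)
  best <- which(sim == max(sim))
  best <- best[order(dict$concept_id[best])][1L]
  list(concept_id = dict$concept_id[best], category = dict$category[best],
       similarity = sim[best])
}

#' Extract the context window around a mention
#'
#' Returns up to `width` tokens before and after the mention span
#' (default 10 each side, the 20-token window), clipped at the note
#' boundaries; the mention's own tokens are excluded. Windows never
#' cross note boundaries and ignore sentence structure.
#'
#' @param tokens Token vector of the note.
#' @param start,end Mention span, 1-based inclusive.
#' @param width Tokens kept on each side (default 10).
#' @return List with `before` and `after` token vectors; `before` keeps
#'   note order (its last element is adjacent to the mention).
#' @export
extract_context <- function(tokens, start, end, width = 10L) {
  stopifnot(start >= 1L, end >= start, end <= length(tokens))
  b0 <- max(1L, start - width)
  a1 <- min(length(tokens), end + width)
  list(
    before = if (start > 1L) tokens[b0:(start - 1L)] else character(),
    after = if (end < length(tokens)) tokens[(end + 1L):a1] else character()
  )
}

# nearest occurrence distance of any trigger n-gram within one window
# side; `before = TRUE` means the window precedes the mention, so the
# trigger token nearest the mention is the *last* one of the match
.nearest_trigger_distance <- function(side_tokens, triggers, before) {
  if (!length(side_tokens) || !length(triggers)) return(NA_integer_)
  nb <- length(side_tokens)
  best <- NA_integer_
  for (tr in triggers) {
    tt <- strsplit(tr, " ", fixed = TRUE)[[1]]
    n <- length(tt)
    if (n > nb) next
    for (i in seq_len(nb - n + 1L)) {
      if (all(side_tokens[i:(i + n - 1L)] == tt)) {
        d <- if (before) nb - (i + n - 1L) + 1L else i
        if (is.na(best) || d < best) best <- d
      }
    }
  }
  best
}

#' Apply the three context labeling functions to a window
#'
#' Each labeling function — negation, historical, family — fires iff one
#' of its trigger n-grams occurs anywhere in the 20-token window, and
#' records the distance (in tokens) from the mention to the nearest
#' firing trigger.
#'
#' @param window List with `before`/`after` from [extract_context()].
#' @param terminology A [terminology()] object.
#' @return `data.frame` with columns `lf` (negation/historical/family),
#'   `fired` (logical) and `distance` (integer, `NA` when abstaining).
#' @export
apply_labeling_functions <- function(window, terminology) {
  lfs <- c("negation", "historical", "family")
  dist <- vapply(lfs, function(lf) {
    trig <- terminology[[lf]]
    d <- c(.nearest_trigger_distance(window$before, trig, before = TRUE),
           .nearest_trigger_distance(window$after, trig, before = FALSE))
    if (all(is.na(d))) NA_integer_ else min(d, na.rm = TRUE)
  }, integer(1))
  data.frame(lf = lfs, fired = !is.na(dist), distance = dist,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resolve labeling-function votes into a mention label
#'
#' A mention with no firing labeling function is `positive` (experienced
#' by the patient, current, not negated). A single firing function gives
#' its label (`absent`, `history`, `family`). When several fire, the
#' trigger nearest the mention wins; distance ties resolve by the
#' precedence absent > history > family.
#'
#' @param lf_votes Output of [apply_labeling_functions()].
#' @return One of `"positive"`, `"absent"`, `"history"`, `"family"`.
#' @export
resolve_mention_label <- function(lf_votes) {
  lab_of <- c(negation = "absent", historical = "history", family = "family")
  fired <- lf_votes[lf_votes$fired, , drop = FALSE]
  if (!nrow(fired)) return("positive")
  prec <- match(fired$lf, names(lab_of)) # 1 = absent strongest
  winner <- order(fired$distance, prec)[1L]
  unname(lab_of[fired$lf[winner]])
}

#' Aggregate mention labels into one note label vector
#'
#' A category is positive for the note iff at least one of its mentions
#' resolved to `positive`; negated, historical and family mentions — and
#' categories with no mention at all — contribute zeros.
#'
#' @param mention_labels `data.frame` with columns `category` and `label`
#'   (one row per mention of this note).
#' @param note_id Note identifier for the output row.
#' @param categories Ordered target categories.
#' @return A 1-row [label_matrix()] with `source = "weak"`.
#' @export
aggregate_note_labels <- function(mention_labels, note_id,
                                  categories = target_categories()) {
  pos <- unique(mention_labels$category[mention_labels$label == "positive"])
  label_matrix(matrix(as.integer(categories %in% pos), nrow = 1L),
               note_ids = note_id, categories = categories, source = "weak")
}

#' Weak-label a preprocessed corpus
#'
#' Runs the full weak-supervision chain per note: mention detection,
#' 20-token context windows, the three trigger labeling functions, the
#' nearest-trigger resolution rule, and any-positive aggregation to note
#' level. This deterministic rule system is the default labeler; the
#' optional EM label model ([fit_label_model()]) serves multi-LF
#' combination experiments.
#'
#' @param tokenized A `tokenized_notes` list from [preprocess_notes()].
#' @param dict A [concept_dictionary()].
#' @param terminology A [terminology()] object.
#' @param categories Ordered target categories.
#' @param width Context half-window in tokens (default 10).
#' @param detector Mention detector, a `function(tokens, note_id)`
#'   returning rows shaped like [detect_mentions()]; default wraps the
#'   dictionary matcher.
#' @param detail Also return the per-mention table (default FALSE).
#' @return A [label_matrix()] with `source = "weak"`; with
#'   `detail = TRUE`, a list with elements `labels` and `mentions`.
#' @export
weak_label_notes <- function(tokenized, dict, terminology,
                             categories = target_categories(), width = 10L,
                             detector = NULL, detail = FALSE) {
  if (is.null(detector)) {
    detector <- function(tokens, note_id) detect_mentions(tokens, dict, note_id = note_id)
  }
  ids <- names(tokenized)
  lab <- matrix(0L, nrow = length(tokenized), ncol = length(categories))
  all_mentions <- if (detail) vector("list", length(tokenized)) else NULL
  for (i in seq_along(tokenized)) {
    toks <- tokenized[[i]]
    men <- detector(toks, ids[i])
    if (nrow(men)) {
      men$label <- vapply(seq_len(nrow(men)), function(k) {
        win <- extract_context(toks, men$start[k], men$end[k], width)
        resolve_mention_label(apply_labeling_functions(win, terminology))
      }, character(1))
      pos <- unique(men$category[men$label == "positive"])
      lab[i, ] <- as.integer(categories %in% pos)
    }
    if (detail) all_mentions[[i]] <- men
  }
  labels <- label_matrix(lab, note_ids = ids, categories = categories,
                         source = "weak")
  if (!detail) return(labels)
  mentions <- do.call(rbind, all_mentions[!vapply(all_mentions, is.null, logical(1))])
  list(labels = labels, mentions = mentions)
}
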