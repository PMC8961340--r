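# Shared fixtures: all built in code at test time.

# neutral filler words: alphabetic, not stop words, not triggers, not
# dictionary surfaces (also after stemming)
filler_words <- function(n) {
  pool <- c("baruto", "kelimo", "davato", "niremo", "solak", "petavi",
            "moradu", "tesilo", "vokar", "lumeda", "gisato", "ropelu",
            "zameti", "fodira", "bulena", "sakemo", "tirogu", "pamelo",
            "denaki", "vilotu")
  rep_len(pool, n)
}

toy_dictionary <- function() {
  concept_dictionary(
    surface_form = c("cough", "chest pain", "shortness of breath", "wheezing"),
    concept_id = c("C-R05-1", "C-R07-1", "C-R06-1", "C-R06-2"),
    icd10_category = c("R05", "R07", "R06", "R06"))
}

toy_terminology <- function() {
  terminology(negation = c("no", "denies", "without", "no evidence of"),
              historical = c("history of", "previously"),
              family = c("father", "mother"))
}

toy_notes <- function(texts, patients = NULL) {
  n <- length(texts)
  if (is.null(patients)) patients <- sprintf("P%03d", seq_len(n))
  clinical_notes(note_id = sprintf("n%03d", seq_len(n)),
                 patient_id = patients,
                 encounter_id = sprintf("e%03d", seq_len(n)),
                 date = as.Date("2015-06-01") + seq_len(n),
                 note_type = "outpatient-progress",
                 text = texts)
}

as_tokenized <- function(lst) {
  stopifnot(!is.null(names(lst)))
  structure(lst, class = "tokenized_notes")
}

# Build a snippet: filler tokens with a mention surface planted at a
# chosen position and optional triggers planted at exact token distances
# (positive distance = before the mention, negative = after).
# Returns the token vector plus the planted span.
build_snippet <- function(surface_tokens, n_tokens = 30L, mention_at = 10L,
                          triggers = list()) {
  toks <- filler_words(n_tokens + 20L)[seq_len(n_tokens)]
  start <- mention_at
  end <- mention_at + length(surface_tokens) - 1L
  stopifnot(end <= n_tokens)
  toks[start:end] <- surface_tokens
  for (tr in triggers) {
    tt <- strsplit(tr$phrase, " ", fixed = TRUE)[[1]]
    if (tr$distance > 0) {            # before: last trigger token at start - d
      pos_last <- start - tr$distance
      pos <- seq(pos_last - length(tt) + 1L, pos_last)
    } else {                          # after: first trigger token at end + |d|
      pos_first <- end - tr$distance  # distance negative
      pos <- seq(pos_first, pos_first + length(tt) - 1L)
    }
    stopifnot(all(pos >= 1L), all(pos <= n_tokens),
              all(pos < start | pos > end))
    toks[pos] <- tt
  }
  list(tokens = toks, start = start, end = end)
}

# Independent brute-force reference for the mention-label rules: scans
# the raw token list directly for trigger occurrences around a known
# span, with no use of extract_context/apply_labeling_functions.
brute_force_label <- function(tokens, start, end, term, width = 10L) {
  hits <- data.frame(label = character(), distance = integer())
  lab_of <- c(negation = "absent", historical = "history", family = "family")
  for (lf in names(lab_of)) {
    for (phrase in term[[lf]]) {
      tt <- strsplit(phrase, " ", fixed = TRUE)[[1]]
      L <- length(tt)
      for (i in seq_len(max(0L, length(tokens) - L + 1L))) {
        j <- i + L - 1L
        if (!all(tokens[i:j] == tt)) next
        if (j < start && j >= start - width && i >= start - width) {
          d <- start - j
        } else if (i > end && i <= end + width && j <= end + width) {
          d <- i - end
        } else next
        hits <- rbind(hits, data.frame(label = lab_of[[lf]], distance = d))
      }
    }
  }
  if (!nrow(hits)) return("positive")
  prec <- match(hits$label, c("absent", "history", "family"))
  hits$label[order(hits$distance, prec)][1]
}

# run the package chain (detect -> window -> LFs -> resolve) on a snippet
pipeline_label <- function(tokens, dict, term, width = 10L) {
  men <- detect_mentions(tokens, dict, note_id = "s")
  stopifnot(nrow(men) >= 1L)
  vapply(seq_len(nrow(men)), function(k) {
    win <- extract_context(tokens, men$start[k], men$end[k], width)
    resolve_mention_label(apply_labeling_functions(win, term))
  }, character(1))
}

# the full battery of constructed snippets used by the rule-oracle
# equivalence checks: context types x mention positions x distances
snippet_battery <- function() {
  dict <- toy_dictionary()
  term <- toy_terminology()
  surfaces <- list(c("cough"), c("wheez"), c("chest", "pain"),
                   c("short", "breath"))
  positions <- c(start = 1L, middle = 12L, end = 26L)
  # single triggers of every labeling function at several distances on
  # both sides, plus multi-trigger conflicts and distance ties
  trig <- list(none = list())
  singles <- list(neg = "deni", hist = "histori", fam = "father")
  for (lf in names(singles)) {
    for (d in c(1L, 3L, 6L, 10L)) {
      trig[[paste0(lf, "_b", d)]] <- list(list(phrase = singles[[lf]],
                                               distance = d))
      trig[[paste0(lf, "_a", d)]] <- list(list(phrase = singles[[lf]],
                                               distance = -d))
    }
  }
  trig$multigram <- list(list(phrase = "no evid", distance = 1L))
  trig$multi_near_hist <- list(list(phrase = "no", distance = 5L),
                               list(phrase = "histori", distance = 2L))
  trig$multi_near_neg <- list(list(phrase = "deni", distance = 1L),
                              list(phrase = "father", distance = 6L))
  trig$tie_neg_hist <- list(list(phrase = "no", distance = 3L),
                            list(phrase = "histori", distance = -3L))
  trig$tie_hist_fam <- list(list(phrase = "previous", distance = 4L),
                            list(phrase = "mother", distance = -4L))
  trig$multi_after <- list(list(phrase = "without", distance = -2L),
                           list(phrase = "mother", distance = -7L))
  out <- list()
  for (s in surfaces) {
    for (pnm in names(positions)) {
      for (tnm in names(trig)) {
        n_tok <- 40L
        at <- switch(pnm, start = 1L, middle = 15L,
                     end = n_tok - length(s) + 1L)
        # drop combinations whose trigger would fall outside the note
        ok <- TRUE
        for (tr in trig[[tnm]]) {
          tt <- strsplit(tr$phrase, " ")[[1]]
          if (tr$distance > 0 &&
              at - tr$distance - length(tt) + 1L < 1L) ok <- FALSE
          if (tr$distance < 0 &&
              at + length(s) - 1L - tr$distance + length(tt) - 1L > n_tok) ok <- FALSE
        }
        if (!ok) next
        snip <- build_snippet(s, n_tokens = n_tok, mention_at = at,
                              triggers = trig[[tnm]])
        out[[length(out) + 1L]] <- c(snip, list(dict = dict, term = term,
                                                case = paste(pnm, tnm)))
      }
    }
  }
  out
}
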