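# Raw-text building blocks for the generator. Trigger phrases are drawn
# from the packaged lexicons (natural forms); positive prefixes contain
# no trigger vocabulary, so a positive-context mention never has a
# modifier inside its window.
.gen_templates <- list(
  positive = c("patient reports", "complains of", "presents with",
               "endorses", "describes"),
  negated = c("no", "denies", "without", "no evidence of"),
  historical = c("history of", "previously"),
  family = c("father", "mother", "brother", "sister")
)

# out-of-dictionary synonym bank: token-disjoint (as contiguous n-grams)
# from every dictionary surface, so a paraphrased mention is a guaranteed
# dictionary-matcher miss
.gen_paraphrases <- list(
  R00 = c("racing pulse", "fluttering in the pulse"),
  R01 = c("audible whoosh on auscultation"),
  R02 = c("necrotic tissue changes"),
  R03 = c("abnormal bp readings"),
  R04 = c("bleeding from the nose", "bloody sputum noted"),
  R05 = c("persistent hacking", "barking spells"),
  R06 = c("winded with minimal exertion", "labored respiration"),
  R07 = c("retrosternal discomfort", "burning behind the sternum"),
  R08 = c("audible crackles on exam"),
  R09 = c("congested airways with rattling")
)

#' Configuration for the synthetic note generator
#'
#' Defines the statistical regime the synthetic EHR emulates: per-note
#' symptom prevalence in the 2-10% band, a context mix dominated by
#' positive mentions with negated/historical/family minorities,
#' encounter coding that under-reports true symptoms (low sensitivity,
#' high specificity), Zipf-distributed filler vocabulary, and a
#' paraphrase rate creating realistic dictionary misses.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient Integer range `c(min, max)` of notes per
#'   patient (default `c(1, 3)`).
#' @param categories Target categories to render (default R00..R09).
#' @param prevalence Per-category probability that a note is truly
#'   positive; default an even grid from 0.02 to 0.10 over the
#'   categories.
#' @param context_mix Probabilities over the mention contexts
#'   `positive`, `negated`, `historical`, `family`; must sum to 1.
#' @param mentions_per_positive Integer range of mentions rendered when
#'   a note mentions a category (default `c(1, 3)`).
#' @param coding_sensitivity,coding_specificity Encounter-coding noise:
#'   a truly positive note-category emits its code with probability
#'   `coding_sensitivity`; a truly negative one with probability
#'   `1 - coding_specificity`. Defaults 0.4 and 0.99.
#' @param filler_vocab_size Size of the Zipfian filler vocabulary
#'   (default 2000).
#' @param note_length_tokens Range of note lengths in tokens (default
#'   `c(80, 160)`, comfortably above the 350-character cohort filter).
#' @param paraphrase_rate Probability that a mention's surface form is
#'   replaced by an out-of-dictionary synonym (default 0.1).
#' @param surface_bank Optional `data.frame` with columns `surface_raw`
#'   and `category` restricting which dictionary surfaces the generator
#'   renders (default: every entry of the packaged dictionary). Useful
#'   for controlled experiments where the mention footprint must be
#'   comparable across categories.
#' @param seed Integer seed; generation is byte-deterministic given the
#'   config.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 200L,
                             notes_per_patient = c(1L, 3L),
                             categories = target_categories(),
                             prevalence = NULL,
                             context_mix = c(positive = 0.60, negated = 0.25,
                                             historical = 0.10, family = 0.05),
                             mentions_per_positive = c(1L, 3L),
                             coding_sensitivity = 0.4,
                             coding_specificity = 0.99,
                             filler_vocab_size = 2000L,
                             note_length_tokens = c(80L, 160L),
                             paraphrase_rate = 0.1,
                             surface_bank = NULL,
                             seed = 1L) {
  if (is.null(prevalence)) {
    prevalence <- setNames(seq(0.02, 0.10, length.out = length(categories)),
                           categories)
  }
  if (is.null(names(prevalence))) names(prevalence) <- categories
  stopifnot(setequal(names(prevalence), categories))
  prevalence <- prevalence[categories]
  cfg <- list(n_patients = as.integer(n_patients),
              notes_per_patient = as.integer(notes_per_patient),
              categories = categories, prevalence = prevalence,
              context_mix = context_mix,
              mentions_per_positive = as.integer(mentions_per_positive),
              coding_sensitivity = coding_sensitivity,
              coding_specificity = coding_specificity,
              filler_vocab_size = as.integer(filler_vocab_size),
              note_length_tokens = as.integer(note_length_tokens),
              paraphrase_rate = paraphrase_rate,
              surface_bank = surface_bank,
              seed = as.integer(seed))
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_patients >= 1L,
              length(notes_per_patient) == 2L,
              notes_per_patient[1] >= 1L,
              notes_per_patient[2] >= notes_per_patient[1],
              all(prevalence > 0 & prevalence < 1),
              all(context_mix >= 0 & context_mix <= 1),
              abs(sum(context_mix) - 1) < 1e-9,
              setequal(names(context_mix),
                       c("positive", "negated", "historical", "family")),
              mentions_per_positive[1] >= 1L,
              coding_sensitivity >= 0, coding_sensitivity <= 1,
              coding_specificity >= 0, coding_specificity <= 1,
              paraphrase_rate >= 0, paraphrase_rate <= 1,
              all(categories %in% target_categories()))
  })
  if (!is.null(cfg$surface_bank)) {
    stopifnot(is.data.frame(cfg$surface_bank),
              all(c("surface_raw", "category") %in% names(cfg$surface_bank)),
              all(cfg$categories %in% cfg$surface_bank$category))
  }
  # mention rate implied by prevalence and context mix must be a probability
  p_pos <- cfg$context_mix[["positive"]]
  if (p_pos > 0) {
    ms <- seq(cfg$mentions_per_positive[1], cfg$mentions_per_positive[2])
    p_any <- mean(1 - (1 - p_pos)^ms)
    if (any(cfg$prevalence / p_any > 1)) {
      stop("inconsistent config: prevalence unreachable under this ",
           "context mix (mention rate would exceed 1)")
    }
  }
  class(cfg) <- "generator_config"
  cfg
}

# pseudo-clinical filler lexicon: pronounceable syllable compounds,
# guaranteed disjoint from stop words, trigger phrases and dictionary
# surfaces (also after stemming)
.filler_vocab <- function(n, dict, stop_words) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- character(0)
  reps <- 2L
  while (length(words) < n && reps <= 4L) {
    grid <- do.call(expand.grid, rep(list(syl), reps))
    cand <- do.call(paste0, grid)
    words <- unique(c(words, cand))
    reps <- reps + 1L
  }
  forbidden <- c(stop_words,
                 unlist(strsplit(unlist(.gen_templates), " ")),
                 unlist(strsplit(dict$surface_raw, " ")),
                 unlist(strsplit(unlist(.gen_paraphrases), " ")))
  forbidden <- unique(c(forbidden, stem_tokens(forbidden)))
  words <- setdiff(words, forbidden)
  words <- words[!(stem_tokens(words) %in% forbidden)]
  if (length(words) < n) stop("filler vocabulary exhausted")
  words[seq_len(n)]
}

.builtin_surface_bank <- function() {
  path <- system.file("extdata", "concept_dictionary_synthetic.csv",
                      package = "symptomweak")
  df <- read.csv(path, colClasses = "character")
  data.frame(surface_raw = df$surface_form, category = df$icd10_category,
             stringsAsFactors = FALSE)
}

#' Render one symptom mention with its context, as raw tokens
#'
#' Emits the raw word sequence for a mention of `category` in the given
#' context: a trigger phrase directly preceding the surface form for
#' negated/historical/family contexts (always within the 10-token
#' window), or a trigger-free reporting prefix for positive context.
#' Uses the session RNG; callers seed it.
#'
#' @param category Target category (must exist in the surface bank).
#' @param context_type One of `"positive"`, `"negated"`, `"historical"`,
#'   `"family"`.
#' @param surfaces `data.frame` with `surface_raw`, `category` (default:
#'   the packaged synthetic dictionary).
#' @param paraphrase Replace the surface with an out-of-dictionary
#'   synonym (default FALSE).
#' @return Character vector of raw word tokens.
#' @export
render_mention <- function(category,
                           context_type = c("positive", "negated",
                                            "historical", "family"),
                           surfaces = .builtin_surface_bank(),
                           paraphrase = FALSE) {
  context_type <- match.arg(context_type)
  pool <- surfaces$surface_raw[surfaces$category == category]
  if (!length(pool)) stop("unknown category: ", category)
  surface <- if (paraphrase) {
    sample(.gen_paraphrases[[category]], 1L)
  } else {
    pool[sample.int(length(pool), 1L)]
  }
  prefix <- switch(context_type,
    positive = sample(.gen_templates$positive, 1L),
    negated = sample(.gen_templates$negated, 1L),
    historical = sample(.gen_templates$historical, 1L),
    family = sample(.gen_templates$family, 1L))
  strsplit(paste(prefix, surface), " ", fixed = TRUE)[[1]]
}

#' Generate a synthetic note corpus with known ground truth
#'
#' Builds notes as Zipf-weighted filler text with injected symptom
#' mention phrases. For each note and category, a mention group appears
#' with the rate implied by the configured prevalence; each mention is
#' rendered in a context drawn from `context_mix`, and the category is
#' truly positive iff at least one mention is in positive context (so
#' the empirical prevalence of truth is exactly the configured
#' Bernoulli rate). Mention groups are separated by at least 12 filler
#' tokens, so one mention's trigger can never sit inside another's
#' 10-token window. Encounter code lists are derived from the truth via
#' [corrupt_codes()]. Fully deterministic given the config.
#'
#' @param config A [generator_config()].
#' @return List with `notes` (`clinical_notes`), `encounters`
#'   (`encounters`, one per note, with coding noise applied), `truth`
#'   (a [label_matrix()], `source = "truth"`), and `mentions` (the
#'   rendered mention inventory: note_id, category, context, surface,
#'   paraphrased).
#' @export
generate_corpus <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  surfaces <- if (is.null(cfg$surface_bank)) .builtin_surface_bank()
              else cfg$surface_bank
  stop_words <- default_stop_words()
  # filler must avoid the full packaged dictionary, not just the bank in
  # use, so the weak labeler never matches filler text
  filler_forbid <- rbind(.builtin_surface_bank(),
                         surfaces[, c("surface_raw", "category")])
  filler <- .filler_vocab(cfg$filler_vocab_size, filler_forbid, stop_words)
  zipf_w <- 1 / seq_along(filler)

  cats <- cfg$categories
  p_pos <- cfg$context_mix[["positive"]]
  ms <- seq(cfg$mentions_per_positive[1], cfg$mentions_per_positive[2])
  p_any <- if (p_pos > 0) mean(1 - (1 - p_pos)^ms) else 1
  q <- cfg$prevalence / p_any           # mention-group rate per category

  n_notes_per_pat <- sample(seq(cfg$notes_per_patient[1],
                                cfg$notes_per_patient[2]),
                            cfg$n_patients, replace = TRUE)
  n_notes <- sum(n_notes_per_pat)
  patient_of <- rep(sprintf("P%05d", seq_len(cfg$n_patients)), n_notes_per_pat)
  note_ids <- sprintf("N%06d", seq_len(n_notes))

  truth <- matrix(0L, nrow = n_notes, ncol = length(cats),
                  dimnames = list(note_ids, cats))
  texts <- character(n_notes)
  mention_log <- vector("list", n_notes)
  ctx_names <- c("positive", "negated", "historical", "family")
  ctx_p <- as.numeric(cfg$context_mix[ctx_names])

  sample_filler <- function(k) {
    if (k <= 0) return(character())
    filler[sample.int(length(filler), k, replace = TRUE, prob = zipf_w)]
  }

  for (i in seq_len(n_notes)) {
    chunks <- list()
    log_rows <- list()
    for (k in seq_along(cats)) {
      if (runif(1) >= q[k]) next
      n_m <- sample(ms, 1L)
      ctxs <- ctx_names[sample.int(4L, n_m, replace = TRUE, prob = ctx_p)]
      for (ctx in ctxs) {
        para <- runif(1) < cfg$paraphrase_rate
        toks <- render_mention(cats[k], ctx, surfaces, paraphrase = para)
        chunks[[length(chunks) + 1L]] <- toks
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          note_id = note_ids[i], category = cats[k], context = ctx,
          surface = paste(toks, collapse = " "), paraphrased = para,
          stringsAsFactors = FALSE)
        if (ctx == "positive") truth[i, k] <- 1L
      }
    }
    len <- sample(seq(cfg$note_length_tokens[1], cfg$note_length_tokens[2]), 1L)
    n_chunks <- length(chunks)
    filler_needed <- max(len - sum(lengths(chunks)), 12L * n_chunks + 5L)
    # split filler into n_chunks + 1 gaps, interior gaps >= 12 tokens
    gaps <- rep(filler_needed %/% (n_chunks + 1L), n_chunks + 1L)
    gaps[1] <- gaps[1] + filler_needed - sum(gaps)
    if (n_chunks > 0 && any(gaps[-1] < 12L)) {
      deficit <- sum(pmax(12L - gaps[-1], 0L))
      gaps[-1] <- pmax(gaps[-1], 12L)
      gaps[1] <- max(gaps[1] - deficit, 0L)
    }
    parts <- character(0)
    for (cidx in seq_len(n_chunks)) {
      parts <- c(parts, sample_filler(gaps[cidx]), chunks[[cidx]])
    }
    parts <- c(parts, sample_filler(gaps[n_chunks + 1L]))
    texts[i] <- paste(parts, collapse = " ")
    if (length(log_rows)) mention_log[[i]] <- do.call(rbind, log_rows)
  }

  notes <- clinical_notes(
    note_id = note_ids, patient_id = patient_of,
    encounter_id = paste0("E", note_ids),
    date = as.Date("2000-01-01") + sample.int(6209L, n_notes, replace = TRUE),
    note_type = "outpatient-progress", text = texts)
  truth_lm <- label_matrix(truth, note_ids = note_ids, categories = cats,
                           source = "truth")
  code_lists <- corrupt_codes(truth_lm, cfg$coding_sensitivity,
                              cfg$coding_specificity,
                              seed = cfg$seed + 1000003L)
  encs <- encounters(encounter_id = paste0("E", note_ids),
                     patient_id = patient_of, icd_codes = code_lists)
  mentions <- do.call(rbind, mention_log[!vapply(mention_log, is.null, logical(1))])
  list(notes = notes, encounters = encs, truth = truth_lm,
       mentions = mentions)
}

#' Corrupt ground-truth labels into encounter code lists
#'
#' Models incomplete encounter coding: each truly positive note-category
#' cell emits its ICD-10 code with probability `sensitivity`; each truly
#' negative cell emits a spurious code with probability
#' `1 - specificity`, independently given the seed. Emitted codes carry
#' random subcategory extensions (e.g. `"R06.02"`); each list also gets
#' 0-2 non-R distractor codes.
#'
#' @param truth A [label_matrix()] of true labels.
#' @param sensitivity,specificity Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of character code vectors, one per note, named by note
#'   id.
#' @export
corrupt_codes <- function(truth, sensitivity, specificity, seed = 1L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  cats <- colnames(truth)
  m <- unclass(truth)
  withr::with_seed(as.integer(seed), {
    emit_p <- ifelse(m == 1L, sensitivity, 1 - specificity)
    emit <- matrix(runif(length(m)) < emit_p, nrow = nrow(m))
    exts <- c("", ".0", ".02", ".2", ".9", ".00")
    distractors <- c("I10", "E11.9", "Z00.0", "K21.9", "M54.5")
    lapply(seq_len(nrow(m)), function(i) {
      codes <- cats[emit[i, ]]
      if (length(codes)) {
        codes <- paste0(codes, sample(exts, length(codes), replace = TRUE))
      }
      nd <- sample.int(3L, 1L) - 1L
      unique(c(codes, sample(distractors, nd)))
    })
  }) -> out
  names(out) <- rownames(truth)
  out
}
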