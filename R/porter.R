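# Porter stemming, suffix-stripping with the measure-based conditions of
# the classic algorithm. Operates on lowercase alphabetic tokens only
# (guaranteed upstream by normalize_text); words of <3 letters pass through.

.p_chop <- function(w, k) substr(w, 1L, nchar(w) - k)
.p_last <- function(w) substr(w, nchar(w), nchar(w))

.p_letters <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# consonant test with the y-rule: y is a consonant word-initially or after
# a vowel, otherwise it behaves as a vowel
.p_cons <- function(b) {
  n <- length(b)
  out <- !(b %in% c("a", "e", "i", "o", "u", "y"))
  ys <- which(b == "y")
  for (i in ys) out[i] <- if (i == 1L) TRUE else !out[i - 1L]
  out
}

# m = number of vowel-consonant sequences in the stem; after dropping a
# leading consonant run the runs alternate V,C,V,C,... so m is the number
# of complete VC pairs
.p_measure <- function(stem) {
  if (!nchar(stem)) return(0L)
  types <- .p_cons(.p_letters(stem))
  r <- rle(types)$values
  if (r[1]) r <- r[-1]
  length(r) %/% 2L
}

.p_has_vowel <- function(stem) {
  nchar(stem) > 0 && any(!.p_cons(.p_letters(stem)))
}

.p_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  b <- .p_letters(w)
  b[n] == b[n - 1L] && .p_cons(b)[n]
}

# consonant-vowel-consonant ending, final consonant not w, x or y
.p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  b <- .p_letters(w)
  cons <- .p_cons(b)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(b[n] %in% c("w", "x", "y"))
}

.p_step2_rules <- list(
  c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
  c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
  c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
  c("iviti", "ive"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("eli", "e")
)

.p_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"),
  c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", "")
)

.p_step4_sufs <- c("ement", "ance", "ence", "able", "ible", "ment",
                   "ant", "ent", "ism", "ate", "iti", "ous", "ive",
                   "ize", "ion", "al", "er", "ic", "ou")

.porter_one <- function(w) {
  if (nchar(w) < 3L) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) w <- .p_chop(w, 2L)
  else if (endsWith(w, "ies")) w <- paste0(.p_chop(w, 3L), "i")
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- .p_chop(w, 1L)

  # step 1b: -eed / -ed / -ing
  cleanup <- FALSE
  if (endsWith(w, "eed")) {
    if (.p_measure(.p_chop(w, 3L)) > 0L) w <- .p_chop(w, 1L)
  } else if (endsWith(w, "ed")) {
    stem <- .p_chop(w, 2L)
    if (.p_has_vowel(stem)) { w <- stem; cleanup <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- .p_chop(w, 3L)
    if (.p_has_vowel(stem)) { w <- stem; cleanup <- TRUE }
  }
  if (cleanup) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) && !(.p_last(w) %in% c("l", "s", "z"))) {
      w <- .p_chop(w, 1L)
    } else if (.p_measure(w) == 1L && .p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: terminal y -> i when the stem has a vowel
  if (endsWith(w, "y") && .p_has_vowel(.p_chop(w, 1L))) {
    w <- paste0(.p_chop(w, 1L), "i")
  }

  # step 2 (m > 0), longest suffix first, first textual match wins
  for (rule in .p_step2_rules) {
    if (endsWith(w, rule[1])) {
      stem <- .p_chop(w, nchar(rule[1]))
      if (.p_measure(stem) > 0L) w <- paste0(stem, rule[2])
      break
    }
  }

  # step 3 (m > 0)
  for (rule in .p_step3_rules) {
    if (endsWith(w, rule[1])) {
      stem <- .p_chop(w, nchar(rule[1]))
      if (.p_measure(stem) > 0L) w <- paste0(stem, rule[2])
      break
    }
  }

  # step 4 (m > 1): strip residual suffixes; -ion needs stem ending s/t
  for (suf in .p_step4_sufs) {
    if (endsWith(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      if (.p_measure(stem) > 1L &&
          (suf != "ion" || .p_last(stem) %in% c("s", "t"))) {
        w <- stem
      }
      break
    }
  }

  # step 5a: drop terminal e
  if (endsWith(w, "e")) {
    stem <- .p_chop(w, 1L)
    a <- .p_measure(stem)
    if (a > 1L || (a == 1L && !.p_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l when m > 1
  if (.p_last(w) == "l" && .p_double_cons(w) && .p_measure(w) > 1L) {
    w <- .p_chop(w, 1L)
  }
  w
}

#' Porter-stem a vector of tokens
#'
#' Reduces inflected English word forms to a common stem with the Porter
#' suffix-stripping algorithm, e.g. `"coughing"` and `"coughs"` both map
#' to `"cough"`. Input tokens are expected lowercase and alphabetic (as
#' produced by [normalize_text()]); output has the same length and order.
#'
#' @param tokens Character vector of normalized tokens.
#' @return Character vector of stems, same length as `tokens`.
#' @export
stem_tokens <- function(tokens) {
  if (!length(tokens)) return(character())
  u <- unique(tokens)
  stems <- vapply(u, .porter_one, character(1), USE.NAMES = FALSE)
  stems[match(tokens, u)]
}
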