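# Porter stemmer (the classic 1980 suffix-stripping algorithm), implemented
# in-package because no stemming library ships with the runtime.  Operates on
# single lowercase ASCII words; words of length <= 2 are returned unchanged.

# y is a vowel only when preceded by a consonant; position is 1-based.
.pt_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of a stem: number of vowel->consonant transitions in [C](VC)^m[V]
.pt_measure <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  if (!length(chars)) return(0L)
  cons <- vapply(seq_along(chars), function(i) .pt_is_cons(chars, i),
                 logical(1))
  rle_v <- rle(cons)$values
  sum(rle_v[-length(rle_v)] == FALSE)  # V runs followed by something => VC
}

.pt_has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  if (!length(chars)) return(FALSE)
  any(!vapply(seq_along(chars), function(i) .pt_is_cons(chars, i),
              logical(1)))
}

.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  chars[n] == chars[n - 1L] && .pt_is_cons(chars, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  .pt_is_cons(chars, n - 2L) && !.pt_is_cons(chars, n - 1L) &&
    .pt_is_cons(chars, n) && !(chars[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substring(word, n - s + 1L, n) == suffix
}

.pt_stem_part <- function(word, suffix) {
  substring(word, 1L, nchar(word) - nchar(suffix))
}

# apply the first matching (longest listed first) rule with an m condition
.pt_rule_table <- function(word, rules, m_min) {
  for (r in rules) {
    if (.pt_ends(word, r[1])) {
      stem <- .pt_stem_part(word, r[1])
      if (.pt_measure(stem) > m_min) {
        return(paste0(stem, r[2]))
      }
      return(word)  # longest match decides; no fallthrough
    }
  }
  word
}

#' Stem an English word with the Porter algorithm
#'
#' The classic five-step suffix-stripping algorithm: plural and participle
#' removal (with e-restoration and consonant undoubling), y/i normalisation,
#' and the three derivational-suffix tables gated on the stem measure m.
#'
#' @param word a single lowercase word (non-alphabetic input is returned
#'   unchanged); vectorised over `word`.
#' @return The stemmed word(s).
#' @examples
#' porter_stem(c("running", "caresses", "relational"))
#' @export
porter_stem <- function(word) {
  vapply(as.character(word), .pt_stem1, character(1), USE.NAMES = FALSE)
}

.pt_stem1 <- function(word) {
  if (is.na(word) || nchar(word) <= 2L || grepl("[^a-z]", word)) return(word)

  # Step 1a
  if (.pt_ends(word, "sses")) {
    word <- paste0(.pt_stem_part(word, "sses"), "ss")
  } else if (.pt_ends(word, "ies")) {
    word <- paste0(.pt_stem_part(word, "ies"), "i")
  } else if (!.pt_ends(word, "ss") && .pt_ends(word, "s")) {
    word <- .pt_stem_part(word, "s")
  }

  # Step 1b
  if (.pt_ends(word, "eed")) {
    stem <- .pt_stem_part(word, "eed")
    if (.pt_measure(stem) > 0L) word <- paste0(stem, "ee")
  } else {
    stripped <- FALSE
    if (.pt_ends(word, "ed") && .pt_has_vowel(.pt_stem_part(word, "ed"))) {
      word <- .pt_stem_part(word, "ed"); stripped <- TRUE
    } else if (.pt_ends(word, "ing") &&
               .pt_has_vowel(.pt_stem_part(word, "ing"))) {
      word <- .pt_stem_part(word, "ing"); stripped <- TRUE
    }
    if (stripped) {
      if (.pt_ends(word, "at") || .pt_ends(word, "bl") ||
          .pt_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (.pt_double_cons(word) &&
                 !substring(word, nchar(word)) %in% c("l", "s", "z")) {
        word <- substring(word, 1L, nchar(word) - 1L)
      } else if (.pt_measure(word) == 1L && .pt_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (.pt_ends(word, "y") && .pt_has_vowel(.pt_stem_part(word, "y"))) {
    word <- paste0(.pt_stem_part(word, "y"), "i")
  }

  # Step 2 (m > 0)
  word <- .pt_rule_table(word, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
    c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
    c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
  ), m_min = 0L)

  # Step 3 (m > 0)
  word <- .pt_rule_table(word, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  ), m_min = 0L)

  # Step 4 (m > 1); "ion" additionally requires the stem to end in s or t
  n <- nchar(word)
  for (suf in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")) {
    if (.pt_ends(word, suf)) {
      stem <- .pt_stem_part(word, suf)
      if (.pt_measure(stem) > 1L &&
          (suf != "ion" ||
           substring(stem, nchar(stem)) %in% c("s", "t"))) {
        word <- stem
      }
      break
    }
  }

  # Step 5a
  if (.pt_ends(word, "e")) {
    stem <- .pt_stem_part(word, "e")
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) word <- stem
  }
  # Step 5b
  if (.pt_measure(word) > 1L && .pt_double_cons(word) &&
      substring(word, nchar(word)) == "l") {
    word <- substring(word, 1L, nchar(word) - 1L)
  }
  word
}
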