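#' Porter suffix-stripping stemmer
#'
#' Classic Porter (1980) stemmer used to conflate inflections of molecular
#' action terms ("phosphorylates", "phosphorylation" -> one stem) before
#' dictionary lookup. Operates on single lowercase words; [stem_action_term()]
#' is the user-facing wrapper that tokenizes, stems to a fixed point and
#' rejoins, guaranteeing idempotence.
#'
#' @param words character vector of words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("binding", "binds", "phosphorylation", "phosphorylates"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, .porter1, character(1), USE.NAMES = FALSE)
}

# consonant/vowel pattern: 'y' is a vowel when preceded by a consonant
.cv_pattern <- function(w) {
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  out <- character(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    out[[i]] <-
      if (ch %in% c("a", "e", "i", "o", "u")) "v"
      else if (ch == "y" && i > 1L && out[[i - 1L]] == "c") "v"
      else "c"
  }
  paste(out, collapse = "")
}

# the measure m: number of vowel->consonant transitions in [C](VC)^m[V]
.measure <- function(w) {
  if (!nzchar(w)) return(0L)
  collapsed <- gsub("(.)\\1+", "\\1", .cv_pattern(w))
  lengths(regmatches(collapsed, gregexpr("vc", collapsed, fixed = TRUE)))
}

.has_vowel <- function(w) nzchar(w) && grepl("v", .cv_pattern(w), fixed = TRUE)

.ends_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  a == b && substr(.cv_pattern(w), n, n) == "c"
}

# *o condition: stem ends cvc where the final consonant is not w, x or y
.ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  p <- .cv_pattern(w)
  substr(p, n - 2L, n) == "cvc" && !substr(w, n, n) %in% c("w", "x", "y")
}

# apply the longest matching suffix rule from an ordered (long-first) table;
# the replacement fires only when measure(stem) > min_m
.apply_rules <- function(w, rules, min_m) {
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suffix[[i]]
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (.measure(stem) > min_m) w <- paste0(stem, rules$repl[[i]])
      return(w)
    }
  }
  w
}

.step2_rules <- data.frame(
  suffix = c("ational", "ization", "iveness", "fulness", "ousness", "tional",
             "biliti", "entli", "ousli", "alism", "aliti", "iviti", "ation",
             "enci", "anci", "izer", "abli", "alli", "ator", "eli"),
  repl   = c("ate", "ize", "ive", "ful", "ous", "tion",
             "ble", "ent", "ous", "al", "al", "ive", "ate",
             "ence", "ance", "ize", "able", "al", "ate", "e"),
  stringsAsFactors = FALSE
)

.step3_rules <- data.frame(
  suffix = c("icate", "ative", "alize", "iciti", "ical", "ful", "ness"),
  repl   = c("ic", "", "al", "ic", "ic", "", ""),
  stringsAsFactors = FALSE
)

.step4_suffixes <- c("ement", "ance", "ence", "able", "ible", "ment", "ant",
                     "ent", "ism", "ate", "iti", "ous", "ive", "ize", "ion",
                     "al", "er", "ic", "ou")

.porter1 <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) w <- sub("sses$", "ss", w)
  else if (endsWith(w, "ies")) w <- sub("ies$", "i", w)
  else if (!endsWith(w, "ss") && endsWith(w, "s")) w <- sub("s$", "", w)

  # step 1b: -eed / -ed / -ing
  cleanup <- FALSE
  if (endsWith(w, "eed")) {
    if (.measure(sub("eed$", "", w)) > 0L) w <- sub("eed$", "ee", w)
  } else if (endsWith(w, "ed") && .has_vowel(sub("ed$", "", w))) {
    w <- sub("ed$", "", w); cleanup <- TRUE
  } else if (endsWith(w, "ing") && .has_vowel(sub("ing$", "", w))) {
    w <- sub("ing$", "", w); cleanup <- TRUE
  }
  if (cleanup) {
    if (grepl("(at|bl|iz)$", w)) w <- paste0(w, "e")
    else if (.ends_double_cons(w) && !grepl("[lsz]$", w)) w <- substr(w, 1L, nchar(w) - 1L)
    else if (.measure(w) == 1L && .ends_cvc(w)) w <- paste0(w, "e")
  }

  # step 1c: terminal y
  if (endsWith(w, "y") && .has_vowel(substr(w, 1L, nchar(w) - 1L)))
    w <- sub("y$", "i", w)

  w <- .apply_rules(w, .step2_rules, 0L)
  w <- .apply_rules(w, .step3_rules, 0L)

  # step 4: drop residual derivational suffixes when m > 1
  for (suf in .step4_suffixes) {
    if (endsWith(w, suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      ok <- .measure(stem) > 1L &&
        (suf != "ion" || grepl("[st]$", stem))
      if (ok) w <- stem
      break
    }
  }

  # step 5a: terminal e
  if (endsWith(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l
  if (.measure(w) > 1L && .ends_double_cons(w) && endsWith(w, "l"))
    w <- substr(w, 1L, nchar(w) - 1L)

  w
}
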