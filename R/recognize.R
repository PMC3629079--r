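#' @name recognize
#' @title Sentence segmentation and dictionary entity recognition
#'
#' @description
#' Titles and abstracts are scanned left-to-right with longest-match,
#' token-boundary-anchored dictionary lookup, one pass per vocabulary
#' category; spans that do not resolve to a vocabulary accession are
#' ignored. Tokens are maximal alphanumeric runs, with hyphens between
#' alphanumerics kept inside a token ("TNF-alpha" is one token). Abstracts
#' are segmented into sentences (several scoring rules are positional or
#' require within-sentence co-occurrence), and a configurable trigger
#' lexicon flags abstracts alluding to additional curatable content in the
#' full text (high-throughput phrases and the like).
NULL

.abbrev_guards <- c("i\\.e\\.", "e\\.g\\.", "et al\\.", "vs\\.", "cf\\.",
                    "Fig\\.", "Figs\\.", "ca\\.", "approx\\.", "No\\.",
                    "St\\.", "Dr\\.", "sp\\.", "spp\\.")

#' Split text into sentence spans
#'
#' Splits at `.`, `!` or `?` followed by whitespace and an uppercase letter
#' or digit; a built-in abbreviation guard (i.e., e.g., et al., vs., cf.,
#' Fig(s)., ca., approx., No., St., Dr., sp(p).) suppresses spurious
#' splits. Offsets are 0-based half-open character positions into `text`.
#'
#' @param text a single string (may be empty).
#' @return tibble with columns `index` (0-based sentence ordinal), `start`,
#'   `end`; empty text yields zero rows.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(index = integer(), start = integer(), end = integer())
  if (is.na(text) || !nzchar(stringr::str_trim(text))) return(empty)

  breaks <- stringr::str_locate_all(text, "[.!?](?=[[:space:]]+[A-Z0-9])")[[1]][, "start"]
  guard_re <- paste0("(?:^|[^[:alnum:]])(?i:",
                     paste(.abbrev_guards, collapse = "|"), ")$")
  keep <- vapply(breaks, function(p) {
    !stringr::str_detect(substr(text, 1L, p), stringr::regex(guard_re))
  }, logical(1))
  breaks <- breaks[keep]

  n <- nchar(text)
  nonspace <- stringr::str_locate_all(text, "[^[:space:]]")[[1]][, "start"]
  first_char <- min(nonspace)
  last_char <- max(nonspace)
  starts <- first_char
  ends <- integer()
  for (p in breaks) {
    ends <- c(ends, p)
    nxt <- stringr::str_locate(substr(text, p + 1L, n), "[^[:space:]]")[1, "start"]
    if (is.na(nxt)) break
    starts <- c(starts, p + nxt)
  }
  if (length(starts) > length(ends)) ends <- c(ends, last_char)
  tibble::tibble(index = seq_along(starts) - 1L,
                 start = as.integer(starts - 1L),
                 end = as.integer(ends))
}

# token runs: alphanumeric, with hyphens joining alphanumerics
.tokenize <- function(text) {
  loc <- stringr::str_locate_all(text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  list(start = unname(loc[, 1]), end = unname(loc[, 2]), n = nrow(loc))
}

.lookup_norm <- function(lexicon, norm, raw, category) {
  if (!nzchar(norm)) return(NA_character_)
  key <- .lex_key(category, norm)
  if (!exists(key, envir = lexicon$index, inherits = FALSE)) return(NA_character_)
  hit <- get(key, envir = lexicon$index)
  if (!is.null(hit$exact) && !raw %in% hit$exact) return(NA_character_)
  hit$accession
}

# longest-match left-to-right scan of one text field for one category
.scan_field <- function(text, lexicon, category, toks = .tokenize(text)) {
  out <- list()
  ntok <- toks$n
  if (ntok == 0L) return(out)
  max_len <- min(lexicon$max_tokens[[category]], ntok)
  if (max_len == 0L) return(out)
  tok_surface <- substring(text, toks$start, toks$end)
  tok_norm <- normalize_surface(tok_surface, category)
  heads <- lexicon$heads[[category]]
  i <- 1L
  while (i <= ntok) {
    matched_len <- 0L
    top <- if (tok_norm[[i]] %in% heads) min(max_len, ntok - i + 1L) else 1L
    for (len in rev(seq_len(top))) {
      j <- i + len - 1L
      cand <- substr(text, toks$start[[i]], toks$end[[j]])
      acc <- if (len == 1L)
        .lookup_norm(lexicon, tok_norm[[i]], cand, category)
      else
        lexicon_lookup(lexicon, cand, category)
      if (!is.na(acc)) {
        out[[length(out) + 1L]] <- list(
          start = as.integer(toks$start[[i]] - 1L),
          end = as.integer(toks$end[[j]]),
          surface = cand, accession = acc)
        matched_len <- len
        break
      }
    }
    i <- i + max(1L, matched_len)
  }
  out
}

.empty_mentions <- function() {
  tibble::tibble(
    pmid = integer(), field = character(), sentence_index = integer(),
    start = integer(), end = integer(), category = character(),
    accession = character(), surface = character(),
    is_target_chemical = logical())
}

#' Find validated vocabulary mentions in a document
#'
#' Scans the title and abstract per category (longest match, left to
#' right, token-boundary anchored; per-category matches never overlap but
#' a span may be claimed by several categories), and matches MeSH
#' chemical-list entries whole-string against chemical surfaces. Every
#' returned mention carries an accession that resolves in the lexicon;
#' unresolvable spans are silently ignored.
#'
#' @param doc a one-row document record (see [parse_records()]).
#' @param lexicon a `triage_lexicon`.
#' @param target_chemical chemical accession the corpus was triaged for;
#'   must exist in the lexicon.
#' @param sentences optional precomputed [split_sentences()] result for
#'   `doc$abstract`.
#' @return a mention tibble: `pmid`, `field` (title/abstract/
#'   chemical_list), `sentence_index` (abstract only), `start`, `end`
#'   (0-based half-open; `NA` for chemical_list), `category`, `accession`,
#'   `surface`, `is_target_chemical`.
#' @export
find_mentions <- function(doc, lexicon, target_chemical, sentences = NULL) {
  stopifnot(inherits(lexicon, "triage_lexicon"), nrow(doc) == 1L)
  chem_accs <- lexicon$entries$accession[lexicon$entries$category == "chemical"]
  if (!target_chemical %in% chem_accs) {
    abort(paste0("target chemical ", target_chemical, " is not in the lexicon"))
  }
  if (is.null(sentences)) sentences <- split_sentences(doc$abstract[[1]])

  field_v <- character(); start_v <- integer(); end_v <- integer()
  cat_v <- character(); acc_v <- character(); surf_v <- character()
  add <- function(field, start, end, category, accession, surface) {
    field_v[[length(field_v) + 1L]] <<- field
    start_v[[length(start_v) + 1L]] <<- start
    end_v[[length(end_v) + 1L]] <<- end
    cat_v[[length(cat_v) + 1L]] <<- category
    acc_v[[length(acc_v) + 1L]] <<- accession
    surf_v[[length(surf_v) + 1L]] <<- surface
  }
  for (field in c("title", "abstract")) {
    text <- doc[[field]][[1]]
    if (is.na(text) || !nzchar(text)) next
    toks <- .tokenize(text)
    for (category in .vocab_categories) {
      for (m in .scan_field(text, lexicon, category, toks)) {
        add(field, m$start, m$end, category, m$accession, m$surface)
      }
    }
  }
  for (entry in doc$chemical_list[[1]]) {
    acc <- lexicon_lookup(lexicon, entry, "chemical")
    if (is.na(acc)) next
    add("chemical_list", NA_integer_, NA_integer_, "chemical", acc, entry)
  }
  if (length(field_v) == 0L) return(.empty_mentions())
  sent_v <- rep(NA_integer_, length(field_v))
  if (nrow(sentences) > 0L) {
    for (i in which(field_v == "abstract")) {
      in_span <- which(sentences$start <= start_v[[i]] &
                       start_v[[i]] < sentences$end)
      if (length(in_span) > 0L) sent_v[[i]] <- sentences$index[[in_span[[1]]]]
    }
  }
  tibble::tibble(
    pmid = doc$pmid[[1]], field = field_v, sentence_index = sent_v,
    start = start_v, end = end_v, category = cat_v, accession = acc_v,
    surface = surf_v,
    is_target_chemical = cat_v == "chemical" & acc_v == target_chemical)
}

#' Default full-text-allusion trigger phrases
#'
#' Reads the trigger lexicon shipped with the package (one phrase per
#' line, `#` comments): high-throughput and full-text-allusion phrases
#' such as "microarray", "proteomic", "transcriptome", "supplementary",
#' "genome-wide".
#'
#' @return character vector of phrases.
#' @export
default_trigger_phrases <- function() {
  read_trigger_lexicon(system.file("extdata", "full_text_triggers.txt",
                                   package = "litriage", mustWork = TRUE))
}

#' Read a trigger-phrase lexicon
#'
#' @param path plain-text file, one phrase per line; `#` starts a comment.
#' @return character vector of phrases.
#' @export
read_trigger_lexicon <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_squish(stringr::str_remove(lines, "#.*$"))
  lines[nzchar(lines)]
}

.escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.trigger_cache <- new.env(parent = emptyenv())

# token-anchored, case-insensitive phrase regex consistent with .tokenize():
# a hyphen joining alphanumerics is token-internal
.phrase_regex <- function(phrase) {
  stringr::regex(paste0(
    "(?<![\\p{L}\\p{N}])(?<![\\p{L}\\p{N}]-)", .escape_regex(phrase),
    "(?![\\p{L}\\p{N}])(?!-[\\p{L}\\p{N}])"), ignore_case = TRUE)
}

#' Detect allusions to curatable content in the full text
#'
#' An abstract earns the flat full-text boost when it alludes to
#' additional relevant information beyond the abstract (typically
#' high-throughput studies whose data live in supplementary tables). The
#' detector looks for any phrase of a configurable trigger lexicon,
#' case-insensitively and anchored at token boundaries.
#'
#' @param doc one-row document record.
#' @param triggers trigger phrases; defaults to the shipped lexicon.
#' @return list with `allusion` (logical) and `triggers` (character vector
#'   of the phrases found, possibly empty).
#' @export
detect_full_text_allusion <- function(doc, triggers = default_trigger_phrases()) {
  text <- doc$abstract[[1]]
  if (is.na(text) || !nzchar(text) || length(triggers) == 0L) {
    return(list(allusion = FALSE, triggers = character()))
  }
  # cheap combined screen first; per-phrase scan only on a hit
  combined <- .trigger_cache$regex
  if (is.null(combined) || !identical(.trigger_cache$phrases, triggers)) {
    combined <- stringr::regex(paste0(
      "(?<![\\p{L}\\p{N}])(?<![\\p{L}\\p{N}]-)(?:",
      paste(.escape_regex(triggers), collapse = "|"),
      ")(?![\\p{L}\\p{N}])(?!-[\\p{L}\\p{N}])"), ignore_case = TRUE)
    .trigger_cache$phrases <- triggers
    .trigger_cache$regex <- combined
  }
  if (!stringr::str_detect(text, combined)) {
    return(list(allusion = FALSE, triggers = character()))
  }
  found <- triggers[vapply(triggers, function(p)
    stringr::str_detect(text, .phrase_regex(p)), logical(1))]
  list(allusion = length(found) > 0L, triggers = unname(found))
}
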