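#' @name lexicon
#' @title Controlled vocabularies and term normalization
#'
#' @description
#' Recognition is dictionary-based: every candidate span in a title or
#' abstract is normalized and looked up against controlled vocabularies of
#' chemicals, genes, diseases and molecular action terms; spans that do not
#' resolve to a vocabulary accession are ignored. This file provides the
#' vocabulary loader, the per-category normalizers (gene-symbol
#' normalization, action-term stemming, case/whitespace folding) and the
#' indexed lexicon used by the recognizer.
NULL

.vocab_categories <- c("chemical", "gene", "disease", "action")

# Greek letter words -> single-letter romanizations used in gene symbols
.greek_map <- c(
  alpha = "a", beta = "b", gamma = "g", delta = "d", epsilon = "e",
  zeta = "z", eta = "h", theta = "q", iota = "i", kappa = "k",
  lambda = "l", mu = "m", nu = "n", xi = "x", omicron = "o",
  pi = "p", rho = "r", sigma = "s", tau = "t", upsilon = "u",
  phi = "f", chi = "c", psi = "y", omega = "w"
)

#' Load a controlled vocabulary from tab-separated text
#'
#' Expected columns: `accession`, `name`, `synonyms` (pipe-separated, may be
#' empty). Entries are returned in file order with `category` stamped on
#' each.
#'
#' @param path path to a UTF-8 tab-separated vocabulary file with a header.
#' @param category one of `"chemical"`, `"gene"`, `"disease"`, `"action"`.
#' @return a tibble with columns `accession`, `category`, `name`,
#'   `synonyms` (list column of character vectors).
#' @export
load_vocabulary <- function(path, category) {
  category <- match.arg(category, .vocab_categories)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("accession", "name", "synonyms")
  if (!all(required %in% names(tab))) {
    abort(paste0("vocabulary file ", path, " must have columns: ",
                 paste(required, collapse = ", ")))
  }
  if (nrow(tab) == 0L) {
    return(tibble::tibble(accession = character(), category = character(),
                          name = character(), synonyms = list()))
  }
  if (any(is.na(tab$name) | !nzchar(trimws(tab$name)))) {
    abort("vocabulary entries must have a non-empty name")
  }
  dup <- tab$accession[duplicated(tab$accession)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate accession(s) in ", category, " vocabulary: ",
                 paste(unique(dup), collapse = ", ")))
  }
  syn <- lapply(tab$synonyms, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character() else
      trimws(strsplit(s, "|", fixed = TRUE)[[1]])
  })
  syn <- lapply(syn, function(s) s[nzchar(s)])
  tibble::tibble(
    accession = tab$accession,
    category = category,
    name = trimws(tab$name),
    synonyms = syn
  )
}

#' Normalize a gene symbol
#'
#' Case-folds, maps whole-word Greek letter names to their single-letter
#' romanizations (alpha -> a, ..., omega -> w), and removes hyphens and
#' internal spaces, so that "TNF-alpha", "TNF alpha" and "tnfa" share one
#' key. Idempotent.
#'
#' @param surface non-empty character vector of gene surfaces.
#' @return normalized keys, same length.
#' @examples
#' normalize_gene_symbol(c("TNF-alpha", "Mapk 3"))
#' @export
normalize_gene_symbol <- function(surface) {
  stopifnot(is.character(surface), all(nzchar(surface)))
  x <- stringr::str_to_lower(surface)
  any_greek <- paste0("(?<![[:alnum:]])(?:",
                      paste(names(.greek_map), collapse = "|"),
                      ")(?![[:alnum:]])")
  has_greek <- stringr::str_detect(x, any_greek)
  if (any(has_greek)) {
    for (greek in names(.greek_map)) {
      x[has_greek] <- stringr::str_replace_all(
        x[has_greek], paste0("(?<![[:alnum:]])", greek, "(?![[:alnum:]])"),
        .greek_map[[greek]])
    }
  }
  stringr::str_remove_all(x, "[-[:space:]]+")
}

#' Stem an action term
#'
#' Lower-cases, splits on whitespace, Porter-stems each word to a fixed
#' point and rejoins with single spaces, so inflections of an action term
#' ("binds", "binding") share a stem. Idempotent by construction.
#'
#' @param surface non-empty character vector.
#' @return stemmed keys, same length.
#' @examples
#' stem_action_term(c("phosphorylation", "phosphorylates"))
#' @export
stem_action_term <- function(surface) {
  stopifnot(is.character(surface), all(nzchar(surface)))
  x <- tolower(surface)
  simple <- !grepl("[[:space:]]", x)
  out <- character(length(x))
  out[simple] <- vapply(x[simple], .stem_word_cached, character(1),
                        USE.NAMES = FALSE)
  for (i in which(!simple)) {
    words <- strsplit(stringr::str_squish(x[[i]]), " ", fixed = TRUE)[[1]]
    out[[i]] <- paste(vapply(words, .stem_word_cached, character(1)),
                      collapse = " ")
  }
  out
}

# fixed-point Porter stem of a single lowercase word, memoized (corpus
# tokens repeat heavily, and stemming dominates recognition cost otherwise)
.stem_cache <- new.env(parent = emptyenv())

.stem_word_cached <- function(w) {
  hit <- .stem_cache[[w]]
  if (!is.null(hit)) return(hit)
  out <- w
  for (i in 1:5) {
    nxt <- .porter1(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  if (nchar(w) < 30L) .stem_cache[[w]] <- out
  out
}

#' Normalize a surface form for lookup under a category
#'
#' Genes use [normalize_gene_symbol()], actions use [stem_action_term()],
#' chemicals and diseases are case-folded with whitespace runs collapsed.
#'
#' @param surface character vector.
#' @param category vocabulary category.
#' @return normalized keys.
#' @export
normalize_surface <- function(surface, category) {
  category <- match.arg(category, .vocab_categories)
  empty <- !nzchar(surface)
  out <- character(length(surface))
  s <- surface[!empty]
  if (length(s) > 0L) {
    out[!empty] <- switch(category,
      gene = normalize_gene_symbol(s),
      action = stem_action_term(s),
      stringr::str_squish(stringr::str_to_lower(s))
    )
  }
  out
}

.lex_key <- function(category, norm) paste0(category, "\x1f", norm)

#' Build an indexed lexicon from vocabulary entries
#'
#' Every name and synonym is inserted under its normalized surface form,
#' per category (the same surface may resolve to one entry per category).
#' Within a category, two accessions claiming the same surface collide; the
#' lexicographically smallest accession wins and a warning is emitted.
#' Surfaces whose normalized form has two characters or fewer additionally
#' require an exact-case match at recognition time, to suppress false hits
#' on short stopword-like symbols.
#'
#' @param entries a tibble as returned by [load_vocabulary()] (categories
#'   may be mixed; bind rows of several vocabularies).
#' @return an object of class `triage_lexicon`.
#' @export
build_index <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("accession", "category", "name", "synonyms") %in% names(entries)))
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(entries))) {
    cat_i <- entries$category[[i]]
    acc_i <- entries$accession[[i]]
    surfaces <- unique(c(entries$name[[i]], entries$synonyms[[i]]))
    for (sf in surfaces) {
      norm <- normalize_surface(sf, cat_i)
      if (!nzchar(norm)) next
      key <- .lex_key(cat_i, norm)
      hit <- if (exists(key, envir = index, inherits = FALSE))
        get(key, envir = index) else NULL
      if (is.null(hit)) {
        assign(key, list(accession = acc_i, exact = if (nchar(norm) <= 2L) sf),
               envir = index)
      } else if (!identical(hit$accession, acc_i)) {
        keep <- min(hit$accession, acc_i)
        warn(paste0("surface '", sf, "' (", cat_i, ") claimed by ",
                    hit$accession, " and ", acc_i, "; keeping ", keep))
        if (keep != hit$accession) {
          assign(key, list(accession = acc_i,
                           exact = if (nchar(norm) <= 2L) sf), envir = index)
        }
      } else if (nchar(norm) <= 2L) {
        assign(key, list(accession = acc_i, exact = unique(c(hit$exact, sf))),
               envir = index)
      }
    }
  }
  max_tokens <- vapply(.vocab_categories, function(cat_i) {
    rows <- entries$category == cat_i
    if (!any(rows)) return(0L)
    surfaces <- unlist(c(entries$name[rows], entries$synonyms[rows]))
    if (length(surfaces) == 0L) return(0L)
    max(stringr::str_count(stringr::str_squish(surfaces), " ") + 1L)
  }, integer(1))
  # normalized first words of multi-word surfaces, used by the recognizer
  # to prune multi-token candidate generation
  heads <- lapply(setNames(nm = .vocab_categories), function(cat_i) {
    rows <- entries$category == cat_i
    if (!any(rows)) return(character())
    surfaces <- stringr::str_squish(
      unlist(c(entries$name[rows], entries$synonyms[rows])))
    multi <- surfaces[stringr::str_detect(surfaces, " ")]
    if (length(multi) == 0L) return(character())
    first <- vapply(strsplit(multi, " ", fixed = TRUE), `[[`, character(1), 1L)
    unique(normalize_surface(first, cat_i))
  })
  structure(
    list(entries = tibble::as_tibble(entries), index = index,
         max_tokens = max_tokens, heads = heads),
    class = "triage_lexicon"
  )
}

#' Resolve a surface form against the lexicon
#'
#' @param lexicon a `triage_lexicon`.
#' @param surface raw surface text (pre-normalization).
#' @param category vocabulary category to look under.
#' @return the matching accession, or `NA_character_` if the surface does
#'   not resolve (including short surfaces failing the exact-case check).
#' @export
lexicon_lookup <- function(lexicon, surface, category) {
  stopifnot(inherits(lexicon, "triage_lexicon"))
  vapply(surface, function(sf) {
    if (!nzchar(sf)) return(NA_character_)
    norm <- normalize_surface(sf, category)
    if (!nzchar(norm)) return(NA_character_)
    key <- .lex_key(category, norm)
    if (!exists(key, envir = lexicon$index, inherits = FALSE)) return(NA_character_)
    hit <- get(key, envir = lexicon$index)
    if (!is.null(hit$exact) && !sf %in% hit$exact) return(NA_character_)
    hit$accession
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.triage_lexicon <- function(x, ...) {
  counts <- table(factor(x$entries$category, levels = .vocab_categories))
  cat("<triage_lexicon> ", nrow(x$entries), " entries (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
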