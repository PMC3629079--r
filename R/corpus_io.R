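#' @name corpus_io
#' @title Reading and writing corpus artifacts
#'
#' @description
#' The pipeline consumes PubMed eFetch XML (`PubmedArticleSet`) and
#' exchanges its own artifacts as tab-separated text: ranked lists
#' (pmid, drs, bin, target_chemical, title) and curation logs (one row per
#' curated interaction, or a single row for a rejected article). All text
#' is UTF-8; whitespace runs are collapsed to single spaces at parse time
#' and XML entities are decoded.
NULL

.squish_na <- function(x) {
  x <- stringr::str_squish(x)
  x[is.na(x)] <- ""
  x
}

#' Parse PubMed eFetch XML into document records
#'
#' Reads a `PubmedArticleSet`, extracting PMID, `ArticleTitle`, the
#' abstract (`AbstractText` sections concatenated in document order with a
#' single space), `Journal/Title` and the MeSH chemical list
#' (`ChemicalList/Chemical/NameOfSubstance`). Missing title, abstract or
#' chemical list map to empty values; input order is preserved and no
#' record is dropped.
#'
#' @param xml path, URL or literal XML string accepted by [xml2::read_xml()].
#' @return a tibble with columns `pmid` (integer), `title`, `abstract`,
#'   `journal_name` (character), `chemical_list` (list of character
#'   vectors), `pub_year` (integer, `NA` when absent).
#' @export
parse_records <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) {
    abort(paste0("malformed XML: ", conditionMessage(e)))
  })
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- purrr::map(articles, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    abstract_parts <- xml2::xml_text(
      xml2::xml_find_all(a, ".//Article/Abstract/AbstractText"))
    chems <- xml2::xml_text(
      xml2::xml_find_all(a, ".//ChemicalList/Chemical/NameOfSubstance"))
    chems <- .squish_na(chems)
    year <- xml2::xml_text(xml2::xml_find_first(
      a, ".//Article/Journal/JournalIssue/PubDate/Year"))
    tibble::tibble(
      pmid = suppressWarnings(as.integer(pmid)),
      title = .squish_na(xml2::xml_text(
        xml2::xml_find_first(a, ".//Article/ArticleTitle"))),
      abstract = stringr::str_squish(
        paste(abstract_parts[nzchar(.squish_na(abstract_parts))], collapse = " ")),
      journal_name = .squish_na(xml2::xml_text(
        xml2::xml_find_first(a, ".//Article/Journal/Title"))),
      chemical_list = list(chems[nzchar(chems)]),
      pub_year = suppressWarnings(as.integer(year))
    )
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(pmid = integer(), title = character(),
                          abstract = character(), journal_name = character(),
                          chemical_list = list(), pub_year = integer())
  }
  if (anyNA(out$pmid) || any(out$pmid <= 0L)) {
    abort("every PubmedArticle must carry a positive integer PMID")
  }
  dup <- unique(out$pmid[duplicated(out$pmid)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate PMID(s) in corpus: ", paste(dup, collapse = ", ")))
  }
  out
}

.curation_statuses <- c("curated", "rejected")
.interaction_kinds <- c("chemical-gene", "chemical-disease", "gene-disease")
.interaction_sources <- c("abstract", "full_text")
.interaction_assays <- c("in_vivo", "in_vitro", "high_throughput", "unspecified")

#' Read a curation log
#'
#' Tab-separated with header columns `pmid`, `status`, `minutes`,
#' `reject_reason`, `kind`, `actors`, `source`, `novel`, `assay`. Rejected
#' articles occupy one row with empty interaction columns; curated articles
#' have one row per extracted interaction (`actors` is a pipe-separated
#' list of `category:accession` pairs). Rows are grouped by `pmid`.
#'
#' @param path path to the log.
#' @return a tibble with one row per article: `pmid`, `status`, `minutes`,
#'   `reject_reason`, and `interactions` (list column of tibbles with
#'   columns `kind`, `actors` (list of character), `source`, `novel`,
#'   `assay`).
#' @export
read_curation_log <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    pmid = readr::col_integer(), status = readr::col_character(),
    minutes = readr::col_double(), reject_reason = readr::col_character(),
    kind = readr::col_character(), actors = readr::col_character(),
    source = readr::col_character(), novel = readr::col_logical(),
    assay = readr::col_character()), progress = FALSE)
  bad_status <- setdiff(unique(tab$status), .curation_statuses)
  if (length(bad_status) > 0L) {
    abort(paste0("unknown curation status: ", paste(bad_status, collapse = ", ")))
  }
  if (any(tab$minutes < 0, na.rm = TRUE)) abort("minutes must be non-negative")
  groups <- split(tab, tab$pmid)
  recs <- purrr::map(groups, function(g) {
    status <- unique(g$status)
    if (length(status) > 1L) {
      abort(paste0("pmid ", g$pmid[[1]], " has conflicting statuses"))
    }
    minutes <- unique(g$minutes)
    if (length(minutes) > 1L) {
      abort(paste0("pmid ", g$pmid[[1]], " has conflicting minutes"))
    }
    has_interaction <- !is.na(g$kind) & nzchar(.squish_na(g$kind))
    if (status == "rejected" && any(has_interaction)) {
      abort(paste0("rejected pmid ", g$pmid[[1]], " carries interactions"))
    }
    ints <- g[has_interaction, , drop = FALSE]
    interactions <- tibble::tibble(
      kind = ints$kind,
      actors = lapply(ints$actors, function(a)
        trimws(strsplit(a, "|", fixed = TRUE)[[1]])),
      source = ints$source,
      novel = ints$novel,
      assay = ints$assay
    )
    bad_kind <- setdiff(interactions$kind, .interaction_kinds)
    if (length(bad_kind) > 0L) {
      abort(paste0("unknown interaction kind: ", paste(bad_kind, collapse = ", ")))
    }
    tibble::tibble(
      pmid = g$pmid[[1]], status = status, minutes = minutes,
      reject_reason = .squish_na(g$reject_reason[[1]]),
      interactions = list(interactions)
    )
  })
  dplyr::arrange(dplyr::bind_rows(recs), pmid)
}

#' Write a curation log
#'
#' Inverse of [read_curation_log()]; used by the synthetic-corpus
#' generator and for round-tripping.
#'
#' @param log a tibble as returned by [read_curation_log()].
#' @param path output path.
#' @export
write_curation_log <- function(log, path) {
  rows <- purrr::pmap(log, function(pmid, status, minutes, reject_reason,
                                    interactions, ...) {
    if (nrow(interactions) == 0L) {
      tibble::tibble(pmid = pmid, status = status, minutes = minutes,
                     reject_reason = reject_reason, kind = NA_character_,
                     actors = NA_character_, source = NA_character_,
                     novel = NA, assay = NA_character_)
    } else {
      tibble::tibble(pmid = pmid, status = status, minutes = minutes,
                     reject_reason = reject_reason, kind = interactions$kind,
                     actors = vapply(interactions$actors, paste,
                                     character(1), collapse = "|"),
                     source = interactions$source, novel = interactions$novel,
                     assay = interactions$assay)
    }
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Write a ranked list
#'
#' Tab-separated columns `pmid`, `drs`, `bin`, `target_chemical`, `title`,
#' in the order given (callers rank first). Round-trips through
#' [read_ranked_list()] without loss of the (pmid, drs, bin) triples.
#'
#' @param scored_docs tibble with at least columns `pmid`, `drs`, `bin`,
#'   `target_chemical`, `title`, already ordered.
#' @param path output path.
#' @export
write_ranked_list <- function(scored_docs, path) {
  cols <- c("pmid", "drs", "bin", "target_chemical", "title")
  stopifnot(all(cols %in% names(scored_docs)))
  readr::write_tsv(scored_docs[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a ranked list written by [write_ranked_list()]
#'
#' @param path path to the TSV.
#' @return tibble with columns `pmid`, `drs`, `bin`, `target_chemical`,
#'   `title`, in file order.
#' @export
read_ranked_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    pmid = readr::col_integer(), drs = readr::col_integer(),
    bin = readr::col_character(), target_chemical = readr::col_character(),
    title = readr::col_character()), progress = FALSE)
}

#' Serialize document records to PubMed eFetch XML
#'
#' Used by the synthetic-corpus generator so that generated corpora enter
#' the pipeline through the same parser as real ones.
#'
#' @param docs tibble of document records (see [parse_records()]).
#' @param path output path.
#' @export
write_corpus_xml <- function(docs, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(docs))) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", as.character(docs$pmid[[i]]))
    article <- xml2::xml_add_child(cit, "Article")
    journal <- xml2::xml_add_child(article, "Journal")
    xml2::xml_add_child(journal, "Title", docs$journal_name[[i]])
    if (!is.na(docs$pub_year[[i]])) {
      issue <- xml2::xml_add_child(journal, "JournalIssue")
      pd <- xml2::xml_add_child(issue, "PubDate")
      xml2::xml_add_child(pd, "Year", as.character(docs$pub_year[[i]]))
    }
    xml2::xml_add_child(article, "ArticleTitle", docs$title[[i]])
    if (nzchar(docs$abstract[[i]])) {
      ab <- xml2::xml_add_child(article, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", docs$abstract[[i]])
    }
    chems <- docs$chemical_list[[i]]
    if (length(chems) > 0L) {
      cl <- xml2::xml_add_child(cit, "ChemicalList")
      for (ch in chems) {
        c_el <- xml2::xml_add_child(cl, "Chemical")
        xml2::xml_add_child(c_el, "NameOfSubstance", ch)
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
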