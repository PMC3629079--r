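#' @name score
#' @title The 13-rule document relevancy score (DRS)
#'
#' @description
#' Each article receives an integer document relevancy score: the sum of
#' thirteen additive rules evaluated independently on its validated
#' mentions. The rules reward an abstract alluding to full-text content
#' (flat 50), target-chemical mentions in the title (10 each),
#' within-sentence co-occurrence of an action term with two entity
#' categories (8 per sentence-pair), the target chemical on the MeSH
#' chemical list (flat 5), target-chemical mentions in the first / second /
#' second-to-last / last abstract sentence (5/3/3/3 each), action-term and
#' entity occurrences in the abstract (4/2 per occurrence when the
#' abstract contains both genes and chemicals, otherwise 1/1), and
#' publication in a priority journal (flat 1). All point values and the
#' priority-journal list live in a [default_rule_config()] and can be
#' re-weighted without code change.
NULL

.rule_ids <- c(
  "full_text_boost", "target_in_title", "cooccurrence",
  "target_in_chemical_list", "target_in_first_sentence",
  "action_with_gene_chem", "target_in_second_sentence",
  "target_in_second_last_sentence", "target_in_last_sentence",
  "entity_with_gene_chem", "action_without_gene_chem",
  "entity_without_gene_chem", "priority_journal")

.default_points <- c(
  full_text_boost = 50L, target_in_title = 10L, cooccurrence = 8L,
  target_in_chemical_list = 5L, target_in_first_sentence = 5L,
  action_with_gene_chem = 4L, target_in_second_sentence = 3L,
  target_in_second_last_sentence = 3L, target_in_last_sentence = 3L,
  entity_with_gene_chem = 2L, action_without_gene_chem = 1L,
  entity_without_gene_chem = 1L, priority_journal = 1L)

.default_priority_journals <- c(
  "Nature", "Science", "Environment Health Perspectives",
  "Toxicological Sciences", "Cell", "The Journal of Biological Chemistry")

#' Default rule configuration
#'
#' @param points named integer vector of per-rule point values; names must
#'   be the 13 rule identifiers.
#' @param priority_journals journal names earning the flat priority point.
#' @param trigger_phrases full-text-allusion trigger phrases; `NULL` uses
#'   the shipped lexicon.
#' @return a list of class `rule_config`.
#' @export
default_rule_config <- function(points = .default_points,
                                priority_journals = .default_priority_journals,
                                trigger_phrases = NULL) {
  stopifnot(setequal(names(points), .rule_ids),
            all(points >= 0), all(points == as.integer(points)))
  structure(list(points = points[.rule_ids],
                 priority_journals = priority_journals,
                 trigger_phrases = trigger_phrases),
            class = "rule_config")
}

.journal_key <- function(x) {
  x <- stringr::str_squish(stringr::str_replace_all(
    stringr::str_to_lower(x), "[^[:alnum:]]+", " "))
  stringr::str_remove(x, "^the ")
}

#' Is a journal on the priority list?
#'
#' Comparison is case-insensitive after trimming, collapsing whitespace
#' and punctuation, and dropping a leading "The" (MEDLINE journal strings
#' vary in these respects).
#'
#' @param journal_name journal name(s) as printed in the record.
#' @param config a `rule_config`.
#' @return logical vector.
#' @export
is_priority_journal <- function(journal_name, config = default_rule_config()) {
  .journal_key(journal_name) %in% .journal_key(config$priority_journals)
}

#' Count within-sentence action/entity-pair co-occurrences
#'
#' For each abstract sentence and each of the category pairs
#' gene+chemical, gene+disease, chemical+disease: one occurrence when the
#' sentence contains at least one action-term mention and at least one
#' mention of each category in the pair. Returns the sum over sentences
#' and pairs.
#'
#' @param mentions mention tibble (abstract rows are used).
#' @param sentences sentence spans from [split_sentences()].
#' @return non-negative integer count.
#' @export
count_cooccurrences <- function(mentions, sentences) {
  ab <- mentions[mentions$field == "abstract" & !is.na(mentions$sentence_index), ]
  if (nrow(ab) == 0L || nrow(sentences) == 0L) return(0L)
  pairs <- list(c("gene", "chemical"), c("gene", "disease"),
                c("chemical", "disease"))
  total <- 0L
  for (s in unique(ab$sentence_index)) {
    cats <- unique(ab$category[ab$sentence_index == s])
    if (!"action" %in% cats) next
    for (p in pairs) if (all(p %in% cats)) total <- total + 1L
  }
  total
}

#' Score one document with the 13-rule algorithm
#'
#' All rules are evaluated independently and their contributions summed
#' (a first-sentence target-chemical mention also counts toward the
#' entity-occurrence rule; in one- or two-sentence abstracts the
#' positional rules may coincide and stack). Title and chemical-list
#' mentions do not feed the abstract occurrence/action rules. The
#' "part 1"/"part 2" variants of the action and entity rules are switched
#' by whether the abstract contains both a gene and a chemical mention.
#'
#' @param doc one-row document record.
#' @param mentions mentions for `doc` from [find_mentions()].
#' @param sentences sentence spans for `doc$abstract`.
#' @param target_chemical target chemical accession.
#' @param config a `rule_config`.
#' @return a list of class `scored_document`: `pmid`, `target_chemical`,
#'   `drs` (non-negative integer), `bin`, and `hits` (tibble with columns
#'   `rule_id`, `occurrences`, `points_per_occurrence`, `total`).
#' @export
score_document <- function(doc, mentions, sentences, target_chemical,
                           config = default_rule_config()) {
  stopifnot(inherits(config, "rule_config"), nrow(doc) == 1L)
  n_sent <- nrow(sentences)
  ab <- mentions[mentions$field == "abstract", ]
  if (any(!is.na(ab$sentence_index) & (ab$sentence_index < 0L |
                                       ab$sentence_index >= n_sent))) {
    abort("mention sentence_index outside the provided sentence spans")
  }

  g_flag <- any(ab$category == "gene") && any(ab$category == "chemical")
  tgt_ab <- ab[ab$is_target_chemical, ]
  occ <- setNames(integer(length(.rule_ids)), .rule_ids)

  triggers <- config$trigger_phrases
  allusion <- if (is.null(triggers)) detect_full_text_allusion(doc)
              else detect_full_text_allusion(doc, triggers)
  occ[["full_text_boost"]] <- as.integer(allusion$allusion)
  occ[["target_in_title"]] <-
    sum(mentions$field == "title" & mentions$is_target_chemical)
  occ[["cooccurrence"]] <- count_cooccurrences(mentions, sentences)
  occ[["target_in_chemical_list"]] <-
    as.integer(any(mentions$field == "chemical_list" &
                   mentions$is_target_chemical))
  occ[["target_in_first_sentence"]] <- sum(tgt_ab$sentence_index == 0L,
                                           na.rm = TRUE)
  occ[["target_in_second_sentence"]] <- sum(tgt_ab$sentence_index == 1L,
                                            na.rm = TRUE)
  occ[["target_in_second_last_sentence"]] <-
    sum(tgt_ab$sentence_index == n_sent - 2L, na.rm = TRUE)
  occ[["target_in_last_sentence"]] <-
    sum(tgt_ab$sentence_index == n_sent - 1L, na.rm = TRUE)
  n_action <- sum(ab$category == "action")
  n_entity <- sum(ab$category %in% c("chemical", "gene", "disease"))
  occ[["action_with_gene_chem"]] <- if (g_flag) n_action else 0L
  occ[["action_without_gene_chem"]] <- if (g_flag) 0L else n_action
  occ[["entity_with_gene_chem"]] <- if (g_flag) n_entity else 0L
  occ[["entity_without_gene_chem"]] <- if (g_flag) 0L else n_entity
  occ[["priority_journal"]] <-
    as.integer(is_priority_journal(doc$journal_name[[1]], config))

  hits <- tibble::tibble(
    rule_id = .rule_ids,
    occurrences = as.integer(occ),
    points_per_occurrence = as.integer(config$points[.rule_ids]),
    total = as.integer(occ) * as.integer(config$points[.rule_ids]))
  drs <- sum(hits$total)
  structure(list(pmid = doc$pmid[[1]], target_chemical = target_chemical,
                 drs = drs, bin = assign_bin(drs), hits = hits),
            class = "scored_document")
}

#' @export
print.scored_document <- function(x, ...) {
  cat("<scored_document> pmid ", x$pmid, ": DRS ", x$drs, " (", x$bin, ")\n",
      sep = "")
  fired <- x$hits[x$hits$occurrences > 0L, ]
  if (nrow(fired) > 0L) print(fired)
  invisible(x)
}

#' Recognize and score every document of a corpus
#'
#' Runs [split_sentences()], [find_mentions()] and [score_document()] over
#' a corpus tibble.
#'
#' @param docs document records from [parse_records()].
#' @param lexicon a `triage_lexicon`.
#' @param target_chemical target chemical accession.
#' @param config a `rule_config`.
#' @return a tibble with one row per document: `pmid`, `title`,
#'   `target_chemical`, `drs`, `bin`, plus list columns `hits` and
#'   `mentions`.
#' @export
score_corpus <- function(docs, lexicon, target_chemical,
                         config = default_rule_config()) {
  # resolve the trigger lexicon once for the whole corpus
  if (is.null(config$trigger_phrases)) {
    config$trigger_phrases <- default_trigger_phrases()
  }
  rows <- purrr::map(seq_len(nrow(docs)), function(i) {
    doc <- docs[i, ]
    sentences <- split_sentences(doc$abstract[[1]])
    mentions <- find_mentions(doc, lexicon, target_chemical, sentences)
    scored <- score_document(doc, mentions, sentences, target_chemical, config)
    tibble::tibble(pmid = doc$pmid[[1]], title = doc$title[[1]],
                   target_chemical = target_chemical,
                   drs = scored$drs, bin = scored$bin,
                   hits = list(scored$hits), mentions = list(mentions))
  })
  dplyr::bind_rows(rows)
}
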