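#' @name evaluate
#' @title Ranking-quality and curation-productivity metrics
#'
#' @description
#' A ranking is judged by how highly it places the articles a biocurator
#' actually curated: average precision per target chemical, mean average
#' precision (MAP) across chemicals, macro-averaged recall of curated
#' actors against mined mentions, per-bin curation tables (counts,
#' minutes, curation/rejection rates, interactions), and quartile
#' comparisons of a DRS ranking against the PMID recency baseline,
#' including the interaction yield rate (interactions curated per minute).
#' Precision of mined actors is deliberately not computed: the universe of
#' cited-but-uncurated actors in an abstract is unknown, and curated
#' actors may live only in the full text.
NULL

#' Round half away from zero
#'
#' Plain half-up rounding (0.5 -> 1), used for printed percentages; R's
#' `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# percentages at the printed precision: integers, one decimal below 1%
.pct <- function(frac) {
  p <- 100 * frac
  ifelse(is.na(p), NA_real_,
         ifelse(abs(p) < 1, round_half_up(p, 1), round_half_up(p, 0)))
}

#' Average precision of one ranked relevance list
#'
#' Mean over the relevant items of (number of relevant items at or above
#' its rank) / rank.
#'
#' @param relevance logical vector in rank order (`TRUE` = relevant).
#' @return fraction in (0, 1].
#' @export
average_precision <- function(relevance) {
  stopifnot(is.logical(relevance))
  if (!any(relevance)) abort("average precision undefined: no relevant item")
  ranks <- which(relevance)
  mean(cumsum(relevance)[ranks] / ranks)
}

#' Mean average precision over target chemicals
#'
#' Unweighted mean of per-chemical average precisions. Chemicals with no
#' relevant (curated) document are skipped with a warning.
#'
#' @param rankings named list: one logical relevance vector (in rank
#'   order) per target chemical.
#' @return fraction in (0, 1].
#' @export
map_score <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 1L)
  has_rel <- vapply(rankings, any, logical(1))
  if (!any(has_rel)) abort("no target chemical has a relevant document")
  if (!all(has_rel)) {
    warn(paste0("skipping target chemical(s) with no relevant document: ",
                paste(names(rankings)[!has_rel], collapse = ", ")))
  }
  aps <- vapply(rankings[has_rel], average_precision, numeric(1))
  mean(aps)
}

#' Macro-averaged recall of curated actors, by category
#'
#' For each group (reference or target chemical) and category: the number
#' of distinct curated accessions also present among the mined mentions,
#' divided by the number of distinct curated accessions. A curated actor
#' found through any synonym counts, since synonyms resolve to the same
#' accession. The macro-average is the unweighted mean over groups with at
#' least one curated actor in that category.
#'
#' @param curated_actors tibble with columns `group`, `category`,
#'   `accession` — the actors biocurators used in interactions.
#' @param mined_mentions tibble with columns `group`, `category`,
#'   `accession` — validated mentions found by the recognizer.
#' @return named numeric vector over `chemical`, `gene`, `disease`,
#'   `action` (`NA` for categories with no curated actor anywhere).
#' @export
recall_by_category <- function(curated_actors, mined_mentions) {
  stopifnot(all(c("group", "category", "accession") %in% names(curated_actors)),
            all(c("group", "category", "accession") %in% names(mined_mentions)))
  if (nrow(curated_actors) == 0L) {
    abort("recall undefined: no curated actors in any group")
  }
  out <- setNames(rep(NA_real_, length(.vocab_categories)), .vocab_categories)
  for (cat_i in .vocab_categories) {
    cur <- curated_actors[curated_actors$category == cat_i, ]
    if (nrow(cur) == 0L) next
    per_group <- vapply(unique(cur$group), function(g) {
      curated <- unique(cur$accession[cur$group == g])
      mined <- unique(mined_mentions$accession[
        mined_mentions$group == g & mined_mentions$category == cat_i])
      length(intersect(curated, mined)) / length(curated)
    }, numeric(1))
    out[[cat_i]] <- mean(per_group)
  }
  out
}

.count_interactions <- function(interactions) {
  vapply(interactions, nrow, integer(1))
}

#' Per-bin curation metrics table
#'
#' Reproduces the per-bin curation bookkeeping: articles reviewed, curated
#' and rejected (with shares of the bin), minutes spent on curated and
#' rejected articles (with shares of the bin's minutes), curation rate
#' (minutes per curated article) and rejection rate (minutes per rejected
#' article) with their standard deviations, and interactions extracted
#' (share of the corpus total). Percentage columns (`pct_*`) are rounded
#' half-up to the precision such tables print (integers; one decimal below
#' 1%); the raw fractions are kept alongside. Rates over zero articles are
#' reported as `NA`, not 0.
#'
#' @param scored_docs tibble with `pmid` and `bin` (and/or `drs`).
#' @param curation_log curation records from [read_curation_log()]; every
#'   logged pmid must be present among `scored_docs`.
#' @return a tibble with one row per bin (`total`, `high`, `medium`,
#'   `low`).
#' @export
bin_metrics <- function(scored_docs, curation_log) {
  missing <- setdiff(curation_log$pmid, scored_docs$pmid)
  if (length(missing) > 0L) {
    abort(paste0("curation log pmid(s) absent from corpus: ",
                 paste(missing, collapse = ", ")))
  }
  if (!"bin" %in% names(scored_docs)) {
    scored_docs$bin <- assign_bin(scored_docs$drs)
  }
  log <- dplyr::left_join(curation_log,
                          scored_docs[, c("pmid", "bin")], by = "pmid")
  log$n_int <- .count_interactions(log$interactions)
  total_int <- sum(log$n_int)

  one_bin <- function(rows, label) {
    cur <- rows[rows$status == "curated", ]
    rej <- rows[rows$status == "rejected", ]
    tibble::tibble(
      bin = label,
      n_reviewed = nrow(rows),
      n_curated = nrow(cur),
      frac_curated = nrow(cur) / nrow(rows),
      n_rejected = nrow(rej),
      frac_rejected = nrow(rej) / nrow(rows),
      minutes_reviewed = sum(rows$minutes),
      minutes_curated = sum(cur$minutes),
      frac_minutes_curated = sum(cur$minutes) / sum(rows$minutes),
      minutes_rejected = sum(rej$minutes),
      frac_minutes_rejected = sum(rej$minutes) / sum(rows$minutes),
      curation_rate = if (nrow(cur) > 0L) sum(cur$minutes) / nrow(cur) else NA_real_,
      curation_rate_sd = if (nrow(cur) > 1L) sd(cur$minutes) else NA_real_,
      rejection_rate = if (nrow(rej) > 0L) sum(rej$minutes) / nrow(rej) else NA_real_,
      rejection_rate_sd = if (nrow(rej) > 1L) sd(rej$minutes) else NA_real_,
      n_interactions = sum(rows$n_int),
      frac_interactions = if (total_int > 0L) sum(rows$n_int) / total_int
                          else NA_real_)
  }
  bins <- c("high", "medium", "low")
  out <- dplyr::bind_rows(
    one_bin(log, "total"),
    purrr::map(bins, function(b) one_bin(log[log$bin == b, ], b)))
  out$pct_curated <- .pct(out$frac_curated)
  out$pct_rejected <- .pct(out$frac_rejected)
  out$pct_minutes_curated <- .pct(out$frac_minutes_curated)
  out$pct_minutes_rejected <- .pct(out$frac_minutes_rejected)
  out$pct_interactions <- .pct(out$frac_interactions)
  out
}

#' Quartile comparison of a DRS ranking against the PMID baseline
#'
#' Cuts each ranking into progressive quantile groups and tabulates, per
#' ranking and group: curated/rejected counts, novel interactions by kind,
#' total interactions, minutes, and the interaction yield rate (all
#' interactions, novel plus repeated, divided by minutes spent in the
#' group).
#'
#' @param ranked_by_drs,ranked_by_pmid the same scored corpus under the
#'   two orderings (see [rank_documents()]); must hold identical pmid
#'   sets.
#' @param curation_log curation records covering the corpus.
#' @param k number of groups (default 4).
#' @return tibble with one row per (ranking, quartile).
#' @export
quartile_comparison <- function(ranked_by_drs, ranked_by_pmid, curation_log,
                                k = 4L) {
  if (!setequal(ranked_by_drs$pmid, ranked_by_pmid$pmid) ||
      nrow(ranked_by_drs) != nrow(ranked_by_pmid)) {
    abort("the two rankings must be permutations of the same pmids")
  }
  log <- curation_log
  log$n_int <- .count_interactions(log$interactions)
  novel_by_kind <- function(interactions, kind_i) {
    sum(vapply(interactions, function(x) sum(x$novel & x$kind == kind_i),
               integer(1)))
  }
  one_ranking <- function(ranked, label) {
    groups <- quantile_groups(ranked, k)
    purrr::map(seq_len(k), function(qi) {
      pmids <- ranked$pmid[groups == qi]
      rows <- log[log$pmid %in% pmids, ]
      minutes <- sum(rows$minutes)
      n_int <- sum(rows$n_int)
      tibble::tibble(
        ranking = label, quartile = qi, n_documents = length(pmids),
        n_curated = sum(rows$status == "curated"),
        n_rejected = sum(rows$status == "rejected"),
        novel_chemical_gene = novel_by_kind(rows$interactions, "chemical-gene"),
        novel_chemical_disease = novel_by_kind(rows$interactions, "chemical-disease"),
        novel_gene_disease = novel_by_kind(rows$interactions, "gene-disease"),
        n_interactions = n_int,
        minutes = minutes,
        yield_rate = if (minutes > 0) n_int / minutes else NA_real_)
    }) |> dplyr::bind_rows()
  }
  dplyr::bind_rows(one_ranking(ranked_by_drs, "drs"),
                   one_ranking(ranked_by_pmid, "pmid"))
}

#' Assemble a full evaluation report
#'
#' Convenience wrapper producing the JSON-serializable report the
#' `evaluate`/`report` commands write: MAP under both orderings, per-bin
#' curation metrics and the quartile comparison. When mined mentions and
#' curated actors are supplied, macro-averaged recalls are included.
#'
#' @param scored_docs scored corpus (one target chemical per row).
#' @param curation_log curation records.
#' @param curated_actors,mined_mentions optional tibbles for
#'   [recall_by_category()].
#' @param k number of quantile groups.
#' @return a list of class `evaluation_report`.
#' @export
evaluation_report <- function(scored_docs, curation_log,
                              curated_actors = NULL, mined_mentions = NULL,
                              k = 4L) {
  status <- setNames(curation_log$status, as.character(curation_log$pmid))
  by_drs <- rank_documents(scored_docs, "drs")
  by_pmid <- rank_documents(scored_docs, "pmid")
  relevance <- function(ranked) {
    split_pm <- split(ranked$pmid, ranked$target_chemical)
    lapply(split_pm, function(pm)
      unname(status[as.character(pm)] == "curated" &
               !is.na(status[as.character(pm)])))
  }
  report <- list(
    map = list(drs = map_score(relevance(by_drs)),
               pmid = map_score(relevance(by_pmid))),
    bin_table = bin_metrics(scored_docs, curation_log),
    quartile_table = quartile_comparison(by_drs, by_pmid, curation_log, k))
  if (!is.null(curated_actors) && !is.null(mined_mentions)) {
    report$recall <- as.list(recall_by_category(curated_actors, mined_mentions))
  }
  structure(report, class = "evaluation_report")
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
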