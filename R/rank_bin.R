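#' @name rank_bin
#' @title Ranking, DRS bins and progressive quantile groups
#'
#' @description
#' Scored corpora are ordered either by descending DRS (ties broken by
#' descending PMID, falling back to the recency baseline) or by descending
#' PMID alone — the pre-text-mining baseline in which newly published
#' articles sit at the top of the review list. DRS strata are binned as
#' high (>= 100), medium (21-99) and low (<= 20), and rankings are cut
#' into contiguous progressive quantile groups for evaluation.
NULL

#' Rank scored documents
#'
#' @param scored_docs tibble with at least `pmid` and `drs` columns.
#' @param key `"drs"` (descending DRS, ties by descending PMID) or
#'   `"pmid"` (descending PMID — the recency baseline).
#' @return the input tibble reordered, with an `ordering_key` attribute.
#' @export
rank_documents <- function(scored_docs, key = c("drs", "pmid")) {
  key <- match.arg(key)
  dup <- unique(scored_docs$pmid[duplicated(scored_docs$pmid)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate pmid(s): ", paste(dup, collapse = ", ")))
  }
  ord <- if (key == "drs") order(-scored_docs$drs, -scored_docs$pmid)
         else order(-scored_docs$pmid)
  out <- scored_docs[ord, ]
  attr(out, "ordering_key") <- key
  out
}

#' Assign a DRS bin
#'
#' High when DRS >= 100, medium for 21-99, low for 20 and below (the low
#' bin is extended to 0; in practice every triaged article matches
#' something and scores at least a few points).
#'
#' @param drs non-negative integer score(s).
#' @param thresholds `c(low = ..., high = ...)`: smallest medium and
#'   smallest high score.
#' @return character vector over `"high"`, `"medium"`, `"low"`.
#' @export
assign_bin <- function(drs, thresholds = c(low = 21, high = 100)) {
  if (any(drs < 0)) abort("DRS must be non-negative")
  stopifnot(thresholds[["low"]] < thresholds[["high"]])
  dplyr::case_when(
    drs >= thresholds[["high"]] ~ "high",
    drs >= thresholds[["low"]] ~ "medium",
    TRUE ~ "low")
}

#' Progressive quantile groups along a ranking
#'
#' Cuts `n` ranked documents into `k` contiguous groups whose sizes differ
#' by at most one, larger groups first: n = qk + r gives r groups of q + 1
#' followed by k - r groups of q (so 3,583 documents yield quartiles of
#' 896, 896, 896 and 895).
#'
#' @param ranked ranked tibble (or anything with `nrow`), non-empty.
#' @param k number of groups (default 4, i.e. quartiles).
#' @return integer vector of group indices (1..k) along the ranking.
#' @export
quantile_groups <- function(ranked, k = 4L) {
  n <- nrow(ranked)
  stopifnot(k >= 1L)
  if (n == 0L) abort("ranking is empty")
  if (k > n) abort("more groups than documents")
  q <- n %/% k
  r <- n %% k
  sizes <- c(rep(q + 1L, r), rep(q, k - r))
  rep(seq_len(k), times = sizes)
}
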