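#' @name pipeline
#' @title End-to-end orchestration and command-line entry point
#'
#' @description
#' `triage_run()` ties the modules together behind five commands —
#' `score`, `rank`, `evaluate`, `simulate` and `report` — mirroring the
#' stages of the triage pipeline. A thin `Rscript` wrapper over it ships
#' at `system.file("cli", "litriage", package = "litriage")`. Runs are
#' deterministic: identical inputs, configuration and seed produce
#' identical output files; partial outputs are removed on validation
#' errors.
NULL

.log_stage <- function(stage, ...) {
  message(sprintf("[litriage] stage=%s %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " ")))
}

#' Load a vocabulary directory into a lexicon
#'
#' Expects `chemicals.tsv`, `genes.tsv`, `diseases.tsv`, `actions.tsv`
#' (the layout written by [make_fixture_vocabulary()]).
#'
#' @param dir vocabulary directory.
#' @return a `triage_lexicon`.
#' @export
load_lexicon <- function(dir) {
  files <- c(chemical = "chemicals.tsv", gene = "genes.tsv",
             disease = "diseases.tsv", action = "actions.tsv")
  paths <- file.path(dir, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(paste0("missing vocabulary file(s): ",
                 paste(missing, collapse = ", ")))
  }
  entries <- dplyr::bind_rows(purrr::imap(
    setNames(paths, names(files)),
    function(path, cat_i) load_vocabulary(path, cat_i)))
  build_index(entries)
}

#' Read a rule configuration file
#'
#' JSON with keys `points` (object mapping the 13 rule identifiers to
#' integer point values), `priority_journals` (array of journal names) and
#' optionally `triggers` (path to a trigger lexicon). Missing keys fall
#' back to the defaults.
#'
#' @param path JSON file.
#' @return a `rule_config`.
#' @export
read_rule_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  points <- .default_points
  if (!is.null(raw$points)) {
    unknown <- setdiff(names(raw$points), .rule_ids)
    if (length(unknown) > 0L) {
      abort(paste0("unknown rule id(s) in config: ",
                   paste(unknown, collapse = ", ")))
    }
    points[names(raw$points)] <- as.integer(unlist(raw$points))
  }
  journals <- raw$priority_journals %||% .default_priority_journals
  triggers <- if (!is.null(raw$triggers)) read_trigger_lexicon(raw$triggers)
  default_rule_config(points, journals, triggers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.score_stage <- function(config, rule_config) {
  lexicon <- load_lexicon(config$vocab_dir)
  docs <- parse_records(config$corpus)
  t0 <- Sys.time()
  scored <- score_corpus(docs, lexicon, config$target_chemical, rule_config)
  secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  .log_stage("score", documents = nrow(docs),
             secs_per_abstract = sprintf("%.4f", secs / max(1L, nrow(docs))))
  list(docs = docs, scored = scored, lexicon = lexicon)
}

#' Run a pipeline command
#'
#' @param command one of `"score"` (XML corpus + vocabularies ->
#'   DRS-ranked list TSV + per-document rule-hit JSON), `"rank"` (re-order
#'   an existing ranked list by `key`), `"evaluate"` (ranked list +
#'   curation log -> JSON report), `"simulate"` (seeded synthetic corpus:
#'   XML + curation log + fixture vocabularies), or `"report"` (score +
#'   evaluate end-to-end).
#' @param config named list. Keys by command — `corpus` (XML path),
#'   `vocab_dir`, `target_chemical`, `out_dir` (always), `rule_config`
#'   (optional JSON path), `key` (`"drs"`/`"pmid"`, for rank),
#'   `ranked_list` (for rank/evaluate), `curation_log` (for
#'   evaluate/report), `n_documents` and `seed` (for simulate).
#' @return invisibly, a named list of the files written.
#' @export
triage_run <- function(command = c("score", "rank", "evaluate", "simulate",
                                   "report"),
                       config) {
  command <- match.arg(command)
  stopifnot(is.list(config), !is.null(config$out_dir))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  out <- function(name) {
    path <- file.path(config$out_dir, name)
    written[[length(written) + 1L]] <<- path
    path
  }
  rule_config <- if (!is.null(config$rule_config))
    read_rule_config(config$rule_config) else default_rule_config()

  result <- switch(command,
    score = {
      st <- .score_stage(config, rule_config)
      ranked <- rank_documents(st$scored, "drs")
      write_ranked_list(ranked, out("ranked_list.tsv"))
      hits <- lapply(seq_len(nrow(ranked)), function(i) {
        c(list(pmid = ranked$pmid[[i]], drs = ranked$drs[[i]],
               bin = ranked$bin[[i]]),
          list(hits = ranked$hits[[i]]))
      })
      jsonlite::write_json(hits, out("rule_hits.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "rows")
      list(ranked = ranked)
    },
    rank = {
      ranked <- read_ranked_list(config$ranked_list)
      key <- config$key %||% "drs"
      reranked <- rank_documents(ranked, key)
      write_ranked_list(reranked, out(paste0("ranked_by_", key, ".tsv")))
      .log_stage("rank", documents = nrow(reranked), key = key)
      list(ranked = reranked)
    },
    evaluate = {
      ranked <- read_ranked_list(config$ranked_list)
      log <- read_curation_log(config$curation_log)
      report <- evaluation_report(ranked, log)
      write_evaluation_report(report, out("evaluation.json"))
      .log_stage("evaluate", documents = nrow(ranked),
                 map_drs = sprintf("%.3f", report$map$drs),
                 map_pmid = sprintf("%.3f", report$map$pmid))
      list(report = report)
    },
    simulate = {
      vocab_dir <- file.path(config$out_dir, "vocab")
      paths <- make_fixture_vocabulary(vocab_dir)
      written <- c(written, unname(paths))
      lexicon <- load_lexicon(vocab_dir)
      sc <- synth_config(
        n_documents = config$n_documents %||% 1000L,
        seed = config$seed %||% 1L,
        target_chemical = config$target_chemical %||% "MESH:D002104")
      corpus <- generate_corpus(sc, lexicon)
      write_corpus_xml(corpus$documents, out("corpus.xml"))
      write_curation_log(corpus$curation, out("curation_log.tsv"))
      .log_stage("simulate", documents = nrow(corpus$documents),
                 seed = sc$seed)
      list(corpus = corpus, vocab_dir = vocab_dir)
    },
    report = {
      st <- .score_stage(config, rule_config)
      ranked <- rank_documents(st$scored, "drs")
      write_ranked_list(ranked, out("ranked_list.tsv"))
      log <- read_curation_log(config$curation_log)
      report <- evaluation_report(st$scored, log)
      write_evaluation_report(report, out("evaluation.json"))
      .log_stage("report", documents = nrow(ranked),
                 map_drs = sprintf("%.3f", report$map$drs),
                 map_pmid = sprintf("%.3f", report$map$pmid))
      list(ranked = ranked, report = report)
    })
  ok <- TRUE
  invisible(c(list(files = written), result))
}
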