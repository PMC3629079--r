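#' @name synth
#' @title Seeded synthetic corpora with planted rule triggers
#'
#' @description
#' Real triage corpora and their curation labels cannot be redistributed,
#' so end-to-end behavior is exercised on generated ones. Each synthetic
#' document is assembled from sentence templates with a sampled number of
#' planted features — target-chemical title mentions, positional
#' target-chemical sentences, within-sentence action/gene/chemical
#' co-occurrences, full-text-allusion trigger phrases, MeSH chemical-list
#' entries, priority journals — and its curation outcome is sampled from a
#' logistic model in the planted-feature count, so that curation
#' probability and interaction density rise with the score the pipeline
#' will assign. PMIDs are shuffled independently of relevance, making the
#' recency baseline uninformative by construction. Everything is driven by
#' one integer seed.
NULL

#' Synthetic-corpus configuration
#'
#' Defaults emulate the curation structure of a heavy-metal triage corpus:
#' curated fractions of roughly 85% / 45% / 15% in the high / medium / low
#' DRS bins, mean review times of 16.5 minutes per curated and 1.6 minutes
#' per rejected article, and interaction counts per curated article that
#' grow with planted relevance.
#'
#' @param n_documents number of documents (>= 1).
#' @param seed integer seed driving the single pseudo-random stream.
#' @param target_chemical chemical accession the corpus is "triaged" for.
#' @param relevance_intercept,relevance_slope logistic model mapping the
#'   planted-feature count f to the curation probability
#'   `plogis(intercept + slope * f)`.
#' @param interaction_rate mean extra interactions per planted feature for
#'   curated documents (counts are `1 + rpois(rate * f)`).
#' @param minutes_curated_mean,minutes_curated_sd,minutes_rejected_mean,minutes_rejected_sd
#'   truncated-normal review-time models (minutes) per status.
#' @param full_text_only_fraction fraction of interaction actors drawn
#'   from vocabulary entries absent from the abstract, emulating curation
#'   from the full text (these cap attainable recall).
#' @param priority_journal_rate probability of a priority journal.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_documents = 1000L, seed = 1L,
                         target_chemical = "MESH:D002104",
                         relevance_intercept = -2.2, relevance_slope = 0.55,
                         interaction_rate = 0.6,
                         minutes_curated_mean = 16.5, minutes_curated_sd = 8,
                         minutes_rejected_mean = 1.6, minutes_rejected_sd = 0.8,
                         full_text_only_fraction = 0.15,
                         priority_journal_rate = 0.1) {
  stopifnot(n_documents >= 1L, interaction_rate >= 0,
            full_text_only_fraction >= 0, full_text_only_fraction <= 1,
            priority_journal_rate >= 0, priority_journal_rate <= 1,
            minutes_curated_mean >= 0, minutes_rejected_mean >= 0)
  structure(as.list(environment()), class = "synth_config")
}

.filler_sentences <- c(
  "The authors describe a cohort assessed over several months.",
  "Samples were collected and processed following standard procedures.",
  "Statistical models were fitted to the observed dose groups.",
  "Results were compared against historical controls from the same region.")

.synth_journals <- c("Archives of Experimental Research",
                     "International Journal of Applied Studies",
                     "Annals of Laboratory Medicine Reports")

.pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# sentence-initial capitalization (keeps the sentence splitter's uppercase
# cue after a period; dictionary matching is case-insensitive for terms of
# three or more characters, so planted mentions still resolve)
.cap <- function(s) paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))

#' Generate a synthetic corpus with curation outcomes
#'
#' Deterministic given `config$seed`. Sampling order per document is fixed
#' (feature count, title mentions, trigger, co-occurrence sentences,
#' positional mentions, chemical list, journal, then curation status,
#' minutes and interactions), so outputs are stable across runs.
#'
#' @param config a [synth_config()].
#' @param lexicon a `triage_lexicon` containing the target chemical and at
#'   least one entry per category; planted surfaces are drawn from it, so
#'   every planted mention is recognizable by [find_mentions()].
#' @return list with `documents` (tibble in [parse_records()] layout),
#'   `curation` (tibble in [read_curation_log()] layout) and `planted`
#'   (tibble of per-document planted-feature counts, for diagnostics).
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "synth_config"),
            inherits(lexicon, "triage_lexicon"))
  ent <- lexicon$entries
  for (cat_i in .vocab_categories) {
    if (!any(ent$category == cat_i)) {
      abort(paste0("lexicon has no ", cat_i, " entries"))
    }
  }
  tgt_row <- which(ent$category == "chemical" &
                   ent$accession == config$target_chemical)
  if (length(tgt_row) == 0L) {
    abort(paste0("target chemical ", config$target_chemical,
                 " is not in the lexicon"))
  }
  target_name <- ent$name[[tgt_row[[1]]]]
  genes <- ent[ent$category == "gene", ]
  diseases <- ent[ent$category == "disease", ]
  actions <- ent[ent$category == "action", ]
  other_chems <- ent[ent$category == "chemical" &
                     ent$accession != config$target_chemical, ]

  withr::with_seed(config$seed, {
    n <- config$n_documents
    pmids <- sample(100000L + seq_len(n))  # recency uncorrelated with relevance

    docs <- vector("list", n)
    cur <- vector("list", n)
    planted <- vector("list", n)
    for (i in seq_len(n)) {
      p_rel <- runif(1)
      k <- rbinom(1, 8, p_rel)

      n_title <- rbinom(1, 2, k / 8)
      has_trigger <- runif(1) < (0.05 + 0.65 * k / 8)
      n_cooc <- rbinom(1, 3, k / 8)
      tgt_first <- runif(1) < min(1, k / 4)
      tgt_last <- runif(1) < min(1, k / 5)
      in_chemlist <- runif(1) < (0.2 + 0.6 * k / 8)

      title <- switch(n_title + 1L,
        "A laboratory study of environmental exposures",
        paste0("Effects of ", target_name, " on hepatic function"),
        paste0("Role of ", target_name, ": ", target_name,
               " toxicity revisited"))

      sents <- character()
      if (tgt_first) {
        sents <- c(sents, paste0(target_name,
          " exposure was examined in this study."))
      }
      cooc_genes <- character()
      cooc_diseases <- character()
      if (n_cooc > 0L) {
        for (j in seq_len(n_cooc)) {
          g <- .pick(seq_len(nrow(genes)))
          a <- .pick(seq_len(nrow(actions)))
          with_disease <- runif(1) < 0.4
          s <- paste0(target_name, " altered the ", actions$name[[a]],
                      " of ", genes$name[[g]])
          if (with_disease) {
            d <- .pick(seq_len(nrow(diseases)))
            s <- paste0(s, " in patients with ", diseases$name[[d]])
            cooc_diseases <- c(cooc_diseases, diseases$accession[[d]])
          }
          sents <- c(sents, paste0(s, "."))
          cooc_genes <- c(cooc_genes, genes$accession[[g]])
        }
      }
      sents <- c(sents, .pick(.filler_sentences, 1L + rbinom(1, 2, 0.5)))
      if (has_trigger) {
        sents <- c(sents,
          "A genome-wide microarray screen identified numerous candidates.")
      }
      if (tgt_last) {
        sents <- c(sents, paste0("These findings clarify the contribution of ",
                                 target_name, " to observed outcomes."))
      }
      abstract <- paste(vapply(sents, .cap, character(1)), collapse = " ")

      chem_list <- character()
      if (in_chemlist) chem_list <- target_name
      if (runif(1) < 0.3 && nrow(other_chems) > 0L) {
        chem_list <- c(chem_list,
                       other_chems$name[[.pick(seq_len(nrow(other_chems)))]])
      }
      journal <- if (runif(1) < config$priority_journal_rate)
        .pick(.default_priority_journals) else .pick(.synth_journals)

      f <- n_title + n_cooc + tgt_first + tgt_last + 2L * has_trigger +
        in_chemlist
      curated <- runif(1) < plogis(config$relevance_intercept +
                                   config$relevance_slope * f)
      if (curated) {
        minutes <- max(0.5, rnorm(1, config$minutes_curated_mean,
                                  config$minutes_curated_sd))
        n_int <- 1L + rpois(1, config$interaction_rate * f)
        ints <- vector("list", n_int)
        for (j in seq_len(n_int)) {
          full_text_only <- runif(1) < config$full_text_only_fraction
          gene_acc <- if (full_text_only || length(cooc_genes) == 0L) {
            avail <- setdiff(genes$accession, cooc_genes)
            if (length(avail) == 0L) avail <- genes$accession
            .pick(avail)
          } else .pick(cooc_genes)
          kind <- if (length(cooc_diseases) > 0L && runif(1) < 0.15) {
            if (runif(1) < 0.5) "chemical-disease" else "gene-disease"
          } else "chemical-gene"
          actors <- switch(kind,
            "chemical-gene" = c(paste0("chemical:", config$target_chemical),
                                paste0("gene:", gene_acc)),
            "chemical-disease" = c(paste0("chemical:", config$target_chemical),
                                   paste0("disease:", .pick(cooc_diseases))),
            "gene-disease" = c(paste0("gene:", gene_acc),
                               paste0("disease:", .pick(cooc_diseases))))
          ints[[j]] <- tibble::tibble(
            kind = kind, actors = list(actors),
            source = if (full_text_only) "full_text" else "abstract",
            novel = runif(1) < 0.93,
            assay = if (has_trigger && runif(1) < 0.6) "high_throughput"
                    else .pick(c("in_vivo", "in_vitro")))
        }
        interactions <- dplyr::bind_rows(ints)
        reject_reason <- ""
      } else {
        # rejecting information-dense articles takes longer
        minutes <- max(0.2, rnorm(1, config$minutes_rejected_mean * (1 + 0.1 * f),
                                  config$minutes_rejected_sd))
        interactions <- tibble::tibble(
          kind = character(), actors = list(), source = character(),
          novel = logical(), assay = character())
        reject_reason <- .pick(c("no interaction described",
                                 "species out of scope", "review article"))
      }

      docs[[i]] <- tibble::tibble(
        pmid = pmids[[i]], title = title, abstract = abstract,
        journal_name = journal, chemical_list = list(chem_list),
        pub_year = 2000L + (pmids[[i]] %% 20L))
      cur[[i]] <- tibble::tibble(
        pmid = pmids[[i]], status = if (curated) "curated" else "rejected",
        minutes = round(minutes, 1), reject_reason = reject_reason,
        interactions = list(interactions))
      planted[[i]] <- tibble::tibble(
        pmid = pmids[[i]], features = f, n_title = n_title,
        n_cooc = n_cooc, has_trigger = has_trigger, tgt_first = tgt_first,
        tgt_last = tgt_last, in_chemlist = in_chemlist)
    }
    list(documents = dplyr::bind_rows(docs),
         curation = dplyr::bind_rows(cur),
         planted = dplyr::bind_rows(planted))
  })
}

.fixture_chemicals <- tibble::tribble(
  ~accession, ~name, ~synonyms,
  "MESH:D002104", "cadmium", "cadmium compounds",
  "MESH:D003035", "cobalt", "cobalt compounds",
  "MESH:D003300", "copper", "copper compounds|cupric ion",
  "MESH:D007854", "lead", "lead compounds",
  "MESH:D008345", "manganese", "manganese compounds",
  "MESH:D008628", "mercury", "mercury compounds|methylmercury",
  "MESH:D009532", "nickel", "nickel compounds",
  "MESH:D019256", "cadmium chloride", "",
  "MESH:D014807", "vitamin e", "alpha-tocopherol",
  "MESH:D018698", "glutamate", "glutamic acid",
  "MESH:D010100", "zinc oxide", "")

.fixture_genes <- tibble::tribble(
  ~accession, ~name, ~synonyms,
  "GENE:7124", "TNF", "TNF-alpha|tumor necrosis factor",
  "GENE:4489", "MT1A", "metallothionein 1A",
  "GENE:3162", "HMOX1", "heme oxygenase 1",
  "GENE:836", "CASP3", "caspase 3",
  "GENE:5594", "MAPK1", "",
  "GENE:5595", "MAPK3", "Mapk 3",
  "GENE:847", "CAT", "catalase",
  "GENE:3725", "JUN", "",
  "GENE:4780", "NFE2L2", "NRF2",
  "GENE:3479", "IGF1", "insulin-like growth factor 1")

.fixture_diseases <- tibble::tribble(
  ~accession, ~name, ~synonyms,
  "MESH:D000544", "Alzheimer disease", "Alzheimer dementia",
  "MESH:D007674", "kidney diseases", "nephropathy",
  "MESH:D008113", "liver neoplasms", "hepatic cancer",
  "MESH:D006973", "hypertension", "high blood pressure",
  "MESH:D000740", "anemia", "",
  "MESH:D003875", "dermatitis", "eczema")

.fixture_actions <- tibble::tibble(
  accession = sprintf("ACT:%03d", 1:30),
  name = c("expression", "methylation", "binding", "phosphorylation",
           "activity", "localization", "secretion", "splicing", "stability",
           "folding", "import", "export", "cleavage", "ubiquitination",
           "acetylation", "glycosylation", "oxidation", "reduction",
           "transport", "degradation", "metabolism", "uptake", "abundance",
           "sumoylation", "hydroxylation", "nitrosation", "alkylation",
           "hydrolysis", "mutagenesis", "glutathionylation"),
  synonyms = "")

#' Write the fixture vocabularies
#'
#' Writes small chemical (including the seven heavy metals cadmium,
#' cobalt, copper, lead, manganese, mercury and nickel), gene, disease and
#' action-term vocabularies as tab-separated files that round-trip through
#' [load_vocabulary()]. Deterministic. These stand in for real controlled
#' vocabularies, which are configurable inputs.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
make_fixture_vocabulary <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- list(chemical = .fixture_chemicals, gene = .fixture_genes,
                 disease = .fixture_diseases, action = .fixture_actions)
  paths <- vapply(names(tables), function(cat_i) {
    path <- file.path(dir, paste0(cat_i, "s.tsv"))
    readr::write_tsv(tables[[cat_i]], path, progress = FALSE)
    path
  }, character(1))
  paths
}

#' Build the fixture lexicon directly
#'
#' Convenience for tests and examples: the fixture vocabularies of
#' [make_fixture_vocabulary()] loaded and indexed without touching disk.
#'
#' @return a `triage_lexicon`.
#' @export
fixture_lexicon <- function() {
  dir <- withr::local_tempdir()
  paths <- make_fixture_vocabulary(dir)
  entries <- dplyr::bind_rows(purrr::imap(
    paths, function(path, cat_i) load_vocabulary(path, cat_i)))
  build_index(entries)
}
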