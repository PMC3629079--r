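# Shared fixtures: a small lexicon, document constructors, a corpus XML
# string, and an independent recipe-based document builder whose expected
# DRS is computed by hand-rolled Table-style arithmetic (no shared code
# with the scorer).

test_lexicon <- fixture_lexicon()

make_doc <- function(pmid = 1L, title = "", abstract = "",
                     journal = "Test Journal", chemicals = character(),
                     year = NA_integer_) {
  tibble::tibble(pmid = as.integer(pmid), title = title, abstract = abstract,
                 journal_name = journal, chemical_list = list(chemicals),
                 pub_year = as.integer(year))
}

CADMIUM <- "MESH:D002104"

fixture_corpus_xml <- function() {
  paste0(
    '<?xml version="1.0"?>\n<PubmedArticleSet>\n',
    ' <PubmedArticle><MedlineCitation><PMID>101</PMID>\n',
    '  <Article>\n',
    '   <Journal><Title>Nature</Title>',
    '<JournalIssue><PubDate><Year>2011</Year></PubDate></JournalIssue>',
    '</Journal>\n',
    '   <ArticleTitle>Cadmium  and   stress &amp; injury</ArticleTitle>\n',
    '   <Abstract><AbstractText Label="BACKGROUND">Cadmium is toxic.',
    '</AbstractText><AbstractText Label="RESULTS">It binds MT1A.',
    '</AbstractText></Abstract>\n',
    '  </Article>\n',
    '  <ChemicalList><Chemical><NameOfSubstance>cadmium</NameOfSubstance>',
    '</Chemical><Chemical><NameOfSubstance>metallothionein</NameOfSubstance>',
    '</Chemical></ChemicalList>\n',
    ' </MedlineCitation></PubmedArticle>\n',
    ' <PubmedArticle><MedlineCitation><PMID>102</PMID>\n',
    '  <Article>\n',
    '   <Journal><Title>Archives of Experimental Research</Title></Journal>\n',
    '   <ArticleTitle>A study without an abstract</ArticleTitle>\n',
    '  </Article>\n',
    ' </MedlineCitation></PubmedArticle>\n',
    '</PubmedArticleSet>\n')
}

# ---- recipe-based random documents with an independently computed DRS ----
#
# Sentence types (composition known by construction; all surface words
# outside the planted terms are absent from the fixture vocabularies):
#   A filler            -> no mentions
#   B target chemical   -> 1 chemical (target)
#   C chem+action+gene  -> co-occurrence triple
#   D C plus disease    -> all three pairs
#   E action only
#   F gene only
#   G disease only
#   H trigger phrase    -> full-text allusion, no mentions
.sentence_bank <- list(
  A = list(text = "Many results were reported here.",
           chem = 0L, tgt = 0L, gene = 0L, dis = 0L, act = 0L, trig = FALSE),
  B = list(text = "Cadmium was measured here.",
           chem = 1L, tgt = 1L, gene = 0L, dis = 0L, act = 0L, trig = FALSE),
  C = list(text = "Cadmium altered the binding of TNF.",
           chem = 1L, tgt = 1L, gene = 1L, dis = 0L, act = 1L, trig = FALSE),
  D = list(text = "Cadmium altered the binding of TNF in anemia.",
           chem = 1L, tgt = 1L, gene = 1L, dis = 1L, act = 1L, trig = FALSE),
  E = list(text = "The binding was measured.",
           chem = 0L, tgt = 0L, gene = 0L, dis = 0L, act = 1L, trig = FALSE),
  F = list(text = "TNF was measured.",
           chem = 0L, tgt = 0L, gene = 1L, dis = 0L, act = 0L, trig = FALSE),
  G = list(text = "Anemia was observed.",
           chem = 0L, tgt = 0L, gene = 0L, dis = 1L, act = 0L, trig = FALSE),
  H = list(text = "Microarray profiling was performed.",
           chem = 0L, tgt = 0L, gene = 0L, dis = 0L, act = 0L, trig = TRUE))

# build one random document plus its recipe
random_recipe_doc <- function(pmid) {
  n_title <- sample(0:2, 1)
  title <- switch(n_title + 1L,
                  "A descriptive survey",
                  "Cadmium under scrutiny",
                  "Cadmium versus cadmium in context")
  types <- sample(names(.sentence_bank), sample(1:5, 1), replace = TRUE)
  abstract <- paste(vapply(types, function(t) .sentence_bank[[t]]$text,
                           character(1)), collapse = " ")
  in_chemlist <- runif(1) < 0.5
  priority <- runif(1) < 0.3
  doc <- make_doc(pmid, title, abstract,
                  journal = if (priority) "Nature" else "Test Journal",
                  chemicals = if (in_chemlist) "cadmium" else character())
  list(doc = doc, n_title = n_title, types = types,
       in_chemlist = in_chemlist, priority = priority)
}

# independent scorer: plain arithmetic over the recipe, no package scoring
# code involved
expected_recipe_drs <- function(recipe) {
  bank <- .sentence_bank[recipe$types]
  S <- length(bank)
  chem <- vapply(bank, `[[`, integer(1), "chem")
  tgt <- vapply(bank, `[[`, integer(1), "tgt")
  gene <- vapply(bank, `[[`, integer(1), "gene")
  dis <- vapply(bank, `[[`, integer(1), "dis")
  act <- vapply(bank, `[[`, integer(1), "act")
  trig <- any(vapply(bank, `[[`, logical(1), "trig"))
  g_flag <- sum(gene) > 0 && sum(chem) > 0

  cooc <- 0L
  for (s in seq_len(S)) {
    if (act[s] > 0) {
      cooc <- cooc + (gene[s] > 0 && chem[s] > 0) +
        (gene[s] > 0 && dis[s] > 0) + (chem[s] > 0 && dis[s] > 0)
    }
  }
  # positional rules are independent: in short abstracts one sentence can
  # be first and last (or second and second-to-last) at once
  positional <- tgt[1] * 5 +
    (if (S >= 2) tgt[2] * 3 else 0) +
    (if (S >= 2) tgt[S - 1] * 3 else 0) +
    tgt[S] * 3

  50 * trig +
    10 * recipe$n_title +
    8 * cooc +
    5 * recipe$in_chemlist +
    positional +
    (if (g_flag) 4 else 1) * sum(act) +
    (if (g_flag) 2 else 1) * (sum(chem) + sum(gene) + sum(dis)) +
    1 * recipe$priority
}

# brute-force recognition oracle: enumerate every token-boundary substring,
# keep lexicon hits, then greedily keep the longest non-overlapping hit per
# category, left to right
oracle_mentions <- function(text, lexicon, category) {
  loc <- stringr::str_locate_all(
    text, "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*")[[1]]
  n <- nrow(loc)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      cand <- substr(text, loc[i, 1], loc[j, 2])
      acc <- lexicon_lookup(lexicon, cand, category)
      if (!is.na(acc)) {
        hits[[length(hits) + 1L]] <-
          list(start = loc[i, 1], end = loc[j, 2], acc = acc, surface = cand)
      }
    }
  }
  picked <- list()
  pos <- 0
  repeat {
    avail <- Filter(function(h) h$start > pos, hits)
    if (length(avail) == 0L) break
    starts <- vapply(avail, `[[`, numeric(1), "start")
    first <- avail[starts == min(starts)]
    lens <- vapply(first, function(h) h$end - h$start, numeric(1))
    best <- first[[which.max(lens)]]
    picked[[length(picked) + 1L]] <- best
    pos <- best$end
  }
  picked
}

# all permutations of a (short) vector, duplicates included
combinat_perms <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[[i]], rest)
    }
  }
  out
}

score_one <- function(doc, lexicon = test_lexicon, target = CADMIUM,
                      config = default_rule_config()) {
  sentences <- split_sentences(doc$abstract[[1]])
  mentions <- find_mentions(doc, lexicon, target, sentences)
  score_document(doc, mentions, sentences, target, config)
}
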