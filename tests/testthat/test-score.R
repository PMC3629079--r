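test_that("a document with no scoring features scores zero", {
  doc <- make_doc(1)
  scored <- score_one(doc)
  expect_identical(scored$drs, 0L)
  expect_identical(scored$bin, "low")
  expect_true(all(scored$hits$occurrences == 0L))
})

test_that("a lone full-text trigger phrase scores the flat 50-point boost", {
  doc <- make_doc(1, abstract = "Microarray profiling was performed.")
  scored <- score_one(doc)
  expect_identical(scored$drs, 50L)
  expect_identical(
    scored$hits$total[scored$hits$rule_id == "full_text_boost"], 50L)
})

test_that("title, chemical list and first-sentence mentions stack to 21", {
  # 10 (title) + 5 (chemical list) + 5 (first sentence) + 1 (entity
  # occurrence, no genes present so the 1-point variant applies); three
  # sentences so the first is not simultaneously a last sentence
  doc <- make_doc(1, title = "Cadmium under scrutiny",
                  abstract = paste("Cadmium was measured here.",
                                   "Many results were reported here.",
                                   "The work concluded without incident."),
                  chemicals = "cadmium")
  scored <- score_one(doc)
  expect_identical(scored$drs, 21L)
})

test_that("in a one-sentence abstract the positional rules stack (first and last)", {
  doc <- make_doc(1, abstract = "Cadmium was measured here.")
  scored <- score_one(doc)
  h <- setNames(scored$hits$total, scored$hits$rule_id)
  expect_identical(h[["target_in_first_sentence"]], 5L)
  expect_identical(h[["target_in_last_sentence"]], 3L)
  expect_identical(h[["target_in_second_sentence"]], 0L)
  expect_identical(scored$drs, 9L)  # 5 + 3 + 1 entity occurrence
})

test_that("the gene+chemical condition switches action and entity point values", {
  # without genes: action 1/occurrence, entity 1/occurrence
  doc1 <- make_doc(1, abstract = "Cadmium altered the binding of nothing.")
  s1 <- score_one(doc1)
  h1 <- setNames(s1$hits$total, s1$hits$rule_id)
  expect_identical(h1[["action_without_gene_chem"]], 1L)
  expect_identical(h1[["entity_without_gene_chem"]], 1L)
  expect_identical(h1[["action_with_gene_chem"]], 0L)

  # with a gene present: 4 and 2 points per occurrence
  doc2 <- make_doc(1, abstract = "Cadmium altered the binding of TNF.")
  s2 <- score_one(doc2)
  h2 <- setNames(s2$hits$total, s2$hits$rule_id)
  expect_identical(h2[["action_with_gene_chem"]], 4L)
  expect_identical(h2[["entity_with_gene_chem"]], 4L)  # 2 entities x 2
  expect_identical(h2[["cooccurrence"]], 8L)
})

test_that("co-occurrence counts sentence-pair combinations", {
  mk <- function(abstract) {
    doc <- make_doc(1, abstract = abstract)
    sentences <- split_sentences(abstract)
    mentions <- find_mentions(doc, test_lexicon, CADMIUM, sentences)
    count_cooccurrences(mentions, sentences)
  }
  expect_identical(mk("Cadmium altered the binding of TNF."), 1L)
  expect_identical(mk("The binding was measured."), 0L)
  # action + gene + chemical + disease: all three pairs fire
  expect_identical(mk("Cadmium altered the binding of TNF in anemia."), 3L)
  # two qualifying sentences accumulate
  expect_identical(mk(paste("Cadmium altered the binding of TNF.",
                            "Cadmium altered the expression of CAT.")), 2L)
  # entities without an action term do not fire
  expect_identical(mk("Cadmium affected TNF in anemia."), 0L)
})

test_that("priority-journal matching normalizes case, punctuation and a leading article", {
  cfg <- default_rule_config()
  expect_true(is_priority_journal("The Journal of Biological Chemistry", cfg))
  expect_true(is_priority_journal("journal of biological chemistry", cfg))
  expect_true(is_priority_journal("  NATURE ", cfg))
  expect_true(is_priority_journal("Toxicological sciences.", cfg))
  expect_false(is_priority_journal("PLoS ONE", cfg))
  expect_false(is_priority_journal("Nature Reviews Genetics", cfg))
})

test_that("mentions outside the sentence spans are a consistency error", {
  doc <- make_doc(1, abstract = "Cadmium was measured here.")
  sentences <- split_sentences(doc$abstract[[1]])
  mentions <- find_mentions(doc, test_lexicon, CADMIUM, sentences)
  mentions$sentence_index <- 5L
  expect_error(score_document(doc, mentions, sentences, CADMIUM),
               "sentence_index")
})

test_that("DRS equals the sum of per-rule totals and is non-negative", {
  withr::with_seed(3, {
    for (i in 1:25) {
      recipe <- random_recipe_doc(i)
      scored <- score_one(recipe$doc)
      expect_identical(scored$drs, sum(scored$hits$total))
      expect_gte(scored$drs, 0L)
      expect_identical(scored$hits$total,
                       scored$hits$occurrences * scored$hits$points_per_occurrence)
    }
  })
})

test_that("adding a target-chemical title mention never decreases the DRS", {
  withr::with_seed(4, {
    for (i in 1:15) {
      recipe <- random_recipe_doc(i)
      base <- score_one(recipe$doc)
      bumped <- recipe$doc
      bumped$title <- paste(bumped$title, "with cadmium")
      expect_gte(score_one(bumped)$drs, base$drs)
    }
  })
})

test_that("stripping all mentions leaves only the priority-journal point", {
  doc_plain <- make_doc(1, title = "Nothing here",
                        abstract = "Many results were reported here.")
  expect_identical(score_one(doc_plain)$drs, 0L)
  doc_journal <- make_doc(1, title = "Nothing here",
                          abstract = "Many results were reported here.",
                          journal = "Cell")
  expect_identical(score_one(doc_journal)$drs, 1L)
})

test_that("rule weights are configurable without code change", {
  pts <- litriage:::.default_points
  pts[["target_in_title"]] <- 100L
  cfg <- default_rule_config(points = pts)
  doc <- make_doc(1, title = "Cadmium under scrutiny")
  expect_identical(score_one(doc, config = cfg)$drs, 100L)
})
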