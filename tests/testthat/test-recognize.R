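test_that("sentence splitting honours terminators and the abbreviation guard", {
  s <- split_sentences("Cadmium is toxic. It binds MT1A.")
  expect_identical(nrow(s), 2L)
  expect_identical(s$index, 0:1)

  g <- split_sentences("Metals (e.g. lead) are studied. Yes.")
  expect_identical(nrow(g), 2L)
  expect_identical(substr("Metals (e.g. lead) are studied. Yes.",
                          g$start[[2]] + 1L, g$end[[2]]), "Yes.")

  expect_identical(nrow(split_sentences("")), 0L)
  expect_identical(nrow(split_sentences("No terminator at all")), 1L)
  # no split without following uppercase/digit
  expect_identical(nrow(split_sentences("Levels of 2.5 were seen. Twice.")), 2L)
  expect_identical(nrow(split_sentences("See Fig. 2 for details. Done.")), 2L)
})

test_that("sentence spans are ordered, non-overlapping and inside the text", {
  txt <- paste("First sentence here. Second one follows! Third asks? Yes.",
               "And a fifth.")
  s <- split_sentences(txt)
  expect_identical(nrow(s), 5L)
  expect_true(all(s$start < s$end))
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
  expect_true(all(s$end <= nchar(txt)))
})

test_that("mentions carry resolvable accessions and sentence indices", {
  doc <- make_doc(1, title = "", abstract = "Cadmium induces HMOX1.")
  m <- find_mentions(doc, test_lexicon, CADMIUM)
  expect_identical(nrow(m), 2L)
  expect_setequal(m$category, c("chemical", "gene"))
  expect_identical(unique(m$sentence_index), 0L)
  # validation closure: each surface re-resolves to its accession
  for (i in seq_len(nrow(m))) {
    expect_identical(
      lexicon_lookup(test_lexicon, m$surface[[i]], m$category[[i]]),
      m$accession[[i]])
  }
})

test_that("longest match wins and unresolvable spans are ignored", {
  doc <- make_doc(1, abstract = "Exposure to cadmium chloride and xyzzyol.")
  m <- find_mentions(doc, test_lexicon, CADMIUM)
  expect_identical(m$surface, "cadmium chloride")
  expect_identical(m$accession, "MESH:D019256")
  expect_false(m$is_target_chemical)
})

test_that("chemical-list entries match whole-string only", {
  doc <- make_doc(1, chemicals = c("cadmium", "cadmium and friends"))
  m <- find_mentions(doc, test_lexicon, CADMIUM)
  expect_identical(nrow(m), 1L)
  expect_identical(m$field, "chemical_list")
  expect_true(m$is_target_chemical)
})

test_that("the target chemical must exist in the lexicon", {
  doc <- make_doc(1, abstract = "Cadmium here.")
  expect_error(find_mentions(doc, test_lexicon, "MESH:NOPE"),
               "not in the lexicon")
})

test_that("full-text allusion triggers fire on token-anchored phrases", {
  hit <- detect_full_text_allusion(
    make_doc(1, abstract = "Microarray analysis revealed changes."))
  expect_true(hit$allusion)
  expect_identical(hit$triggers, "microarray")

  expect_false(detect_full_text_allusion(
    make_doc(1, abstract = "Nothing of note was assayed."))$allusion)
  expect_false(detect_full_text_allusion(make_doc(1, abstract = ""))$allusion)
  # token anchoring: no hit inside a larger token
  expect_false(detect_full_text_allusion(
    make_doc(1, abstract = "The pseudomicroarray method differs."))$allusion)
  multi <- detect_full_text_allusion(
    make_doc(1, abstract = "Details are in the supporting information file."))
  expect_true(multi$allusion)
  expect_identical(multi$triggers, "supporting information")
})

test_that("the scanner agrees with the brute-force longest-match oracle", {
  pool <- c("cadmium", "cadmium chloride", "mercury", "TNF", "TNF-alpha",
            "tumor necrosis factor", "binding", "phosphorylation", "anemia",
            "kidney diseases", "catalase", "the", "of", "shows", "induces",
            "unrelated", "words", "heavy", "profile", "NRF2")
  withr::with_seed(11, {
    for (rep in 1:40) {
      n_sent <- sample(1:3, 1)
      sents <- vapply(seq_len(n_sent), function(i) {
        words <- sample(pool, sample(3:8, 1), replace = TRUE)
        paste0("Xq ", paste(words, collapse = " "), ".")
      }, character(1))
      text <- paste(sents, collapse = " ")
      doc <- make_doc(1, abstract = text)
      m <- find_mentions(doc, test_lexicon, CADMIUM)
      m <- m[m$field == "abstract", ]
      for (category in c("chemical", "gene", "disease", "action")) {
        got <- m[m$category == category, ]
        want <- oracle_mentions(text, test_lexicon, category)
        expect_identical(nrow(got), length(want),
                         label = paste(category, text))
        if (length(want) > 0L) {
          expect_identical(got$start + 1L,
                           as.integer(vapply(want, `[[`, numeric(1), "start")))
          expect_identical(got$end,
                           as.integer(vapply(want, `[[`, numeric(1), "end")))
          expect_identical(got$accession,
                           vapply(want, `[[`, character(1), "acc"))
        }
      }
    }
  })
})

test_that("recognition is deterministic", {
  doc <- make_doc(1, title = "Cadmium study",
                  abstract = "Cadmium alters TNF binding. Anemia was seen.")
  m1 <- find_mentions(doc, test_lexicon, CADMIUM)
  m2 <- find_mentions(doc, test_lexicon, CADMIUM)
  expect_identical(m1, m2)
})
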