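# exhaustive AP oracle straight from the definition
oracle_ap <- function(rel) {
  precisions <- numeric()
  seen <- 0
  for (r in seq_along(rel)) {
    if (rel[[r]]) {
      seen <- seen + 1
      precisions <- c(precisions, seen / r)
    }
  }
  mean(precisions)
}

test_that("average precision matches hand-derived values", {
  expect_equal(average_precision(c(TRUE, FALSE, TRUE)), (1 + 2/3) / 2)
  expect_equal(average_precision(c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(average_precision(c(FALSE, FALSE, TRUE)), 1/3)
  expect_error(average_precision(c(FALSE, FALSE)), "no relevant item")
})

test_that("average precision agrees with the exhaustive oracle on all short lists", {
  for (n in 1:6) {
    for (n_rel in 1:n) {
      base <- c(rep(TRUE, n_rel), rep(FALSE, n - n_rel))
      perms <- unique(combinat_perms(base))
      for (p in perms) {
        expect_equal(average_precision(p), oracle_ap(p),
                     label = paste(as.integer(p), collapse = ""))
      }
    }
  }
})

test_that("AP is 1 exactly when relevant items lead, and adjacent fixes increase it", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(2:10, 1)
      rel <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(rel)) rel[[1]] <- TRUE
      ap <- average_precision(rel)
      sorted_first <- all(diff(rel) <= 0)
      expect_identical(ap == 1, sorted_first)
      # swapping a (non-relevant, relevant) adjacent pair strictly helps
      bad <- which(!rel[-n] & rel[-1])
      if (length(bad) > 0L) {
        j <- bad[[1]]
        swapped <- rel
        swapped[c(j, j + 1L)] <- swapped[c(j + 1L, j)]
        expect_gt(average_precision(swapped), ap)
      }
    }
  })
})

test_that("MAP is the unweighted mean over target chemicals", {
  expect_equal(map_score(list(a = c(TRUE, FALSE))), 1)
  expect_equal(map_score(list(a = c(TRUE, FALSE), b = c(FALSE, TRUE))), 0.75)
  perfect <- rep(list(c(TRUE, TRUE, FALSE)), 7)
  names(perfect) <- paste0("chem", 1:7)
  expect_equal(map_score(perfect), 1)
  expect_warning(
    out <- map_score(list(a = c(TRUE, FALSE), b = c(FALSE, FALSE))),
    "skipping")
  expect_equal(out, 1)
  expect_error(map_score(list(a = FALSE)), "no target chemical")
})

test_that("recall counts distinct curated accessions found by any synonym", {
  curated <- tibble::tibble(
    group = "ref1", category = "gene",
    accession = c("GENE:1", "GENE:2", "GENE:3", "GENE:4"))
  mined <- tibble::tibble(
    group = "ref1", category = "gene",
    accession = c("GENE:1", "GENE:2", "GENE:3", "GENE:3"))
  r <- recall_by_category(curated, mined)
  expect_equal(r[["gene"]], 0.75)
  expect_true(is.na(r[["disease"]]))

  # a synonym surface resolving to the curated accession counts as found
  acc <- lexicon_lookup(test_lexicon, "tumor necrosis factor", "gene")
  expect_identical(acc, "GENE:7124")
  r2 <- recall_by_category(
    tibble::tibble(group = "r", category = "gene", accession = "GENE:7124"),
    tibble::tibble(group = "r", category = "gene", accession = acc))
  expect_equal(r2[["gene"]], 1)

  expect_error(recall_by_category(curated[0, ], mined), "no curated actors")
})

test_that("macro-averaged recall is an unweighted mean over groups and monotone in mining", {
  curated <- tibble::tibble(
    group = c("a", "a", "b"), category = "chemical",
    accession = c("M:1", "M:2", "M:9"))
  mined1 <- tibble::tibble(group = "a", category = "chemical", accession = "M:1")
  # group a: 1/2, group b: 0/1 -> macro 0.25
  expect_equal(recall_by_category(curated, mined1)[["chemical"]], 0.25)
  mined2 <- dplyr::bind_rows(
    mined1, tibble::tibble(group = "b", category = "chemical", accession = "M:9"))
  expect_equal(recall_by_category(curated, mined2)[["chemical"]], 0.75)
  expect_gte(recall_by_category(curated, mined2)[["chemical"]],
             recall_by_category(curated, mined1)[["chemical"]])
})

make_log_row <- function(pmid, status, minutes, n_int = 0L, novel = TRUE,
                         kind = "chemical-gene") {
  ints <- if (n_int > 0L) {
    tibble::tibble(kind = rep(kind, n_int),
                   actors = rep(list(c("chemical:M:1", "gene:G:1")), n_int),
                   source = "abstract", novel = novel, assay = "in_vivo")
  } else {
    tibble::tibble(kind = character(), actors = list(), source = character(),
                   novel = logical(), assay = character())
  }
  tibble::tibble(pmid = as.integer(pmid), status = status,
                 minutes = as.numeric(minutes), reject_reason = "",
                 interactions = list(ints))
}

test_that("bin metrics conserve counts and guard empty denominators", {
  scored <- tibble::tibble(pmid = 1:6,
                           drs = c(150L, 120L, 50L, 40L, 10L, 5L))
  scored$bin <- assign_bin(scored$drs)
  log <- dplyr::bind_rows(
    make_log_row(1, "curated", 20, n_int = 10),
    make_log_row(2, "curated", 10, n_int = 4),
    make_log_row(3, "curated", 8, n_int = 2),
    make_log_row(4, "rejected", 2),
    make_log_row(5, "rejected", 1),
    make_log_row(6, "rejected", 3))
  tab <- bin_metrics(scored, log)
  total <- tab[tab$bin == "total", ]
  by_bin <- tab[tab$bin != "total", ]
  expect_identical(sum(by_bin$n_reviewed), total$n_reviewed)
  expect_identical(sum(by_bin$n_curated), total$n_curated)
  expect_identical(sum(by_bin$n_interactions), total$n_interactions)
  expect_equal(sum(by_bin$minutes_reviewed), total$minutes_reviewed)
  # the high bin has no rejected articles: rate is absent, not zero
  high <- tab[tab$bin == "high", ]
  expect_true(is.na(high$rejection_rate))
  expect_equal(high$curation_rate, 15)
  # the low bin has no curated articles
  low <- tab[tab$bin == "low", ]
  expect_true(is.na(low$curation_rate))
  expect_error(bin_metrics(scored, make_log_row(99, "curated", 5, 1)),
               "absent from corpus: 99")
})

test_that("quartile comparison tabulates yield rates and novel interactions by kind", {
  scored <- tibble::tibble(pmid = 1:8,
                           drs = c(200L, 150L, 120L, 90L, 50L, 30L, 10L, 2L))
  log <- dplyr::bind_rows(
    make_log_row(1, "curated", 10, n_int = 12),
    make_log_row(2, "curated", 10, n_int = 6, kind = "chemical-disease"),
    make_log_row(3, "curated", 5, n_int = 2, novel = FALSE),
    make_log_row(4, "rejected", 2),
    make_log_row(5, "curated", 4, n_int = 1, kind = "gene-disease"),
    make_log_row(6, "rejected", 1),
    make_log_row(7, "rejected", 1),
    make_log_row(8, "rejected", 2))
  by_drs <- rank_documents(scored, "drs")
  by_pmid <- rank_documents(scored, "pmid")
  tab <- quartile_comparison(by_drs, by_pmid, log, k = 4L)
  expect_identical(nrow(tab), 8L)
  q1 <- tab[tab$ranking == "drs" & tab$quartile == 1L, ]
  # pmids 1 and 2: 18 interactions in 20 minutes
  expect_equal(q1$yield_rate, 18 / 20)
  expect_identical(q1$novel_chemical_gene, 12L)
  expect_identical(q1$novel_chemical_disease, 6L)
  # counts are conserved within each ranking
  for (r in c("drs", "pmid")) {
    sub <- tab[tab$ranking == r, ]
    expect_identical(sum(sub$n_curated), 4L)
    expect_identical(sum(sub$n_interactions), 21L)
  }
  expect_error(
    quartile_comparison(by_drs, by_pmid[1:4, ], log),
    "permutations")
})
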