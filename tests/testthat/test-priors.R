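assoc_fixture <- function() {
  tibble::tibble(article_id = c("pmid1", "pmid2", "pmid1", "pmid2"),
                 gene_symbol = c("G1", "G1", "G2", "G1"))
}

test_that("gene-specific counting is per distinct article", {
  # pmid2/G1 appears twice: mentions within one article count once
  tab <- count_citations(assoc_fixture(), mode = "gene_specific")
  expect_identical(tab$n_citations[tab$gene_symbol == "G1"], 2L)
  expect_identical(tab$n_citations[tab$gene_symbol == "G2"], 1L)
})

test_that("gene-disease counting joins on article id against the term list", {
  dis <- tibble::tibble(article_id = "pmid1", disease_term = "Breast Cancer")
  tab <- count_citations(assoc_fixture(), mode = "gene_disease",
                         disease_assoc = dis,
                         disease_terms = "breast cancer")
  expect_identical(tab$n_citations[tab$gene_symbol == "G1"], 1L)
  expect_identical(tab$n_citations[tab$gene_symbol == "G2"], 1L)
  expect_identical(attr(tab, "mode"), "gene_disease")
})

test_that("gene-disease mode without a disease file or terms is a\n          configuration error", {
  expect_error(count_citations(assoc_fixture(), mode = "gene_disease"),
               "disease")
})

test_that("empty associations give an empty table and all-ones penalties", {
  tab <- count_citations(assoc_fixture()[0, ])
  expect_identical(nrow(tab), 0L)
  d <- make_toy_data(n = 10, p = 3)
  pv <- penalty_vector(d, tab, epsilon = 0.5)
  expect_equal(pv$gamma, rep(1, 3))
})

test_that("gene-disease counts never exceed gene-specific counts", {
  set.seed(99)
  for (rep in 1:5) {
    ga <- tibble::tibble(
      article_id = paste0("p", sample(20, 60, replace = TRUE)),
      gene_symbol = paste0("G", sample(8, 60, replace = TRUE)))
    da <- tibble::tibble(
      article_id = paste0("p", sample(20, 15, replace = TRUE)),
      disease_term = sample(c("brca", "lung"), 15, replace = TRUE))
    gs <- count_citations(ga)
    gd <- count_citations(ga, "gene_disease", da, "brca")
    merged <- dplyr::left_join(gd, gs, by = "gene_symbol",
                               suffix = c("_d", "_s"))
    expect_true(all(merged$n_citations_d <= merged$n_citations_s))
  }
})

test_that("gamma_factor matches its closed form and domain", {
  expect_equal(gamma_factor(0, 0.5), 1)
  expect_equal(gamma_factor(99, 1), 0.01)
  expect_equal(gamma_factor(3, 0.5), 0.5)
  expect_error(gamma_factor(1, 0), "epsilon")
  expect_error(gamma_factor(1, 1.2), "epsilon")
  expect_error(gamma_factor(-1, 0.5), "non-negative")
})

test_that("gamma is strictly decreasing in citations and flattens as\n          epsilon shrinks", {
  cites <- 0:50
  for (eps in c(0.1, 0.5, 1)) {
    g <- gamma_factor(cites, eps)
    expect_true(all(diff(g) < 0))
    expect_true(all(g > 0 & g <= 1))
  }
  # smaller epsilon => larger gamma at fixed positive cites, -> 1 as eps -> 0
  for (cts in c(1, 10, 1000)) {
    eps_grid <- c(0.5, 0.1, 0.01, 0.001)
    g <- vapply(eps_grid, function(e) gamma_factor(cts, e), 1)
    expect_true(all(diff(g) > 0))
    expect_lt(abs(g[length(g)] - 1), 0.01)
  }
})

test_that("penalty vectors align to gene order with case-folded matching\n          and default gamma 1 for absent genes", {
  d <- make_toy_data(n = 10, p = 2)   # genes G1, G2
  tab <- count_citations(tibble::tibble(article_id = paste0("p", 1:99),
                                        gene_symbol = "G1"))
  pv <- penalty_vector(d, tab, epsilon = 1)
  expect_identical(pv$gene_symbol, c("G1", "G2"))
  expect_equal(pv$gamma, c(0.01, 1))
  # case-insensitive match after whitespace stripping
  tab2 <- count_citations(tibble::tibble(article_id = paste0("p", 1:3),
                                         gene_symbol = " g1 "))
  pv2 <- penalty_vector(d, tab2, epsilon = 0.5)
  expect_equal(pv2$gamma[pv2$gene_symbol == "G1"], 0.5)
  expect_error(penalty_vector(d, tab, epsilon = 0), "epsilon")
})

test_that("explicit overrides allow zero factors, citation-derived never", {
  d <- make_toy_data(n = 10, p = 3)
  pv <- penalty_override(d, c(G2 = 0))
  expect_equal(pv$gamma, c(1, 0, 1))
  expect_identical(attr(pv, "source"), "override")
  expect_true(all(penalty_vector(d, NULL, 1)$gamma > 0))
  expect_error(penalty_override(d, c(G9 = 0)), "G9")
  expect_error(penalty_override(d, c(G1 = 2)), "\\[0, 1\\]")
})

test_that("precomputed count tables load and unparseable rows are skipped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\tn_citations", "TP53\t100", "BRCA1\t"), f)
  expect_warning(tab <- read_citation_counts(f), "skipped")
  expect_identical(tab$n_citations, 100L)
})
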