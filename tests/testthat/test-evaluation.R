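test_that("cv plans partition samples with near-equal folds and are\n          reproducible", {
  p1 <- make_cv_plan(10, 10, R = 1, seed = 3)
  expect_true(all(table(p1$fold) == 1))
  p2 <- make_cv_plan(1212, 10, R = 2, seed = 5,
                     stratify_labels = rep(c(0, 1), c(1013, 199)))
  for (r in 1:2) {
    rep_r <- p2[p2$repetition == r, ]
    expect_identical(sort(rep_r$sample), 1:1212)   # partition: each sample once
    expect_true(all(table(rep_r$fold) %in% c(121, 122)))
  }
  # repetitions differ, same seed reproduces bitwise
  expect_false(identical(p2$fold[p2$repetition == 1],
                         p2$fold[p2$repetition == 2]))
  expect_identical(
    as.data.frame(p2),
    as.data.frame(make_cv_plan(1212, 10, R = 2, seed = 5,
                               stratify_labels = rep(c(0, 1), c(1013, 199)))))
})

test_that("stratified folds balance classes; impossible stratification and\n          K > n are errors", {
  y <- rep(c(0, 1), c(40, 10))
  pl <- make_cv_plan(50, 5, seed = 1, stratify_labels = y)
  per_fold <- tapply(y[order(pl$sample)], pl$fold, sum)
  expect_true(all(per_fold == 2))
  expect_error(make_cv_plan(5, 6), "K")
  expect_error(make_cv_plan(12, 10, stratify_labels = rep(c(0, 1), c(9, 3))),
               "stratification")
})

test_that("rank-based AUC agrees with brute-force pair counting", {
  expect_equal(auc_score(c(0.9, 0.6, 0.4), c(1, 1, 0)), 1)
  expect_equal(auc_score(c(0.2, 0.6, 0.4), c(1, 1, 0)), 0.5)
  expect_equal(auc_score(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # forces ties
    expect_equal(auc_score(s, y), brute_force_auc(s, y))
  }
})

test_that("robustness index matches hand-worked overlap examples", {
  expect_equal(robustness_index_rep(list(c("A", "B"), c("A", "B"))), 1)
  expect_equal(robustness_index_rep(list(c("A"), c("B"), c("C"))), 0)
  expect_equal(robustness_index_rep(list(c("A", "B", "C"),
                                         c("A", "B", "D"),
                                         c("A", "E"))), 0.375)
  expect_equal(robustness_index_rep(list(character(0), character(0))), 0)
  expect_error(robustness_index_rep(list("A")), "two")
})

test_that("aggregate RI is the mean with its spread, and stays in [0,1]", {
  expect_equal(robustness_index(0.5)$ri, 0.5)
  agg <- robustness_index(c(0, 1))
  expect_equal(agg$ri, 0.5)
  v <- robustness_index(rep(0.3, 100))
  expect_equal(v$ri, 0.3)
  expect_equal(v$ri_sd, 0)
  expect_error(robustness_index(numeric(0)), "empty")
  set.seed(31)
  for (i in 1:20) {
    sig <- replicate(4, sample(LETTERS, sample(0:10, 1)), simplify = FALSE)
    ri <- robustness_index_rep(sig)
    expect_gte(ri, 0); expect_lte(ri, 1)
  }
})

fake_eval <- function(aucs, plan) {
  K <- attr(plan, "K"); R <- attr(plan, "R")
  structure(list(model = "fake", plan = plan,
                 results = tibble::tibble(
                   repetition = rep(seq_len(R), each = K),
                   fold = rep(seq_len(K), R), auc = aucs)),
            class = "blasso_eval")
}

test_that("paired Wilcoxon comparison matches the exact signed-rank\n          distribution and is antisymmetric", {
  plan <- make_cv_plan(40, 10, R = 2, seed = 2)
  base <- seq(0.5, 0.69, length.out = 20)
  a <- fake_eval(base + seq(0.01, 0.2, length.out = 20), plan)
  b <- fake_eval(base, plan)
  res <- compare_models(a, b)
  expect_equal(res$p_value, 2 * (1 / 2^20))   # all 20 differences positive
  expect_identical(res$n_pairs, 20L)
  flipped <- compare_models(b, a)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p_value, res$p_value)
  # identical reports: degenerate, p = 1
  same <- compare_models(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # different plans cannot be paired
  other <- fake_eval(base, make_cv_plan(40, 10, R = 2, seed = 99))
  expect_error(compare_models(a, other), "plan")
})

test_that("nested selection reduces to lambda tuning for a single epsilon\n          and returns the largest epsilon when the prior is flat", {
  d <- make_toy_data(n = 60, p = 6, seed = 41)
  one <- nested_cv(d, NULL, epsilon_grid = 0.3, inner_K = 3, n_lambda = 10,
                   seed = 4)
  expect_equal(one$epsilon, 0.3)
  expect_true(one$lambda %in% one$inner_curves$lambda)
  # all-zero citation counts: every epsilon gives gamma = 1; tie-break
  # must return the largest epsilon and one lambda curve only
  tab <- count_citations(tibble::tibble(article_id = character(0),
                                        gene_symbol = character(0)))
  flat <- nested_cv(d, function(e) penalty_vector(d, tab, e),
                    epsilon_grid = c(0.1, 0.5, 1), inner_K = 3,
                    n_lambda = 10, seed = 4)
  expect_equal(flat$epsilon, 1)
  expect_equal(unique(flat$inner_curves$epsilon), 1)
})

test_that("an informative prior on the true genes wins the inner\n          cross-validation against a flattened one", {
  gen <- generate_expression(150, 40, block_size = 8,
                             within_block_corr = 0.3, seed = 51)
  out <- generate_outcome(gen, 5, flip_fraction = 0, seed = 52)
  # heavy citations exactly on the causal genes
  tab <- count_citations(tibble::tibble(
    article_id = paste0("p", 1:500),
    gene_symbol = rep(out$truth$causal_genes, length.out = 500)))
  ncv <- nested_cv(out$data, function(e) penalty_vector(out$data, tab, e),
                   epsilon_grid = c(0.01, 1), inner_K = 3, n_lambda = 15,
                   seed = 6)
  curves <- ncv$inner_curves |>
    dplyr::group_by(epsilon) |>
    dplyr::summarise(best = max(mean_metric))
  expect_gte(curves$best[curves$epsilon == 1],
             curves$best[curves$epsilon == 0.01])
})

test_that("evaluate_model bookkeeping: K x R rows, determinism, and\n          invariance to sample reordering", {
  d <- make_toy_data(n = 60, p = 5, seed = 61)
  plan <- make_cv_plan(60, 2, R = 2, seed = 7, stratify_labels = d$label)
  rep1 <- evaluate_model(d, plan, inner_K = 2, n_lambda = 8)
  expect_identical(nrow(rep1$results), 4L)
  expect_true(all(rep1$results$auc >= 0 & rep1$results$auc <= 1))
  expect_identical(rep1$model, "LASSO")
  rep2 <- evaluate_model(d, plan, inner_K = 2, n_lambda = 8)
  expect_equal(rep1$results, rep2$results)      # same seed, same report
  expect_equal(glance(rep1), glance(rep2))
  # permute rows and remap the plan: results must not change
  set.seed(42)
  perm <- sample(60)
  d_perm <- d[perm, ]
  plan_perm <- plan
  inv <- match(seq_len(60), perm)
  plan_perm$sample <- inv[plan$sample]
  rep3 <- evaluate_model(d_perm, plan_perm, inner_K = 2, n_lambda = 8)
  expect_equal(rep3$results$auc, rep1$results$auc, tolerance = 1e-10)
  expect_equal(rep3$summary$ri, rep1$summary$ri)
})

test_that("with homogeneous priors the full evaluation equals the plain\n          LASSO baseline run", {
  d <- make_toy_data(n = 50, p = 5, seed = 71)
  plan <- make_cv_plan(50, 2, R = 1, seed = 8, stratify_labels = d$label)
  base <- evaluate_model(d, plan, inner_K = 2, n_lambda = 8)
  tab <- count_citations(tibble::tibble(article_id = character(0),
                                        gene_symbol = character(0)))
  flat <- evaluate_model(d, plan, citations = tab, inner_K = 2, n_lambda = 8)
  expect_equal(base$results$auc, flat$results$auc)
  expect_equal(base$results$signature, flat$results$signature)
})
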