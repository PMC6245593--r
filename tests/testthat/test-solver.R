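test_that("at lambda >= lambda_max all penalized coefficients are zero and\n          the intercept is the class-balance log-odds", {
  d <- make_toy_data(n = 60, p = 6, seed = 2)
  lm_ <- lambda_max(d)
  f <- fit_blasso(d, lambda = lm_ * 1.0001)
  expect_identical(length(f$signature), 0L)
  expect_equal(f$intercept, qlogis(mean(d$label)), tolerance = 1e-6)
  # definitional check of the closed form (no unpenalized genes)
  X <- expr_matrix(d)
  ctr <- colMeans(X); scl <- sqrt(colMeans(X^2) - ctr^2)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  manual <- max(abs(crossprod(Xs, d$label - mean(d$label)))) / nrow(X)
  expect_equal(lm_, manual, tolerance = 1e-12)
})

test_that("just below lambda_max at least one penalized coefficient\n          activates; doubling the argmax gamma halves its term", {
  d <- make_toy_data(n = 60, p = 6, seed = 3)
  lm_ <- lambda_max(d)
  f <- fit_blasso(d, lambda = 0.99 * lm_)
  expect_gt(length(f$signature), 0L)
  X <- expr_matrix(d)
  ctr <- colMeans(X); scl <- sqrt(colMeans(X^2) - ctr^2)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  contrib <- abs(drop(crossprod(Xs, d$label - mean(d$label)))) / nrow(X)
  j <- which.max(contrib)
  gam <- rep(1, 6); gam[j] <- 2
  others <- max(contrib[-j])
  expect_equal(lambda_max(d, gam), max(contrib[j] / 2, others),
               tolerance = 1e-12)
})

test_that("with all gammas zero the fit matches the Newton (glm) maximum\n          likelihood oracle", {
  for (seed in c(11, 12)) {
    d <- make_toy_data(n = 50, p = 5, seed = seed)
    f <- fit_blasso(d, penalties = rep(0, 5), lambda = 0, tol = 1e-13)
    oracle <- stats::glm(label ~ ., family = binomial(),
                         data = d[c("label", expr_genes(d))])
    expect_lt(max(abs(c(f$intercept, f$beta) - coef(oracle))), 1e-4)
  }
})

test_that("with gamma identically one the solution equals an independent\n          L1-logistic reference", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  for (i in 1:5) {
    d <- make_toy_data(n = 60, p = 10, seed = 100 + i)
    lam <- 0.3 * lambda_max(d)
    f <- fit_blasso(d, lambda = lam, tol = 1e-13)
    g <- glmnet::glmnet(expr_matrix(d), d$label, family = "binomial",
                        lambda = lam, standardize = TRUE, thresh = 1e-14)
    expect_lt(max(abs(f$beta - as.numeric(g$beta))), 1e-5)
    expect_lt(abs(f$intercept - as.numeric(g$a0)), 1e-5)
  }
})

test_that("weighted solutions obey the rescaling equivalence against an\n          unweighted reference on scaled columns", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  for (i in 1:3) {
    d <- make_toy_data(n = 60, p = 10, seed = 200 + i)
    gam <- runif(10, 0.2, 1)
    lam <- 0.02
    f <- fit_blasso(d, penalties = gam, lambda = lam, standardize = FALSE,
                    tol = 1e-13)
    Xs <- sweep(expr_matrix(d), 2, gam, "/")
    g <- glmnet::glmnet(Xs, d$label, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(f$beta * gam - as.numeric(g$beta))), 1e-5)
  }
})

test_that("every path fit carries a KKT certificate and a non-increasing\n          objective trace, and the first signature is empty", {
  d <- make_toy_data(n = 80, p = 15, seed = 7)
  pa <- blasso_path(d, n_lambda = 25, lambda_min_ratio = 0.01, tol = 1e-9)
  expect_identical(length(pa$fits[[1]]$signature), 0L)
  expect_equal(pa$lambda[1] / pa$lambda[25], 100, tolerance = 1e-9)
  for (f in pa$fits) {
    expect_lt(kkt_residual(f, d), 1e-4)
    expect_true(all(diff(f$objective_trace) <= 1e-12))
  }
  # active sets generally grow along the path
  sizes <- vapply(pa$fits, function(f) length(f$signature), 1L)
  expect_gt(sizes[25], sizes[1])
})

test_that("signature is exactly the nonzero-coefficient set and scale\n          invariance holds under standardization", {
  d <- make_toy_data(n = 70, p = 8, seed = 8)
  f <- fit_blasso(d, lambda = 0.3 * lambda_max(d))
  expect_identical(f$signature, names(f$beta)[f$beta != 0])
  d2 <- dplyr::mutate(d, G1 = G1 * 100)
  f2 <- fit_blasso(d2, lambda = 0.3 * lambda_max(d))
  expect_equal(f2$beta[["G1"]] * 100, f$beta[["G1"]], tolerance = 1e-5)
  expect_equal(predict(f, d), predict(f2, d2), tolerance = 1e-6)
})

test_that("label and penalty preconditions are enforced", {
  d <- make_toy_data(n = 30, p = 4, seed = 9)
  d_bad <- d; d_bad$label <- rep(1L, 30)
  expect_error(fit_blasso(d_bad, lambda = 0.1), "degenerate")
  expect_error(fit_blasso(d, lambda = 0), "lambda")
  expect_error(fit_blasso(d, penalties = rep(1, 3), lambda = 0.1), "gamma")
  expect_error(lambda_max(d, rep(0, 4)), "undefined")
  expect_error(blasso_path(d, n_lambda = 1), "n_lambda")
})

test_that("unpenalized genes survive full shrinkage of the rest", {
  d <- make_toy_data(n = 60, p = 6, seed = 10)
  gam <- c(0, rep(1, 5))
  f <- fit_blasso(d, penalties = gam, lambda = lambda_max(d, gam) * 1.001)
  expect_true("G1" %in% f$signature)
  expect_identical(setdiff(f$signature, "G1"), character(0))
})

test_that("fits serialize to a coefficient table plus JSON header", {
  d <- make_toy_data(n = 40, p = 4, seed = 13)
  f <- fit_blasso(d, lambda = 0.05, epsilon = 0.3)
  stem <- withr::local_tempfile()
  write_blasso_fit(f, stem)
  tab <- readr::read_tsv(paste0(stem, ".tsv"), show_col_types = FALSE)
  expect_identical(tab$gene_symbol, expr_genes(d))
  expect_equal(tab$beta, unname(f$beta))
  hdr <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(hdr$lambda, 0.05)
  expect_equal(hdr$epsilon, 0.3)
})
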