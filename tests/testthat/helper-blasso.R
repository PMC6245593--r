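# Shared fixtures and independent oracles, all built in code.

# small random expression tibble with a logistic outcome
make_toy_data <- function(n = 50, p = 5, seed = 1, beta = NULL, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, sd = sd), n, p)
  colnames(X) <- paste0("G", seq_len(p))
  if (is.null(beta)) beta <- c(1.5, -1, rep(0, p - 2))
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  # guard against degenerate draws in tiny samples
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("S", seq_len(n)), label = as.integer(y)),
    tibble::as_tibble(X))
}

# brute-force AUC over all case-control pairs (ties count one half)
brute_force_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# KKT certificate for a fit, checked on the internally standardized problem
kkt_residual <- function(fit, data) {
  X <- blasso::expr_matrix(data)
  y <- as.numeric(data$label)
  n <- nrow(X)
  if (fit$standardize) {
    ctr <- colMeans(X)
    scl <- sqrt(colMeans(X^2) - ctr^2)
    scl[scl <= 0] <- 1
    Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
    beta_std <- fit$beta * scl
  } else {
    Xs <- X
    beta_std <- fit$beta
  }
  eta <- drop(X %*% fit$beta) + fit$intercept
  g <- drop(crossprod(Xs, plogis(eta) - y)) / n
  lam_g <- fit$lambda * fit$gamma
  viol <- ifelse(beta_std != 0,
                 abs(g + lam_g * sign(beta_std)),
                 pmax(0, abs(g) - lam_g))
  max(viol)
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
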