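#' Generate an expression-like matrix with correlated gene blocks
#'
#' Emulates a log2-scale RNA-Seq expression matrix: genes come in
#' contiguous blocks sharing one latent factor, giving equicorrelated
#' columns within a block (pairwise correlation `within_block_corr`) and
#' independence across blocks -- a stand-in for co-expression structure.
#' Values are Gaussian, shifted/scaled to a typical log2 range and
#' truncated at zero (expression cannot be negative). Deterministic given
#' `seed`.
#'
#' @param n Samples.
#' @param p Genes; the last block may be short if `p` is not a multiple of
#'   `block_size`.
#' @param block_size Genes per correlated block.
#' @param within_block_corr Pairwise correlation within a block, in
#'   \[0, 1).
#' @param seed RNG seed.
#' @param mean_log2,sd_log2 Location and spread of the simulated log2
#'   values before truncation at 0.
#' @return An expression tibble (no `label` column) with genes
#'   `G0001, G0002, ...`.
#' @export
generate_expression <- function(n, p, block_size = 50,
                                within_block_corr = 0.6, seed = 1,
                                mean_log2 = 6, sd_log2 = 2) {
  if (within_block_corr < 0 || within_block_corr >= 1) {
    abort("within_block_corr must lie in [0, 1)")
  }
  rho <- within_block_corr
  with_local_seed(seed, {
    n_block <- ceiling(p / block_size)
    u <- matrix(rnorm(n * n_block), n, n_block)   # one latent per block
    e <- matrix(rnorm(n * p), n, p)
    block_of <- rep(seq_len(n_block), each = block_size)[seq_len(p)]
    z <- sqrt(rho) * u[, block_of, drop = FALSE] + sqrt(1 - rho) * e
    m <- pmax(mean_log2 + sd_log2 * z, 0)
    colnames(m) <- sprintf("G%04d", seq_len(p))
    dplyr::bind_cols(tibble::tibble(sample_id = paste0("S", seq_len(n))),
                     tibble::as_tibble(m))
  })
}

#' Threshold sigmoid outcome
#'
#' Labels a sample 1 when the sigmoid of its linear score is at least one
#' half -- equivalently when `x . beta >= 0`; the boundary score 0 maps to
#' class 1.
#'
#' @param x Numeric vector (one sample) or samples-by-genes matrix.
#' @param beta Coefficient vector aligned to `x`.
#' @return Integer label(s) in \{0, 1\}.
#' @export
sigmoid_label <- function(x, beta) {
  eta <- if (is.matrix(x)) drop(x %*% beta) else sum(x * beta)
  as.integer(plogis(eta) >= 0.5)
}

#' Plant a synthetic outcome with known causal genes
#'
#' Draws `k` causal genes uniformly without replacement, samples their true
#' coefficients from Uniform\[0, 1\], and labels each sample by
#' [sigmoid_label()] applied to the *mean-centered* causal columns (raw
#' log2 expression is non-negative, so without centering the nonnegative
#' coefficients would put essentially every sample in class 1). Exactly
#' `round(flip_fraction * n)` labels are then flipped at uniformly chosen
#' samples to add noise.
#'
#' @param data Expression tibble (no label needed).
#' @param k Number of causal genes (<= number of genes).
#' @param flip_fraction Fraction of labels to flip, in \[0, 0.5).
#' @param seed RNG seed.
#' @param causal_genes,true_beta Optional overrides for the causal set and
#'   its coefficients (both must then have length `k`).
#' @return List with `data` (input plus a `label` column) and `truth`, a
#'   `blasso_truth` object holding `causal_genes`, `true_beta` (named),
#'   `flip_mask` (flipped sample indices), `k`, `flip_fraction`, `seed`.
#' @export
generate_outcome <- function(data, k, flip_fraction = 0.05, seed = 1,
                             causal_genes = NULL, true_beta = NULL) {
  genes <- expr_genes(data)
  n <- nrow(data)
  if (k > length(genes)) abort("k exceeds the number of genes")
  if (flip_fraction < 0 || flip_fraction >= 0.5) {
    abort("flip_fraction must lie in [0, 0.5)")
  }
  with_local_seed(seed, {
    if (is.null(causal_genes)) causal_genes <- sample(genes, k)
    if (length(causal_genes) != k) abort("causal_genes must have length k")
    if (is.null(true_beta)) true_beta <- runif(k)
    if (length(true_beta) != k) abort("true_beta must have length k")
    names(true_beta) <- causal_genes
    Xc <- scale(expr_matrix(data)[, causal_genes, drop = FALSE],
                center = TRUE, scale = FALSE)
    labels <- sigmoid_label(Xc, true_beta)
    n_flip <- round(flip_fraction * n)
    flip_mask <- if (n_flip > 0) sort(sample(n, n_flip)) else integer(0)
    labels[flip_mask] <- 1L - labels[flip_mask]
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = data$sample_id, label = labels),
      data[genes])
    truth <- structure(list(causal_genes = causal_genes,
                            true_beta = true_beta, flip_mask = flip_mask,
                            k = k, flip_fraction = flip_fraction,
                            seed = seed),
                       class = "blasso_truth")
    list(data = out, truth = truth)
  })
}

#' @export
print.blasso_truth <- function(x, ...) {
  cat("<blasso_truth> k =", x$k, "causal genes,",
      length(x$flip_mask), "flipped labels (fraction",
      format(x$flip_fraction, digits = 3), "), seed", x$seed, "\n")
  invisible(x)
}

#' Save ground truth as JSON
#'
#' @param truth A `blasso_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(causal_genes = truth$causal_genes,
                            true_beta = unname(truth$true_beta),
                            flip_mask = truth$flip_mask, k = truth$k,
                            flip_fraction = truth$flip_fraction,
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Benchmark settings for the planted-truth experiment
#'
#' The six canonical designs of the controlled experiment, scalable by
#' `scale`: plain LASSO on the causal genes plus `round(100 * scale)`
#' decoys; plus `round(1900 * scale)` decoys; on all genes; on all genes
#' *except* the causal ones; and two prior-informed variants on all genes
#' with epsilon = 1 -- `E1` draws the causal genes' penalty factors from
#' Uniform(0, 1) (a favourable but imperfect prior) and `E2` sets them to 0
#' (the idealised prior: causal genes unpenalized).
#'
#' @param scale Positive multiplier applied to the decoy counts.
#' @return List of `benchmark_setting` specifications, each with `name`,
#'   `pool` (`truth_plus_decoys`, `all`, `all_minus_truth`), `n_decoys`,
#'   `gamma_rule` (`ones`, `uniform_on_truth`, `zero_on_truth`), `epsilon`.
#' @export
benchmark_settings <- function(scale = 1) {
  mk <- function(name, pool, n_decoys, rule) {
    structure(list(name = name, pool = pool, n_decoys = n_decoys,
                   gamma_rule = rule, epsilon = 1),
              class = "benchmark_setting")
  }
  list(
    mk("LASSO_truth+100d", "truth_plus_decoys", round(100 * scale), "ones"),
    mk("LASSO_truth+1900d", "truth_plus_decoys", round(1900 * scale), "ones"),
    mk("LASSO_all", "all", NA_integer_, "ones"),
    mk("LASSO_minus_truth", "all_minus_truth", NA_integer_, "ones"),
    mk("E1_BLASSO", "all", NA_integer_, "uniform_on_truth"),
    mk("E2_BLASSO", "all", NA_integer_, "zero_on_truth")
  )
}

materialize_setting <- function(setting, data, truth, seed) {
  genes <- expr_genes(data)
  causal <- truth$causal_genes
  non_causal <- setdiff(genes, causal)
  pool <- switch(setting$pool,
    truth_plus_decoys = {
      nd <- min(setting$n_decoys, length(non_causal))
      decoys <- with_local_seed(seed + 7919L, sample(non_causal, nd))
      c(causal, decoys)
    },
    all = genes,
    all_minus_truth = non_causal,
    abort(paste0("unknown gene pool: ", setting$pool)))
  sub <- data[c(intersect(RESERVED_COLS, names(data)), pool)]
  pen <- switch(setting$gamma_rule,
    ones = NULL,
    uniform_on_truth = {
      alpha <- with_local_seed(seed + 104729L,
                               runif(length(causal)))
      names(alpha) <- causal
      penalty_override(sub, alpha)
    },
    zero_on_truth = {
      z <- rep(0, length(causal)); names(z) <- causal
      penalty_override(sub, z)
    },
    abort(paste0("unknown gamma rule: ", setting$gamma_rule)))
  list(data = sub, penalties = pen)
}

#' Run the planted-truth benchmark
#'
#' Evaluates each setting of [benchmark_settings()] by K-fold cross-validation
#' (lambda tuned by inner CV; epsilon fixed at 1 as the settings define the
#' penalties explicitly) and reports, per setting, the mean test AUC, the
#' mean signature size (`n_genes`) and the mean overlap of the signature
#' with the planted causal genes (`n_genes_star`).
#'
#' @param data Labelled expression tibble from [generate_outcome()].
#' @param truth The matching `blasso_truth`.
#' @param settings List of settings (default all six at full scale).
#' @param plan Optional `cv_plan`; by default one repetition of `K`-fold
#'   stratified CV under `seed`.
#' @param K,seed Used to build the default plan (and the decoy/alpha
#'   sub-seeds).
#' @param inner_K,n_lambda,lambda_min_ratio,tol,max_sweeps Passed through
#'   to [evaluate_model()].
#' @param verbose Print per-setting progress.
#' @return Tibble with one row per setting: `model`, `auc`, `auc_sd`,
#'   `n_genes`, `n_genes_star`.
#' @export
run_benchmark <- function(data, truth, settings = benchmark_settings(),
                       plan = NULL, K = 10, seed = 1, inner_K = 5,
                       n_lambda = 30, lambda_min_ratio = 0.01,
                       verbose = FALSE, tol = 1e-7, max_sweeps = 1e5) {
  validate_expression(data)
  if (is.null(plan)) {
    plan <- make_cv_plan(nrow(data), K, R = 1, seed = seed,
                         stratify_labels = data$label)
  }
  purrr::map_dfr(settings, function(s) {
    if (verbose) message("setting ", s$name)
    mat <- materialize_setting(s, data, truth, seed)
    rep <- evaluate_model(mat$data, plan, penalties = mat$penalties,
                          inner_K = inner_K, n_lambda = n_lambda,
                          lambda_min_ratio = lambda_min_ratio,
                          model_label = s$name, tol = tol,
                          max_sweeps = max_sweeps)
    star <- vapply(rep$results$signature,
                   function(sig) length(intersect(sig, truth$causal_genes)),
                   integer(1))
    tibble::tibble(model = s$name, auc = mean(rep$results$auc),
                   auc_sd = sd(rep$results$auc),
                   n_genes = mean(rep$results$n_selected),
                   n_genes_star = mean(star))
  })
}
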