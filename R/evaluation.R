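# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% 2147483647L)
  code
}

#' Repeated K-fold cross-validation plan
#'
#' Builds the fold assignment for `R` repetitions of `K`-fold
#' cross-validation. Within a repetition the folds partition all samples
#' with sizes differing by at most one; repetition `r` draws its folds
#' under sub-seed `seed + r`, so repetitions differ but the whole plan is
#' reproducible. With `stratify_labels` supplied, class proportions are
#' balanced across folds (recommended for imbalanced outcomes).
#'
#' @param n Number of samples.
#' @param K Folds per repetition (2 <= K <= n).
#' @param R Repetitions.
#' @param seed Base seed.
#' @param stratify_labels Optional length-`n` binary label vector to
#'   stratify on; `NULL` for unstratified folds.
#' @return A `cv_plan` tibble with columns `repetition`, `sample`, `fold`
#'   and attributes `n`, `K`, `R`, `seed`, `stratified`.
#' @export
make_cv_plan <- function(n, K, R = 1, seed = 1, stratify_labels = NULL) {
  if (K < 2L || K > n) abort("need 2 <= K <= n")
  stratified <- !is.null(stratify_labels)
  if (stratified) {
    if (length(stratify_labels) != n) abort("stratify_labels must have length n")
    check_binary_labels(stratify_labels)
    if (min(table(factor(stratify_labels, levels = c(0, 1)))) < K) {
      abort("stratification impossible: a class has fewer samples than folds")
    }
  }
  one_rep <- function(r) {
    with_local_seed(seed + r, {
      fold <- integer(n)
      if (stratified) {
        totals <- integer(K)
        for (cl in c(0, 1)) {
          idx <- sample(which(stratify_labels == cl))
          nc <- length(idx)
          base <- nc %/% K
          sizes <- rep(base, K)
          extras <- nc %% K
          if (extras > 0) {
            give <- order(totals, seq_len(K))[seq_len(extras)]
            sizes[give] <- sizes[give] + 1L
          }
          fold[idx] <- rep(seq_len(K), times = sizes)
          totals <- totals + sizes
        }
      } else {
        idx <- sample(n)
        sizes <- rep(n %/% K, K)
        extras <- n %% K
        if (extras > 0) sizes[seq_len(extras)] <- sizes[seq_len(extras)] + 1L
        fold[idx] <- rep(seq_len(K), times = sizes)
      }
      tibble::tibble(repetition = r, sample = seq_len(n), fold = fold)
    })
  }
  plan <- purrr::map_dfr(seq_len(R), one_rep)
  structure(plan, n = n, K = K, R = R, seed = seed, stratified = stratified,
            class = c("cv_plan", class(tibble::tibble())))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' case is scored above a randomly chosen control, ties counted one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels aligned to `scores`; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  check_binary_labels(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) abort("AUC requires both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Signature stability within one cross-validation repetition
#'
#' Ratio of the number of genes common to *all* fold signatures to the
#' mean signature size; 1 means identical signatures in every fold, 0 no
#' gene shared by all. Defined as 0 when every signature is empty.
#'
#' @param signatures List of `K >= 2` character vectors of gene symbols.
#' @return A value in \[0, 1\].
#' @export
robustness_index_rep <- function(signatures) {
  if (length(signatures) < 2L) abort("need at least two fold signatures")
  m <- mean(lengths(signatures))
  if (m == 0) return(0)
  length(Reduce(intersect, signatures)) / m
}

#' Aggregate robustness index over repetitions
#'
#' @param per_rep Numeric vector of per-repetition stability values from
#'   [robustness_index_rep()].
#' @return One-row tibble: `ri` (mean), `ri_sd` (standard deviation across
#'   repetitions, the value reported after "+/-"), `n_rep`.
#' @export
robustness_index <- function(per_rep) {
  if (length(per_rep) == 0L) abort("empty repetition list")
  tibble::tibble(ri = mean(per_rep), ri_sd = sd(per_rep),
                 n_rep = length(per_rep))
}

#' Default grid for the prior exponent
#'
#' Covers (0, 1] with extra resolution at the small end, where
#' citation-count differences are flattened the most.
#'
#' @return Increasing numeric vector in (0, 1].
#' @export
default_epsilon_grid <- function() {
  c(0.01, 0.05, 0.1, 0.11, 0.15, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
}

metric_value <- function(scores, labels, metric) {
  if (metric == "auc") return(auc_score(scores, labels))
  # binomial deviance (negated so larger = better, like AUC)
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Inner-CV hyper-parameter selection and refit
#'
#' For each candidate exponent `epsilon`, builds the penalty vector, lays a
#' geometric lambda grid from [lambda_max()] on the full training split,
#' and scores every (epsilon, lambda) pair by stratified `inner_K`-fold
#' cross-validation; the best pair (ties broken toward larger epsilon, then
#' larger lambda, i.e. more regularization) is refit on the whole split.
#' Penalty builders that do not actually depend on epsilon (e.g. all
#' citation counts zero) are detected and evaluated once, at the largest
#' epsilon.
#'
#' @param data Training split (expression tibble with labels).
#' @param gamma_builder `function(epsilon) -> penalties` (anything
#'   [fit_blasso()] accepts), or `NULL` for the homogeneous prior.
#' @param epsilon_grid Candidate exponents in (0, 1].
#' @param inner_K Inner folds.
#' @param n_lambda,lambda_min_ratio Lambda grid (see [blasso_path()]).
#' @param seed Seed for the inner fold assignment.
#' @param metric `"auc"` (default, matching the reported metric) or
#'   `"deviance"`.
#' @param tol,max_sweeps Solver controls.
#' @return List: `epsilon`, `lambda`, `fit` (the refit `blasso_fit`),
#'   `inner_curves` (tibble of mean inner metric per epsilon and lambda).
#' @export
nested_cv <- function(data, gamma_builder = NULL,
                      epsilon_grid = default_epsilon_grid(), inner_K = 5,
                      n_lambda = 100, lambda_min_ratio = 0.01, seed = 1,
                      metric = c("auc", "deviance"),
                      tol = 1e-7, max_sweeps = 1e5) {
  metric <- match.arg(metric)
  validate_expression(data)
  # canonical row order: inner fold draws must not depend on how the
  # caller happened to order the training rows
  if ("sample_id" %in% names(data)) {
    data <- data[order(data$sample_id), , drop = FALSE]
  }
  epsilon_grid <- sort(epsilon_grid)
  for (e in epsilon_grid) check_epsilon(e)

  # materialize penalties per epsilon; drop epsilons yielding duplicate
  # gamma vectors, keeping the largest (tie-break toward more smoothing)
  pens <- lapply(epsilon_grid, function(e) {
    if (is.null(gamma_builder)) NULL else gamma_builder(e)
  })
  gammas <- lapply(pens, function(p) resolve_gamma(data, p))
  keys <- vapply(gammas, function(g) paste(signif(g, 12), collapse = ","), "")
  keep <- !duplicated(keys, fromLast = TRUE)
  epsilon_grid <- epsilon_grid[keep]
  pens <- pens[keep]

  plan <- make_cv_plan(nrow(data), inner_K, R = 1, seed = seed,
                       stratify_labels = data$label)
  fold_of <- plan$fold[order(plan$sample)]

  best <- NULL
  curves <- list()
  for (i in seq_along(epsilon_grid)) {
    eps <- epsilon_grid[i]
    pen <- pens[[i]]
    grid <- make_lambda_grid(data, pen, n_lambda, lambda_min_ratio)
    fold_scores <- matrix(NA_real_, n_lambda, inner_K)
    for (k in seq_len(inner_K)) {
      va <- fold_of == k
      if (length(unique(data$label[va])) < 2L) {
        warn(paste0("inner fold ", k, " has a single class; skipped"))
        next
      }
      path <- blasso_path(data[!va, , drop = FALSE], pen, lambda = grid,
                          epsilon = eps, tol = tol, max_sweeps = max_sweeps)
      sc <- predict(path, data[va, , drop = FALSE])
      for (l in seq_len(n_lambda)) {
        fold_scores[l, k] <- metric_value(sc[, l], data$label[va], metric)
      }
    }
    curve <- rowMeans(fold_scores, na.rm = TRUE)
    curves[[i]] <- tibble::tibble(epsilon = eps, lambda = grid,
                                  mean_metric = curve)
    li <- which.max(curve)          # first max = largest lambda among ties
    sc <- curve[li]
    if (is.null(best) || sc >= best$score - 1e-12) {
      best <- list(epsilon = eps, lambda = grid[li], pen = pen, score = sc)
    }
  }
  fit <- fit_blasso(data, best$pen, lambda = best$lambda,
                    epsilon = best$epsilon, tol = tol,
                    max_sweeps = max_sweeps)
  list(epsilon = best$epsilon, lambda = best$lambda, fit = fit,
       inner_curves = dplyr::bind_rows(curves))
}

#' Full cross-validated model assessment
#'
#' Runs the complete validation protocol: for every (repetition, fold) of
#' `plan`, hyper-parameters are tuned by [nested_cv()] on the K-1 training
#' folds, the refit model is scored on the held-out fold, and the selected
#' gene signature is recorded. Aggregates the per-fold AUCs (mean and 2.5/
#' 97.5 percentile interval across repetition means -- note that no
#' unbiased variance estimator exists for K-fold CV, so the interval is
#' indicative), the mean signature size, and the robustness index.
#'
#' @param data Expression tibble with labels.
#' @param plan A `cv_plan` covering `nrow(data)` samples.
#' @param citations Optional `citation_table`; its counts define the
#'   penalties via [penalty_vector()] at each candidate epsilon. `NULL`
#'   (and no `penalties`) gives the plain-LASSO baseline, gamma = 1.
#' @param penalties Optional fixed penalties (skips epsilon tuning).
#' @param epsilon_grid,inner_K,n_lambda,lambda_min_ratio,metric,tol,max_sweeps
#'   Passed to [nested_cv()].
#' @param model_label Name stored in the report (defaults to `"LASSO"`,
#'   `"BLASSO"`, or `"override"` as appropriate).
#' @param verbose Print per-repetition progress to stderr.
#' @return A `blasso_eval` object; see [tidy.blasso_eval()] and
#'   [glance.blasso_eval()].
#' @export
evaluate_model <- function(data, plan, citations = NULL, penalties = NULL,
                           epsilon_grid = default_epsilon_grid(),
                           inner_K = 5, n_lambda = 100,
                           lambda_min_ratio = 0.01,
                           metric = c("auc", "deviance"),
                           model_label = NULL, verbose = FALSE,
                           tol = 1e-7, max_sweeps = 1e5) {
  metric <- match.arg(metric)
  validate_expression(data)
  n <- nrow(data)
  if (attr(plan, "n") != n) abort("plan does not cover this dataset")
  K <- attr(plan, "K"); R <- attr(plan, "R"); base_seed <- attr(plan, "seed")

  if (!is.null(penalties)) {
    gamma_builder <- function(eps) penalties
    eps_attr <- attr(penalties, "epsilon")
    epsilon_grid <- if (!is.null(eps_attr) && !is.na(eps_attr)) eps_attr else 1
    if (is.null(model_label)) model_label <- "override"
  } else if (!is.null(citations)) {
    gamma_builder <- function(eps) penalty_vector(data, citations, eps)
    if (is.null(model_label)) model_label <- "BLASSO"
  } else {
    gamma_builder <- NULL
    epsilon_grid <- max(epsilon_grid)
    if (is.null(model_label)) model_label <- "LASSO"
  }

  rows <- list()
  for (r in seq_len(R)) {
    if (verbose) message("repetition ", r, "/", R)
    prep <- plan[plan$repetition == r, ]
    fold_of <- prep$fold[order(prep$sample)]
    for (k in seq_len(K)) {
      te <- fold_of == k
      sub_seed <- (base_seed + r * 1009L + k * 31L) %% 2147483647L
      ncv <- nested_cv(data[!te, , drop = FALSE], gamma_builder,
                       epsilon_grid = epsilon_grid, inner_K = inner_K,
                       n_lambda = n_lambda,
                       lambda_min_ratio = lambda_min_ratio, seed = sub_seed,
                       metric = metric, tol = tol, max_sweeps = max_sweeps)
      sc <- predict(ncv$fit, data[te, , drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        repetition = r, fold = k,
        auc = auc_score(sc, data$label[te]),
        n_selected = length(ncv$fit$signature),
        epsilon = ncv$epsilon, lambda = ncv$lambda,
        signature = list(ncv$fit$signature))
    }
  }
  results <- dplyr::bind_rows(rows)

  ri_per_rep <- results |>
    dplyr::group_by(.data$repetition) |>
    dplyr::summarise(ri = robustness_index_rep(.data$signature),
                     .groups = "drop")
  ri_agg <- robustness_index(ri_per_rep$ri)
  rep_means <- results |>
    dplyr::group_by(.data$repetition) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop")

  structure(list(
    model = model_label,
    results = results,
    ri_per_rep = ri_per_rep,
    summary = list(
      auc_mean = mean(results$auc),
      auc_ci = unname(quantile(rep_means$auc, c(0.025, 0.975), type = 7)),
      n_genes_mean = mean(results$n_selected),
      n_genes_sd = sd(results$n_selected),
      ri = ri_agg$ri, ri_sd = ri_agg$ri_sd),
    plan = plan, metric = metric
  ), class = "blasso_eval")
}

#' @export
print.blasso_eval <- function(x, ...) {
  s <- x$summary
  cat("<blasso_eval> model:", x$model,
      " (K =", attr(x$plan, "K"), ", R =", attr(x$plan, "R"), ")\n",
      " mean AUC:", format(s$auc_mean, digits = 4),
      " [", format(s$auc_ci[1], digits = 3), ",",
      format(s$auc_ci[2], digits = 3), "]\n",
      " mean #genes:", format(s$n_genes_mean, digits = 4),
      "  RI:", format(s$ri, digits = 3), "+/-",
      format(s$ri_sd, digits = 2), "\n")
  invisible(x)
}

#' Per-fold results of a cross-validated assessment
#'
#' @param x A `blasso_eval`.
#' @param ... Unused.
#' @return Tibble with one row per (repetition, fold): `auc`, `n_selected`,
#'   chosen `epsilon` and `lambda`, and the signature as a list column.
#' @export
tidy.blasso_eval <- function(x, ...) x$results

#' One-row summary of a cross-validated assessment
#'
#' @param x A `blasso_eval`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `auc_mean`, percentile interval,
#'   `n_genes_mean`, `ri`, `ri_sd`, `K`, `R`.
#' @export
glance.blasso_eval <- function(x, ...) {
  s <- x$summary
  tibble::tibble(model = x$model, auc_mean = s$auc_mean,
                 auc_lo = s$auc_ci[1], auc_hi = s$auc_ci[2],
                 n_genes_mean = s$n_genes_mean, ri = s$ri, ri_sd = s$ri_sd,
                 K = attr(x$plan, "K"), R = attr(x$plan, "R"))
}

#' Paired comparison of two evaluated models
#'
#' Two-sided Wilcoxon signed-rank test on paired AUC differences. Both
#' reports must have been produced under the *same* `cv_plan`, so that
#' fold-level AUCs are paired. Zero differences are dropped (standard
#' signed-rank procedure); if every difference is zero the comparison is
#' degenerate and reported as p = 1.
#'
#' @param report_a,report_b `blasso_eval` objects sharing a plan.
#' @param unit `"fold"` pairs the R*K fold AUCs; `"repetition"` pairs the R
#'   repetition means.
#' @return One-row tibble: `statistic` (signed, centered signed-rank
#'   statistic `V - m(m+1)/4`; positive when `report_a` wins), `v` (raw
#'   Wilcoxon V), `p_value`, `n_pairs` (after dropping zeros),
#'   `degenerate`.
#' @export
compare_models <- function(report_a, report_b,
                           unit = c("fold", "repetition")) {
  unit <- match.arg(unit)
  pa <- report_a$plan; pb <- report_b$plan
  if (!isTRUE(all.equal(as.data.frame(pa), as.data.frame(pb),
                        check.attributes = FALSE))) {
    abort("reports were not produced under the same cv_plan; pairing invalid")
  }
  if (unit == "fold") {
    m <- dplyr::inner_join(report_a$results[c("repetition", "fold", "auc")],
                           report_b$results[c("repetition", "fold", "auc")],
                           by = c("repetition", "fold"),
                           suffix = c("_a", "_b"))
    d <- m$auc_a - m$auc_b
  } else {
    ma <- tapply(report_a$results$auc, report_a$results$repetition, mean)
    mb <- tapply(report_b$results$auc, report_b$results$repetition, mean)
    d <- as.numeric(ma) - as.numeric(mb)
  }
  d <- d[d != 0]
  if (length(d) == 0L) {
    return(tibble::tibble(statistic = NA_real_, v = NA_real_, p_value = 1,
                          n_pairs = 0L, degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided"))
  m <- length(d)
  v <- unname(wt$statistic)
  tibble::tibble(statistic = v - m * (m + 1) / 4, v = v,
                 p_value = wt$p.value, n_pairs = m, degenerate = FALSE)
}

#' Serialize an evaluation report
#'
#' Writes `<stem>_summary.json` (aggregates, model label, plan seed),
#' `<stem>_folds.tsv` (per-fold AUC table) and `<stem>_signatures.tsv`
#' (gene-by-fold membership matrix).
#'
#' @param report A `blasso_eval`.
#' @param stem Output path stem.
#' @return The written paths, invisibly.
#' @export
write_evaluation <- function(report, stem) {
  s <- report$summary
  js <- paste0(stem, "_summary.json")
  jsonlite::write_json(list(
    model = report$model, auc_mean = s$auc_mean,
    auc_ci = s$auc_ci, n_genes_mean = s$n_genes_mean,
    ri = s$ri, ri_sd = s$ri_sd,
    ci_note = "percentile interval across repetition means; no unbiased variance estimator exists for K-fold CV",
    K = attr(report$plan, "K"), R = attr(report$plan, "R"),
    seed = attr(report$plan, "seed")), js, auto_unbox = TRUE, digits = NA)
  ft <- paste0(stem, "_folds.tsv")
  readr::write_tsv(report$results[c("repetition", "fold", "auc",
                                    "n_selected", "epsilon", "lambda")],
                   ft, progress = FALSE)
  st <- paste0(stem, "_signatures.tsv")
  genes <- sort(unique(unlist(report$results$signature)))
  memb <- purrr::map_dfc(seq_len(nrow(report$results)), function(i) {
    col <- tibble::tibble(x = as.integer(genes %in% report$results$signature[[i]]))
    names(col) <- paste0("r", report$results$repetition[i], "f",
                         report$results$fold[i])
    col
  })
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(gene_symbol = genes), memb),
                   st, progress = FALSE)
  invisible(c(js, ft, st))
}
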