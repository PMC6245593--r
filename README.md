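# blasso

Sparse logistic regression for gene-signature discovery, with per-gene L1
penalty factors derived from literature citation counts.

## Why

In RNA-Seq outcome prediction (samples × genes, p ≫ n), L1-penalized
logistic regression is the standard way to get a predictive model *and* a
small gene signature at once. Its weakness is stability: correlated genes
let many different subsets predict equally well, so the selected signature
changes drastically between cross-validation folds and between studies.
This package biases the selection toward genes with prior literature
evidence by giving each gene its own penalty factor

    gamma_j = (1 / (#cites_j + 1))^epsilon,        epsilon in (0, 1]

inside the objective

    min  (1/n) * sum_i NLL(y_i, b0 + x_i' beta)  +  lambda * sum_j gamma_j * |beta_j|

where `#cites_j` counts distinct articles citing gene *j* — either in all
literature (*gene-specific* mode) or only in articles that also mention a
target disease (*gene-disease* mode). Never-cited genes keep the full
penalty (`gamma = 1`); heavily cited genes are nearly unpenalized;
`epsilon` controls how aggressively citations are trusted and is tuned,
together with `lambda`, by nested cross-validation. With `gamma = 1`
everywhere the model is exactly the plain LASSO baseline.

The package provides:

* a coordinate-descent solver for the weighted-L1 logistic objective with
  warm-started regularization paths and KKT certificates (`fit_blasso()`,
  `blasso_path()`);
* citation-prior construction from PubTator-style association extracts
  (`count_citations()`, `penalty_vector()`);
* the full validation protocol — repeated stratified 10-fold CV with
  nested (lambda, epsilon) tuning, AUC, a signature-stability robustness
  index, paired Wilcoxon model comparison (`evaluate_model()`,
  `compare_models()`);
* a synthetic-data generator with planted causal genes and the six-design
  benchmark that validates the approach under a known ground truth
  (`generate_expression()`, `generate_outcome()`, `run_benchmark()`);
* a command-line entry point (`inst/cli/blasso.R`) with subcommands
  `priors`, `fit`, `evaluate`, `synth`, `compare`.

Everything user-facing takes and returns tibbles and supports
`tidy()` / `glance()` / `autoplot()`.

## Worked example

Synthetic data with 8 planted causal genes among 100, a citation table
that (favourably) cites exactly the causal genes, and a paired comparison
of the citation-weighted model against the plain LASSO baseline:

```r
library(blasso)

gen  <- generate_expression(n = 200, p = 100, block_size = 10,
                            within_block_corr = 0.5, seed = 42)
out  <- generate_outcome(gen, k = 8, flip_fraction = 0.05, seed = 43)
cites <- count_citations(tibble::tibble(
  article_id  = paste0("pmid", 1:400),
  gene_symbol = rep(out$truth$causal_genes, each = 50)))

plan  <- make_cv_plan(200, K = 5, R = 2, seed = 7,
                      stratify_labels = out$data$label)
lasso <- evaluate_model(out$data, plan, inner_K = 3, n_lambda = 20)
bl    <- evaluate_model(out$data, plan, citations = cites, inner_K = 3,
                        n_lambda = 20, epsilon_grid = c(0.1, 0.5, 1))
bl
#> <blasso_eval> model: BLASSO  (K = 5 , R = 2 )
#>   mean AUC: 0.9315  [ 0.931 , 0.931 ]
#>   mean #genes: 8   RI: 1 +/- 0
glance(lasso)
#> # A tibble: 1 x 9
#>   model auc_mean auc_lo auc_hi n_genes_mean    ri  ri_sd     K     R
#>   <chr>    <dbl>  <dbl>  <dbl>        <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1 LASSO    0.876  0.875  0.876         25.3 0.322 0.0593     5     2
compare_models(bl, lasso)
#> # A tibble: 1 x 5
#>   statistic     v p_value n_pairs degenerate
#>       <dbl> <dbl>   <dbl>   <int> <lgl>
#> 1      22.5    50  0.0195      10 FALSE
```

Reading the numbers: the citation-weighted model reaches a mean test AUC
of 0.93 versus 0.88 for the baseline, selects signatures of exactly the 8
causal genes in every fold (mean signature size 8, robustness index 1,
i.e. identical signatures across folds, versus 0.32 for the baseline's
25-gene signatures), and the paired Wilcoxon test on the 10 fold AUCs
gives p = 0.02. The positive `statistic` means the first argument wins.

The same pipeline from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "blasso.R", package = "blasso"))')
Rscript $CLI priors   --gene-assoc gene2pubmed.tsv --out-prefix out/pri
Rscript $CLI evaluate --expression expr.tsv --counts out/pri_counts.tsv \
                      --K 10 --R 100 --seed 1 --out-prefix out/blasso
Rscript $CLI evaluate --expression expr.tsv --baseline \
                      --K 10 --R 100 --seed 1 --out-prefix out/lasso
Rscript $CLI compare  --folds-a out/blasso_folds.tsv \
                      --folds-b out/lasso_folds.tsv --out-prefix out/cmp
```

The two `evaluate` runs share `--seed`, so their fold plans are identical
and the comparison is validly paired.

## Applying it to real cohort data

The package ships no cohort data and no literature snapshot. To run the
protocol on e.g. a TCGA expression matrix: export the matrix as TSV
(samples in rows, a binary `label` column, gene columns named by HUGO
symbols), preprocess with `preprocess_expression()` (drops all-zero genes,
applies `log2(v + 1)`), obtain gene–PMID (and, for the gene-disease mode,
disease–PMID) extract files from a PubTator snapshot, and run the four
commands above (add `--mode gene_disease --disease-terms "breast cancer"`
to `priors` for the disease-restricted prior). With 100 repetitions of
10-fold CV at p ~ 20000 expect hours of runtime on one CPU.

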