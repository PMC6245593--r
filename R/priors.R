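#' Count literature citations per gene
#'
#' Builds a citation table from static literature-association extracts
#' (PubTator-style). Counting is per *distinct article*: a gene mentioned
#' several times in one article contributes one citation. Two modes are
#' supported:
#'
#' * `gene_specific` -- count all distinct articles mentioning the gene,
#'   regardless of context;
#' * `gene_disease` -- count only articles that also mention one of the
#'   supplied disease terms, joined by article id.
#'
#' @param gene_assoc A data frame with columns `article_id` and
#'   `gene_symbol` (extra columns ignored), or the path of a TSV in that
#'   layout. A header row naming the columns is recognised; otherwise the
#'   first two columns are used positionally (PubTator gene2pubtator
#'   extracts: article_id, gene_symbol, mentions, resource).
#' @param mode `"gene_specific"` or `"gene_disease"`.
#' @param disease_assoc For `gene_disease` mode: a data frame or TSV path
#'   with columns `article_id` and `disease_term`.
#' @param disease_terms For `gene_disease` mode: non-empty character vector
#'   of disease terms; matching is exact after case-folding and whitespace
#'   trimming (no ontology expansion).
#' @return A `citation_table`: a tibble with columns `gene_symbol` and
#'   `n_citations`, carrying attributes `mode` and `disease_context`.
#'   Genes never mentioned are absent (their count is 0 downstream).
#' @export
count_citations <- function(gene_assoc,
                            mode = c("gene_specific", "gene_disease"),
                            disease_assoc = NULL, disease_terms = NULL) {
  mode <- match.arg(mode)
  ga <- read_assoc(gene_assoc, c("article_id", "gene_symbol"))
  if (mode == "gene_disease") {
    if (is.null(disease_assoc) || length(disease_terms) == 0L) {
      abort("gene_disease mode requires `disease_assoc` and `disease_terms`")
    }
    da <- read_assoc(disease_assoc, c("article_id", "disease_term"))
    terms <- fold_symbol(disease_terms)
    hits <- unique(da$article_id[fold_symbol(da$disease_term) %in% terms])
    ga <- dplyr::filter(ga, .data$article_id %in% hits)
  }
  out <- ga |>
    dplyr::distinct(.data$article_id, .data$gene_symbol) |>
    dplyr::count(.data$gene_symbol, name = "n_citations") |>
    dplyr::arrange(dplyr::desc(.data$n_citations), .data$gene_symbol)
  new_citation_table(out, mode = mode,
                     disease_context = paste(disease_terms, collapse = "; "))
}

new_citation_table <- function(tbl, mode, disease_context = "") {
  stopifnot(all(c("gene_symbol", "n_citations") %in% names(tbl)))
  if (any(tbl$n_citations < 0) || any(tbl$n_citations != round(tbl$n_citations))) {
    abort("citation counts must be non-negative integers")
  }
  tbl$n_citations <- as.integer(tbl$n_citations)
  structure(tibble::as_tibble(tbl),
            mode = mode, disease_context = disease_context,
            class = c("citation_table", class(tibble::tibble())))
}

#' Read a precomputed gene-to-citation-count table
#'
#' @param path Two-column TSV (gene_symbol, count), with or without header.
#' @param mode,disease_context Provenance tags stored on the result.
#' @return A `citation_table` tibble.
#' @export
read_citation_counts <- function(path, mode = "gene_specific",
                                 disease_context = "") {
  tbl <- read_assoc(path, c("gene_symbol", "n_citations"))
  tbl$n_citations <- suppressWarnings(as.numeric(tbl$n_citations))
  bad <- is.na(tbl$n_citations) | is.na(tbl$gene_symbol)
  if (any(bad)) {
    warn(paste0(sum(bad), " unparseable row(s) skipped"))
    tbl <- tbl[!bad, ]
  }
  new_citation_table(tbl, mode = mode, disease_context = disease_context)
}

# Read an association file or pass through a data frame; first two columns
# used positionally unless a header names `want`. Unparseable (NA/empty)
# rows are skipped with a warning.
read_assoc <- function(x, want) {
  if (is.data.frame(x)) {
    if (!all(want %in% names(x))) {
      if (ncol(x) < 2L) abort("association data needs at least two columns")
      names(x)[1:2] <- want
    }
    tbl <- tibble::as_tibble(x)[want]
  } else {
    if (!file.exists(x)) abort(paste0("file not found: ", x))
    raw <- readr::read_tsv(x, col_names = FALSE, progress = FALSE,
                           show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    if (nrow(raw) > 0L &&
        all(fold_symbol(want) %in% fold_symbol(unlist(raw[1, ])))) {
      names(raw) <- fold_symbol(unlist(raw[1, ]))
      raw <- raw[-1, ]
      tbl <- raw[want]
    } else {
      if (ncol(raw) < 2L) abort("association file needs at least two columns")
      tbl <- raw[, 1:2]
      names(tbl) <- want
    }
  }
  tbl[[1]] <- as.character(tbl[[1]])
  tbl[[2]] <- as.character(tbl[[2]])
  bad <- is.na(tbl[[1]]) | is.na(tbl[[2]]) | tbl[[1]] == "" | tbl[[2]] == ""
  if (any(bad)) {
    warn(paste0(sum(bad), " unparseable row(s) skipped"))
    tbl <- tbl[!bad, ]
  }
  tbl
}

fold_symbol <- function(x) tolower(trimws(as.character(x)))

#' Citation-derived penalty factor
#'
#' Maps a citation count to the per-gene L1 penalty factor
#' `gamma = (1 / (cites + 1))^epsilon`. Never-cited genes get `gamma = 1`
#' (fully penalized); heavily cited genes approach 0 (nearly unpenalized).
#' The exponent `epsilon` in (0, 1] controls the smoothness of the
#' down-weighting: small values flatten differences between genes.
#'
#' @param cites Non-negative citation count(s).
#' @param epsilon Exponent in (0, 1].
#' @return Penalty factor(s) in (0, 1].
#' @export
#' @examples
#' gamma_factor(0, 0.5)   # 1
#' gamma_factor(99, 1)    # 0.01
#' gamma_factor(3, 0.5)   # 0.5
gamma_factor <- function(cites, epsilon) {
  if (any(is.na(cites)) || any(cites < 0)) {
    abort("citation counts must be non-negative")
  }
  check_epsilon(epsilon)
  (1 / (cites + 1))^epsilon
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon > 1) {
    abort("epsilon must be a single value in (0, 1]")
  }
  invisible(epsilon)
}

#' Build a penalty vector aligned to an expression dataset
#'
#' Looks up each gene of `data` in a citation table (case-insensitively,
#' after whitespace trimming) and converts counts to penalty factors via
#' [gamma_factor()]. Genes absent from the table count 0 citations and get
#' `gamma = 1`; absence is a defined case, not an error.
#'
#' @inheritParams expr_genes
#' @param citations A `citation_table` from [count_citations()] or
#'   [read_citation_counts()], or `NULL` for the homogeneous prior
#'   (`gamma = 1` everywhere, the plain-LASSO baseline).
#' @param epsilon Exponent in (0, 1] passed to [gamma_factor()].
#' @return A `penalty_vector`: a tibble with columns `gene_symbol`,
#'   `n_citations`, `gamma` in the gene order of `data`, with attributes
#'   `epsilon` and `source`.
#' @export
penalty_vector <- function(data, citations = NULL, epsilon = 1) {
  check_epsilon(epsilon)
  genes <- expr_genes(data)
  if (is.null(citations)) {
    counts <- integer(length(genes))
    src <- "uniform"
  } else {
    key <- fold_symbol(citations$gene_symbol)
    idx <- match(fold_symbol(genes), key)
    counts <- ifelse(is.na(idx), 0L, citations$n_citations[idx])
    src <- paste0("citations/", attr(citations, "mode"))
  }
  out <- tibble::tibble(gene_symbol = genes,
                        n_citations = as.integer(counts),
                        gamma = gamma_factor(counts, epsilon))
  structure(out, epsilon = epsilon, source = src,
            class = c("penalty_vector", class(tibble::tibble())))
}

#' Explicit per-gene penalty factors
#'
#' Manual override constructor: assigns given penalty factors to named
#' genes and a default (1) elsewhere. Unlike citation-derived factors,
#' explicit factors may be exactly 0, which removes those genes from the
#' penalty entirely (they are always retained by the model) -- the
#' idealised-prior experiment uses this.
#'
#' @inheritParams expr_genes
#' @param values Named numeric vector mapping gene symbols to factors in
#'   \[0, 1\].
#' @param default Factor for unnamed genes (default 1).
#' @return A `penalty_vector` tibble with `source = "override"`.
#' @export
penalty_override <- function(data, values, default = 1) {
  genes <- expr_genes(data)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    abort("`values` must be a fully named numeric vector")
  }
  if (any(values < 0) || any(values > 1) || default < 0 || default > 1) {
    abort("penalty factors must lie in [0, 1]")
  }
  missing <- setdiff(names(values), genes)
  if (length(missing) > 0L) {
    abort(paste0("genes not in data: ", paste(head(missing, 5), collapse = ", ")))
  }
  gam <- rep(default, length(genes))
  names(gam) <- genes
  gam[names(values)] <- values
  out <- tibble::tibble(gene_symbol = genes, n_citations = NA_integer_,
                        gamma = unname(gam))
  structure(out, epsilon = NA_real_, source = "override",
            class = c("penalty_vector", class(tibble::tibble())))
}

# Align any accepted penalty representation to the gene order of `data`.
resolve_gamma <- function(data, penalties) {
  genes <- expr_genes(data)
  p <- length(genes)
  if (is.null(penalties)) return(rep(1, p))
  if (inherits(penalties, "penalty_vector") ||
      (is.data.frame(penalties) && all(c("gene_symbol", "gamma") %in% names(penalties)))) {
    idx <- match(genes, penalties$gene_symbol)
    if (anyNA(idx)) {
      abort("penalty vector does not cover all genes in the data")
    }
    g <- penalties$gamma[idx]
  } else if (is.numeric(penalties)) {
    if (!is.null(names(penalties))) {
      idx <- match(genes, names(penalties))
      if (anyNA(idx)) abort("named gamma vector does not cover all genes")
      g <- unname(penalties[idx])
    } else {
      if (length(penalties) != p) {
        abort(paste0("gamma length ", length(penalties),
                     " != number of genes ", p))
      }
      g <- penalties
    }
  } else {
    abort("unsupported penalty specification")
  }
  if (any(is.na(g)) || any(g < 0)) abort("gamma factors must be >= 0")
  g
}
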