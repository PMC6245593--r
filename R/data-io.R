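#' Expression data as a tibble
#'
#' Throughout the package an expression dataset is an ordinary tibble with
#' one row per sample: a character `sample_id` column, an optional integer
#' `label` column with values in \{0, 1\} (0 = control/alive, 1 = case/dead),
#' and one numeric column per gene, named by its symbol (HUGO symbols for
#' real data). Gene order is meaningful and preserved by every operation.
#'
#' @name expression-data
#' @keywords internal
NULL

RESERVED_COLS <- c("sample_id", "label")

#' Gene columns of an expression tibble
#'
#' @param data An expression tibble (see [read_expression()]).
#' @return Character vector of gene symbols, in column order.
#' @export
expr_genes <- function(data) {
  setdiff(names(data), RESERVED_COLS)
}

#' Expression values as a numeric matrix
#'
#' @inheritParams expr_genes
#' @return A samples-by-genes numeric matrix with gene symbols as column
#'   names and sample ids as row names.
#' @export
expr_matrix <- function(data) {
  genes <- expr_genes(data)
  m <- as.matrix(data[genes])
  storage.mode(m) <- "double"
  rownames(m) <- if ("sample_id" %in% names(data)) data$sample_id else NULL
  m
}

validate_expression <- function(data, require_label = TRUE) {
  genes <- expr_genes(data)
  if (length(genes) == 0L) abort("expression data contains no gene columns")
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene symbols: ", paste(dup, collapse = ", ")))
  }
  if (require_label) {
    if (!"label" %in% names(data)) abort("no `label` column present")
    check_binary_labels(data$label)
  }
  invisible(data)
}

check_binary_labels <- function(labels) {
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort("labels must take values in {0, 1} with no missing entries")
  }
  invisible(labels)
}

#' Read an expression matrix with binary outcome labels
#'
#' Reads a delimited text file into the package's expression-tibble layout.
#' Files may store samples in rows (one column per gene, plus the label
#' column) or genes in rows (first column gene symbol, one column per
#' sample, labels in a row whose symbol equals `label_column`). The
#' orientation is always explicit -- there is no auto-detection.
#'
#' @param path Path to a delimited text file with a header row.
#' @param label_column Name of the label column (samples-in-rows) or label
#'   row (genes-in-rows). Default `"label"`.
#' @param orientation `"samples"` if samples are rows, `"genes"` if genes
#'   are rows.
#' @param delim Field delimiter; defaults to tab, or comma when `path` ends
#'   in `.csv`.
#' @param id_column Optional name of a sample-id column (samples-in-rows
#'   only). When absent, ids `S1, S2, ...` are synthesized.
#' @return An expression tibble with columns `sample_id`, `label`, then one
#'   numeric column per gene in input order.
#' @export
read_expression <- function(path, label_column = "label",
                            orientation = c("samples", "genes"),
                            delim = NULL, id_column = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"

  # duplicate symbols must be caught before readr repairs the header
  hdr <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (orientation == "samples" && anyDuplicated(hdr)) {
    abort(paste0("duplicate gene symbols: ",
                 paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }

  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    abort(paste0("parse error at line ", prob$row[1], ": ", prob$expected[1],
                 " expected, got ", prob$actual[1]))
  }

  if (orientation == "genes") {
    sym_col <- names(raw)[1]
    symbols <- as.character(raw[[sym_col]])
    sample_ids <- names(raw)[-1]
    values <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(values) <- symbols
    is_label <- symbols == label_column
    if (sum(is_label) != 1L) {
      abort(paste0("label row `", label_column, "` missing or duplicated"))
    }
    labels <- as.numeric(values[, which(is_label)])
    values <- values[, !is_label, drop = FALSE]
    out <- tibble::tibble(sample_id = sample_ids,
                          label = as.integer(labels))
    out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  } else {
    if (!label_column %in% names(raw)) {
      abort(paste0("label column `", label_column, "` not found"))
    }
    labels <- raw[[label_column]]
    if (is.null(id_column) && "sample_id" %in% names(raw)) {
      id_column <- "sample_id"
    }
    ids <- if (!is.null(id_column)) {
      if (!id_column %in% names(raw)) {
        abort(paste0("id column `", id_column, "` not found"))
      }
      as.character(raw[[id_column]])
    } else {
      paste0("S", seq_len(nrow(raw)))
    }
    gene_cols <- setdiff(names(raw), c(label_column, id_column))
    out <- tibble::tibble(sample_id = ids, label = as.integer(labels))
    out <- dplyr::bind_cols(out, raw[gene_cols])
  }

  check_binary_labels(out$label)
  validate_expression(out)
  genes <- expr_genes(out)
  for (g in genes) {
    if (!is.numeric(out[[g]])) {
      abort(paste0("gene column `", g, "` is not numeric"))
    }
  }
  out
}

#' Write an expression tibble to delimited text
#'
#' Inverse of [read_expression()] for the samples-in-rows orientation;
#' round trips are lossless up to numeric formatting.
#'
#' @inheritParams expr_genes
#' @param path Output path.
#' @param delim Field delimiter; defaults to tab, or comma for `.csv` paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, delim = NULL) {
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(data, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Preprocess an expression matrix
#'
#' Applies the two standard preprocessing steps for raw (non-negative)
#' expression values: genes with zero expression in every sample are
#' removed (they carry no predictive signal), and remaining values are
#' transformed to `log2(v + 1)`. The pseudocount keeps individual zero
#' entries of retained genes finite; a gene is only dropped when it is zero
#' in *all* samples.
#'
#' @inheritParams expr_genes
#' @param already_log2 Set `TRUE` when the input is already on the log2
#'   scale; the transform is then skipped (only the all-zero filter runs),
#'   making the operation idempotent.
#' @return The filtered (and possibly transformed) expression tibble, with
#'   attribute `n_dropped` giving the number of genes removed.
#' @export
preprocess_expression <- function(data, already_log2 = FALSE) {
  validate_expression(data, require_label = FALSE)
  genes <- expr_genes(data)
  m <- expr_matrix(data)
  if (!already_log2 && any(m < 0)) {
    abort("negative raw expression values cannot be log2-transformed")
  }
  all_zero <- colSums(m != 0) == 0L
  dropped <- genes[all_zero]
  keep <- genes[!all_zero]
  out <- data[c(intersect(RESERVED_COLS, names(data)), keep)]
  if (!already_log2) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(keep),
                                            ~ log2(.x + 1)))
  }
  if (length(dropped) > 0L) {
    message(length(dropped), " all-zero gene(s) removed")
  }
  attr(out, "n_dropped") <- length(dropped)
  out
}
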