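# Readers and writers for the plain-text interchange formats: expression
# matrices (TSV/CSV/GCT), entropy curves, and truth label tables. Edge
# lists, trees and partitions live next to their classes.

#' Read an expression matrix from TSV, CSV or GCT
#'
#' TSV/CSV: gene ids in the first column, sample ids in the header row.
#' GCT: the two-line preamble (`#1.2`, then dimensions) followed by
#' Name/Description columns is recognised automatically. Missing values
#' are rejected unless `impute = TRUE`, which fills them with the
#' gene-wise mean.
#'
#' @param path input file.
#' @param sep field separator; guessed from the extension when NULL
#'   (".csv" = comma, otherwise tab).
#' @param impute gene-wise mean imputation of missing values.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path, sep = NULL, impute = FALSE) {
  first <- readLines(path, n = 1)
  is_gct <- startsWith(first, "#1.2")
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is_gct) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                            check.names = FALSE, quote = "")
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE, quote = "")
    genes <- rownames(df)
    vals <- as.matrix(df)
  }
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (!impute) {
      bad <- which(rowSums(is.na(vals)) > 0)[1]
      stop("missing values (first offending gene row: ", genes[bad],
           "); re-run with impute = TRUE for gene-wise mean imputation")
    }
    for (r in which(rowSums(is.na(vals)) > 0)) {
      v <- vals[r, ]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      vals[r, ] <- v
    }
  }
  expression_matrix(vals, genes, colnames(vals))
}

#' @rdname read_expression_matrix
#' @param expr an `expression_matrix`.
#' @export
write_expression_matrix <- function(expr, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an entropy curve table
#'
#' Tab-separated columns `k`, `H`, `stable` (0/1).
#'
#' @param curve an `entropy_curve`.
#' @param path file path.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- data.frame(k = curve$k, H = curve$H, stable = as.integer(curve$stable))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_tsv
#' @export
read_curve_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  curve <- data.frame(k = as.integer(df$k), H = df$H,
                      stable = df$stable == 1)
  class(curve) <- c("entropy_curve", class(curve))
  curve
}

#' Read ground-truth sample labels
#'
#' Two-column table `sample_id TAB label` (header optional).
#'
#' @param path file path.
#' @return named character vector of labels keyed by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) != 2) stop("label table must have two tab-separated columns")
  if (tolower(df[1, 1]) %in% c("sample", "sample_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(df[[2]], df[[1]])
}
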