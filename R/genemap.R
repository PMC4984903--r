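# Gene normalisation, gene-to-module assignment, gene-map construction
# and partition-similarity scoring.
#
# Each gene profile is coded to mean 0 with values in [-1, 1]; a gene is
# assigned to the sample group where its mean coded expression is
# largest, and the reordered matrix (gene blocks x sample groups) shows
# one expression block per module.

#' Normalise a gene expression profile to a coded vector
#'
#' Mean-centres the vector, then divides by the maximum absolute centred
#' value, giving a coded vector with mean 0 and values in [-1, 1] (a
#' constant profile codes to all zeros). This mean-centre/max-abs scheme is
#' the unique simple construction meeting both stated postconditions; the
#' source's displayed normalisation steps are not recoverable.
#'
#' @param values numeric vector of one gene's expression over samples.
#' @return coded numeric vector of the same length.
#' @export
normalise_gene <- function(values) {
  b <- values - mean(values)
  m <- max(abs(b))
  if (m == 0) return(rep(0, length(values)))
  b / m
}

#' @rdname normalise_gene
#' @param expr genes x samples matrix.
#' @return `normalise_matrix`: the matrix with every row coded.
#' @export
normalise_matrix <- function(expr) {
  out <- t(apply(unclass(expr), 1, normalise_gene))
  dimnames(out) <- dimnames(expr)
  out
}

#' Mean coded expression of every gene in every sample group
#'
#' @param norm normalised genes x samples matrix.
#' @param partition partition of the samples: list of sample label (or
#'   column index) vectors, or a membership vector over columns.
#' @return genes x groups matrix of means; columns follow partition order.
#' @export
group_mean_expression <- function(norm, partition) {
  groups <- resolve_sample_groups(partition, colnames(norm), ncol(norm))
  if (any(lengths(groups) == 0)) stop("empty sample group")
  out <- vapply(groups, function(idx) rowMeans(norm[, idx, drop = FALSE]),
                numeric(nrow(norm)))
  rownames(out) <- rownames(norm)
  out
}

# partition given as list of labels/indices or membership vector -> list
# of column indices.
resolve_sample_groups <- function(partition, sample_ids, n) {
  if (!is.list(partition)) {
    if (length(partition) != n) stop("membership vector length mismatch")
    gr <- split(seq_len(n), factor(partition, levels = unique(partition)))
    names(gr) <- NULL
    return(gr)
  }
  lapply(partition, function(s) {
    idx <- if (is.numeric(s)) as.integer(s) else match(as.character(s), sample_ids)
    if (anyNA(idx)) stop("unknown sample id in partition")
    idx
  })
}

#' Assign genes to the sample group they most strongly express
#'
#' Each gene goes to the arg-max group of its mean coded expression (ties
#' to the lowest group index); within a block genes are sorted by
#' decreasing defining-group mean. Blocks partition the gene set.
#'
#' @param means genes x groups matrix from [group_mean_expression()].
#' @return list with `blocks` (list of integer gene-row vectors, ordered)
#'   and `table` (data frame gene_id, block, defining_mean in final map
#'   order).
#' @export
assign_genes <- function(means) {
  L <- ncol(means)
  blk <- max.col(means, ties.method = "first")
  defm <- means[cbind(seq_len(nrow(means)), blk)]
  blocks <- vector("list", L)
  for (j in seq_len(L)) {
    rows <- which(blk == j)
    blocks[[j]] <- rows[order(defm[rows], decreasing = TRUE)]
  }
  ordered <- unlist(blocks, use.names = FALSE)
  tab <- data.frame(gene_id = rownames(means)[ordered],
                    block = rep(seq_len(L), lengths(blocks)),
                    defining_mean = defm[ordered])
  list(blocks = blocks, table = tab)
}

#' Build the gene classification map
#'
#' Reorders the normalised matrix so rows run through the gene blocks
#' B_1..B_L (genes assigned to group j, by decreasing defining mean) and
#' columns through the sample groups X_1..X_L (samples keep input order
#' within a group), producing the block-patterned matrix of coded values.
#' Passing a height-3 tree with `level = 2` gives the three-dimensional
#' map over submodules (groups ordered by parent module, then sibling
#' order).
#'
#' @param norm normalised genes x samples matrix.
#' @param groups a sample partition (list / membership vector) or a
#'   `partition_tree`.
#' @param level tree level to use when `groups` is a tree (1 = modules,
#'   2 = submodules).
#' @return list of class `gene_map`: `matrix` (reordered coded values),
#'   `gene_blocks` (list of gene id vectors), `sample_groups` (list of
#'   sample id vectors), `row_boundaries`, `col_boundaries` (cumulative
#'   block end indices), `assignment` (the gene table).
#' @export
gene_map <- function(norm, groups, level = 1) {
  if (inherits(groups, "partition_tree")) {
    tree <- groups
    if (tree_height(tree) < level) stop("tree too shallow for requested level")
    groups <- lapply(level_partition(pad_to_height(tree, max(tree_height(tree), level)),
                                     level),
                     function(idx) tree$vlabels[idx])
  }
  gidx <- resolve_sample_groups(groups, colnames(norm), ncol(norm))
  gidx <- lapply(gidx, sort)           # samples keep input order within a group
  means <- group_mean_expression(norm, gidx)
  asg <- assign_genes(means)
  row_order <- unlist(asg$blocks, use.names = FALSE)
  col_order <- unlist(gidx, use.names = FALSE)
  M <- norm[row_order, col_order, drop = FALSE]
  structure(list(matrix = M,
                 gene_blocks = lapply(asg$blocks, function(r) rownames(norm)[r]),
                 sample_groups = lapply(gidx, function(c) colnames(norm)[c]),
                 row_boundaries = cumsum(lengths(asg$blocks)),
                 col_boundaries = cumsum(lengths(gidx)),
                 assignment = asg$table),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("gene_map: %d genes x %d samples in %d blocks\n",
              nrow(x$matrix), ncol(x$matrix), length(x$gene_blocks)))
  cat("block sizes:", paste(lengths(x$gene_blocks), collapse = ", "), "\n")
  invisible(x)
}

#' Similarity between two sample sets
#'
#' Jaccard index |X n Y| / |X u Y| by default; `metric = "recall"` gives
#' the asymmetric |X n Y| / |Y| (fraction of the true type Y recovered).
#' Two empty sets score 0 with a warning.
#'
#' @param X,Y vectors of sample ids.
#' @param metric "jaccard" or "recall".
#' @return a score in [0, 1].
#' @export
set_similarity <- function(X, Y, metric = c("jaccard", "recall")) {
  metric <- match.arg(metric)
  X <- unique(X); Y <- unique(Y)
  if (length(X) == 0 && length(Y) == 0) {
    warning("both sets empty; similarity defined as 0")
    return(0)
  }
  inter <- length(intersect(X, Y))
  if (metric == "jaccard") inter / length(union(X, Y))
  else {
    if (length(Y) == 0) return(0)
    inter / length(Y)
  }
}

#' Similarity of a found partition to the true types
#'
#' For each true type Y_j the best similarity over all found modules is
#' reported, together with the size-weighted average sum_j (|Y_j|/n)
#' score_j. Both partitions must cover the same sample universe.
#'
#' @param found,truth partitions of the same samples: lists of sample id
#'   vectors, or named membership vectors (names = sample ids).
#' @param metric passed to [set_similarity()].
#' @return list of class `similarity_table`: `scores` (data frame type,
#'   size, best_module, score) and `weighted_average`.
#' @export
partition_similarity <- function(found, truth, metric = c("jaccard", "recall")) {
  metric <- match.arg(metric)
  found <- as_label_partition(found)
  truth <- as_label_partition(truth)
  uf <- unlist(found); ut <- unlist(truth)
  if (!setequal(uf, ut)) {
    extra <- setdiff(uf, ut); missing <- setdiff(ut, uf)
    stop("sample universes differ; extra in found: ",
         paste(extra, collapse = ","), "; missing from found: ",
         paste(missing, collapse = ","))
  }
  n <- length(ut)
  scores <- data.frame(type = if (!is.null(names(truth))) names(truth)
                              else as.character(seq_along(truth)),
                       size = lengths(truth),
                       best_module = NA_integer_,
                       score = NA_real_)
  for (j in seq_along(truth)) {
    s <- vapply(found, set_similarity, numeric(1), Y = truth[[j]],
                metric = metric)
    scores$best_module[j] <- which.max(s)
    scores$score[j] <- max(s)
  }
  structure(list(scores = scores,
                 weighted_average = sum(scores$size / n * scores$score)),
            class = "similarity_table")
}

as_label_partition <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  if (is.null(names(x))) stop("membership vector must be named by sample id")
  sp <- split(names(x), factor(x, levels = unique(x)))
  sp
}

#' @export
print.similarity_table <- function(x, ...) {
  print(x$scores)
  cat(sprintf("weighted average similarity: %.4f\n", x$weighted_average))
  invisible(x)
}
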