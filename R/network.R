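# Cell-sample network construction: Pearson weights between sample
# expression profiles, noise amplification by a constant modifier, top-k
# edge retention, and the entropy-curve rule that chooses k at the stable
# point of least one-dimensional structural entropy.

#' Expression matrix constructor
#'
#' A genes x samples real matrix with unique gene and sample identifiers.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional identifiers (default taken from
#'   dimnames, else generated).
#' @return a numeric matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (nrow(values) < 2 || ncol(values) < 3)
    stop("expression matrix needs at least 2 genes and 3 samples")
  if (anyNA(values)) stop("missing values in expression matrix; impute or filter first")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Pairwise Pearson correlations between sample profiles
#'
#' The raw sample-network weights: for every pair of samples, the Pearson
#' correlation of their gene expression profiles. The diagonal is set to
#' NA (a sample is never its own neighbour).
#'
#' @param expr genes x samples matrix (see [expression_matrix()]).
#' @return symmetric n x n matrix with NA diagonal, entries in [-1, 1].
#' @export
pearson_weights <- function(expr) {
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample profile(s): ",
         paste(colnames(expr)[sds == 0], collapse = ", "))
  W <- stats::cor(unclass(expr))
  diag(W) <- NA_real_
  W
}

#' Noise amplification of sample weights
#'
#' Adds the same modifier M to every pairwise weight so that trivial
#' (noisy) weights are relatively inflated and easier to filter by top-k
#' retention. By default M realises the "every sample spreads one unit of
#' extra weight uniformly over the others" rule: M = 1/(n-1) for n < 1000
#' and M = 1/n otherwise (the printed noise-amplifier expressions are not
#' recoverable from the source; this equivalence is). Giving `sigma` sets
#' M = sigma * mean weight (mean over distinct pairs, diagonal excluded);
#' giving `modifier` sets M directly.
#'
#' @param weights symmetric weight matrix from [pearson_weights()].
#' @param sigma optional noise amplifier.
#' @param modifier optional explicit modifier M (overrides `sigma`).
#' @return list with `weights` (amplified matrix), `modifier`, `sigma`
#'   (implied M / mean weight) and `mean_weight`.
#' @export
amplify <- function(weights, sigma = NULL, modifier = NULL) {
  n <- ncol(weights)
  wbar <- mean(weights[upper.tri(weights)])
  M <- if (!is.null(modifier)) modifier
       else if (!is.null(sigma)) sigma * wbar
       else if (n < 1000) 1 / (n - 1) else 1 / n
  W2 <- weights + M
  diag(W2) <- NA_real_
  list(weights = W2, modifier = M,
       sigma = if (wbar != 0) M / wbar else NA_real_,
       mean_weight = wbar)
}

#' Top-k neighbour graph from a weight matrix
#'
#' Keeps, for every sample, its k highest-weight neighbours (ties broken
#' by sample input order) and symmetrises by union: an edge survives if
#' either endpoint selects it. Retained edges carry the supplied matrix's
#' weights; edges with non-positive weight are dropped (their count is in
#' attribute `dropped`).
#'
#' @param weights symmetric n x n weight matrix, NA diagonal.
#' @param k neighbour count, 1 <= k <= n-1.
#' @param labels optional vertex labels (default column names).
#' @return a `weighted_graph` over the samples.
#' @export
topk_graph <- function(weights, k, labels = colnames(weights)) {
  n <- ncol(weights)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]")
  sel_i <- integer(0); sel_j <- integer(0)
  for (v in seq_len(n)) {
    wv <- weights[, v]
    wv[v] <- -Inf
    top <- order(wv, decreasing = TRUE)[seq_len(k)]  # ties: input order
    sel_i <- c(sel_i, rep(v, k)); sel_j <- c(sel_j, top)
  }
  lo <- pmin(sel_i, sel_j); hi <- pmax(sel_i, sel_j)
  key <- (lo - 1) * n + hi
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]
  w <- weights[cbind(lo, hi)]
  pos <- w > 0
  g <- weighted_graph(labels,
                      data.frame(from = lo[pos], to = hi[pos], weight = w[pos]))
  attr(g, "dropped") <- sum(!pos)
  g
}

#' Entropy curve H(k) over neighbour counts
#'
#' H(k) is the one-dimensional structural entropy of the top-k graph built
#' from the (amplified) weights. An interior k is a stable point when
#' H(k-1) > H(k) and H(k+1) > H(k) both hold strictly.
#'
#' @param weights symmetric weight matrix (normally amplified).
#' @param k_range increasing integer vector of k values to scan; default
#'   2..min(50, n-1).
#' @return data frame of class `entropy_curve` with columns `k`, `H`,
#'   `stable`.
#' @export
entropy_curve <- function(weights, k_range = NULL) {
  n <- ncol(weights)
  if (is.null(k_range)) k_range <- seq(2L, min(50L, n - 1L))
  k_range <- as.integer(k_range)
  if (length(k_range) == 0) stop("empty k range")
  if (any(diff(k_range) <= 0)) stop("k range must be strictly increasing")
  if (min(k_range) < 1 || max(k_range) > n - 1) stop("k range outside [1, n-1]")
  H <- vapply(k_range, function(k) one_dim_entropy(topk_graph(weights, k)),
              numeric(1))
  curve <- data.frame(k = k_range, H = H, stable = FALSE)
  m <- nrow(curve)
  if (m >= 3) {
    interior <- 2:(m - 1)
    curve$stable[interior] <- H[interior] < H[interior - 1] &
                              H[interior] < H[interior + 1]
  }
  class(curve) <- c("entropy_curve", class(curve))
  curve
}

#' Choose k from an entropy curve
#'
#' The stable point with the least H (ties: smallest k). When no stable
#' point exists, the global argmin of H is returned with a warning.
#'
#' @param curve an `entropy_curve`.
#' @return the chosen integer k.
#' @export
select_k <- function(curve) {
  if (nrow(curve) == 0) stop("empty entropy curve")
  st <- curve[curve$stable, , drop = FALSE]
  if (nrow(st) == 0) {
    warning("no stable point on the entropy curve; using the global argmin of H")
    return(curve$k[which.min(curve$H)])
  }
  st$k[which.min(st$H)]
}

#' Build the cell-sample network from an expression matrix
#'
#' End-to-end composition: Pearson weights, noise amplification, entropy
#' curve over the amplified top-k graphs, stable-point choice of k, and
#' the final top-k network. The final network carries raw Pearson weights
#' by default (amplification only steers the choice of k; adding a
#' constant does not change any top-k neighbour set).
#'
#' @param expr genes x samples matrix (see [expression_matrix()]).
#' @param k optional forced neighbour count (skips the k-chooser).
#' @param k_range optional scan range for the k-chooser.
#' @param sigma,modifier noise amplification overrides (see [amplify()]).
#' @param weights `"raw"` (default) or `"amplified"`: which weights the
#'   final network carries.
#' @return list of class `sample_network` with `graph` (a
#'   `weighted_graph`) and `report` (mean weight, modifier, sigma, curve,
#'   stable points, chosen k, dropped edge count).
#' @export
build_network <- function(expr, k = NULL, k_range = NULL,
                          sigma = NULL, modifier = NULL,
                          weights = c("raw", "amplified")) {
  weights <- match.arg(weights)
  W <- pearson_weights(expr)
  amp <- amplify(W, sigma = sigma, modifier = modifier)
  curve <- NULL; k_forced <- !is.null(k)
  if (is.null(k)) {
    curve <- entropy_curve(amp$weights, k_range)
    k <- select_k(curve)
  }
  Wfinal <- if (weights == "raw") W else amp$weights
  graph <- topk_graph(Wfinal, k)
  out <- list(graph = graph,
              report = list(mean_weight = amp$mean_weight,
                            modifier = amp$modifier, sigma = amp$sigma,
                            curve = curve,
                            stable_points = if (!is.null(curve)) curve$k[curve$stable] else integer(0),
                            k = k, k_forced = k_forced,
                            weight_mode = weights,
                            dropped_edges = attr(graph, "dropped")))
  class(out) <- "sample_network"
  out
}

#' @export
print.sample_network <- function(x, ...) {
  cat(sprintf("sample_network: k = %d%s, %d vertices, %d edges\n",
              x$report$k, if (x$report$k_forced) " (forced)" else "",
              length(x$graph$labels), nrow(x$graph$edges)))
  if (length(x$report$stable_points))
    cat("stable points:", paste(x$report$stable_points, collapse = ", "), "\n")
  invisible(x)
}
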