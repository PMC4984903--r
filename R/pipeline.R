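# End-to-end pipeline: expression matrix -> cell-sample network ->
# entropy-minimising partitioning tree -> gene map -> similarity to known
# labels, with all artefacts written as plain text plus a JSON manifest.

#' Run the full expression-to-gene-map pipeline
#'
#' Executes, in order: gene-wise normalisation, sample-network
#' construction (Pearson weights, noise amplification, entropy-guided
#' top-k), K-dimensional structural-entropy minimisation, gene-map
#' construction over the level-`map_level` sample groups, and (when
#' `truth` labels are supplied) partition-similarity scoring. Clinical
#' joins are out of scope; the sample-to-module table is exported for
#' external use.
#'
#' @param expr an `expression_matrix` or path readable by
#'   [read_expression_matrix()].
#' @param truth optional named vector of true type labels (names = sample
#'   ids), or a path to a two-column label table.
#' @param K tree height (2 = modules, 3 = modules + submodules).
#' @param map_level tree level defining the gene-map sample groups;
#'   default K - 1 (modules for K = 2, submodules for K = 3).
#' @param k,k_range,sigma,modifier,weight_mode passed to
#'   [build_network()].
#' @param metric similarity metric, see [set_similarity()].
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_graph.tsv`, `_curve.tsv`, `_tree.json`, `_partition.tsv`,
#'   `_gene_assignment.tsv`, `_genemap.tsv`, `_genemap_blocks.json`,
#'   `_similarity.tsv` (with truth) and `_manifest.json`. Partial
#'   artefacts are removed if a stage fails.
#' @return list of class `structent_pipeline` with components `network`,
#'   `tree`, `modules` (level-1 sample-id sets), `map_groups`, `genemap`,
#'   `similarity` (or NULL), `entropy`, `manifest`.
#' @export
run_pipeline <- function(expr, truth = NULL, K = 2, map_level = K - 1,
                         k = NULL, k_range = NULL, sigma = NULL,
                         modifier = NULL, weight_mode = "raw",
                         metric = "jaccard", out_prefix = NULL) {
  stopifnot(K >= 2, map_level >= 1, map_level <= K)
  written <- character(0)
  emit <- function(suffix, writer) {
    if (is.null(out_prefix)) return(invisible(NULL))
    p <- paste0(out_prefix, suffix)
    writer(p)
    written <<- c(written, p)
    invisible(p)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      if (length(written)) unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (is.character(expr)) expr <- stage("read", read_expression_matrix(expr))
  if (is.character(truth)) truth <- stage("read", read_labels(truth))
  if (!is.null(truth)) {
    if (is.null(names(truth))) stop("truth labels must be named by sample id")
    if (!setequal(names(truth), colnames(expr)))
      stop("truth sample ids do not match expression columns")
  }

  norm <- stage("normalise", normalise_matrix(expr))
  net <- stage("network",
               build_network(expr, k = k, k_range = k_range, sigma = sigma,
                             modifier = modifier, weights = weight_mode))
  emit("_graph.tsv", function(p) write_edgelist(net$graph, p))
  if (!is.null(net$report$curve))
    emit("_curve.tsv", function(p) write_curve_tsv(net$report$curve, p))

  tree <- stage("partition", minimize_entropy(net$graph, K = K))
  emit("_tree.json", function(p) write_tree_json(tree, p))
  emit("_partition.tsv", function(p) write_partition_tsv(tree, p))

  modules <- lapply(level_partition(tree, 1), function(i) tree$vlabels[i])
  map_groups <- lapply(level_partition(tree, map_level),
                       function(i) tree$vlabels[i])
  gm <- stage("genemap", gene_map(norm, map_groups))
  emit("_gene_assignment.tsv", function(p)
    utils::write.table(gm$assignment, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("_genemap.tsv", function(p) {
    df <- data.frame(gene_id = rownames(gm$matrix), gm$matrix,
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  emit("_genemap_blocks.json", function(p)
    jsonlite::write_json(list(row_boundaries = gm$row_boundaries,
                              col_boundaries = gm$col_boundaries,
                              group_paths = names(map_groups)),
                         p, auto_unbox = FALSE, pretty = TRUE))

  sim <- NULL
  if (!is.null(truth)) {
    sim <- stage("similarity",
                 partition_similarity(modules, as_label_partition(truth),
                                      metric = metric))
    emit("_similarity.tsv", function(p)
      utils::write.table(sim$scores, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("structent")),
                   n_genes = nrow(expr), n_samples = ncol(expr),
                   K = K, map_level = map_level,
                   k = net$report$k, k_forced = net$report$k_forced,
                   mean_weight = net$report$mean_weight,
                   modifier = net$report$modifier, sigma = net$report$sigma,
                   stable_points = net$report$stable_points,
                   weight_mode = weight_mode,
                   n_modules = length(modules),
                   n_map_groups = length(map_groups),
                   entropy = attr(tree, "entropy"),
                   weighted_similarity = if (!is.null(sim)) sim$weighted_average else NULL,
                   metric = metric)
  emit("_manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))

  structure(list(network = net, tree = tree, modules = modules,
                 map_groups = map_groups, genemap = gm, similarity = sim,
                 entropy = attr(tree, "entropy"), manifest = manifest),
            class = "structent_pipeline")
}

#' @export
print.structent_pipeline <- function(x, ...) {
  cat(sprintf("structent pipeline: k = %d, %d modules, %d map groups, H = %.4f bits\n",
              x$manifest$k, x$manifest$n_modules, x$manifest$n_map_groups,
              x$entropy))
  if (!is.null(x$similarity))
    cat(sprintf("weighted similarity to truth: %.4f\n",
                x$similarity$weighted_average))
  invisible(x)
}
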