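# Synthetic generators with planted ground truth: one- and two-level
# planted-partition graphs, and block-structured expression matrices
# (groups of samples sharing over-expressed gene blocks plus Gaussian
# noise). Every generator is deterministic per seed.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Planted-partition graph generator
#'
#' Independent edge inclusion with probability `p_in` within blocks and
#' `p_out` between blocks; unit weights, optionally jittered. With
#' `bridge = TRUE` one unit edge is forced between consecutive blocks
#' (first vertex to first vertex), which builds the classic
#' bridged-cliques test graph when `p_in = 1`, `p_out = 0`. A
#' disconnected result is flagged in the truth, not rejected.
#'
#' @param sizes integer vector of block sizes.
#' @param p_in,p_out within/between edge probabilities, `p_out < p_in`.
#' @param weight_jitter sd of multiplicative lognormal-ish jitter
#'   (weights = exp(rnorm(0, jitter))); 0 = unit weights.
#' @param bridge force one unit edge between consecutive blocks.
#' @param seed RNG seed (restores the caller's RNG state).
#' @return list with `graph` (a `weighted_graph`) and `truth` (list:
#'   `membership` integer vector, `params`, `connected`).
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, weight_jitter = 0,
                                    bridge = FALSE, seed = NULL) {
  stopifnot(p_out >= 0, p_out <= p_in, p_in <= 1)
  n <- sum(sizes)
  member <- rep(seq_along(sizes), sizes)
  labels <- paste0("v", seq_len(n))
  with_seed(seed, {
    pr <- utils::combn(n, 2)
    same <- member[pr[1, ]] == member[pr[2, ]]
    p <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pr)) < p
    ei <- pr[1, keep]; ej <- pr[2, keep]
    if (bridge && length(sizes) > 1) {
      firsts <- cumsum(c(1, sizes[-length(sizes)]))
      for (b in seq_len(length(sizes) - 1)) {
        a <- firsts[b]; z <- firsts[b + 1]
        if (!any(ei == a & ej == z)) { ei <- c(ei, a); ej <- c(ej, z) }
      }
    }
    w <- if (weight_jitter > 0) exp(stats::rnorm(length(ei), 0, weight_jitter))
         else rep(1, length(ei))
    g <- weighted_graph(labels, data.frame(from = ei, to = ej, weight = w))
    truth <- list(membership = member,
                  params = list(sizes = sizes, p_in = p_in, p_out = p_out,
                                weight_jitter = weight_jitter, bridge = bridge,
                                seed = seed),
                  connected = length(unique(graph_components(g))) == 1)
    list(graph = g, truth = truth)
  })
}

#' Two-level (hierarchical) planted graph generator
#'
#' Three-tier connection probabilities: `p_sub` within a submodule,
#' `p_mod` between submodules of the same module, `p_out` between
#' modules; requires `p_out < p_mod < p_sub`. Truth records both levels.
#'
#' @param modules number of level-1 modules.
#' @param submodules submodules per module.
#' @param subsize vertices per submodule.
#' @param p_sub,p_mod,p_out the three connection probabilities.
#' @inheritParams planted_partition_graph
#' @return list with `graph` and `truth` (`membership` level-1,
#'   `sub_membership` level-2, `params`, `connected`).
#' @export
hierarchical_planted_graph <- function(modules, submodules, subsize,
                                       p_sub, p_mod, p_out,
                                       weight_jitter = 0, seed = NULL) {
  stopifnot(p_out < p_mod, p_mod < p_sub, p_sub <= 1, p_out >= 0)
  n <- modules * submodules * subsize
  mod <- rep(seq_len(modules), each = submodules * subsize)
  sub <- rep(seq_len(modules * submodules), each = subsize)
  labels <- paste0("v", seq_len(n))
  with_seed(seed, {
    pr <- utils::combn(n, 2)
    same_sub <- sub[pr[1, ]] == sub[pr[2, ]]
    same_mod <- mod[pr[1, ]] == mod[pr[2, ]]
    p <- ifelse(same_sub, p_sub, ifelse(same_mod, p_mod, p_out))
    keep <- stats::runif(ncol(pr)) < p
    ei <- pr[1, keep]; ej <- pr[2, keep]
    w <- if (weight_jitter > 0) exp(stats::rnorm(length(ei), 0, weight_jitter))
         else rep(1, length(ei))
    g <- weighted_graph(labels, data.frame(from = ei, to = ej, weight = w))
    truth <- list(membership = mod, sub_membership = sub,
                  params = list(modules = modules, submodules = submodules,
                                subsize = subsize, p_sub = p_sub,
                                p_mod = p_mod, p_out = p_out, seed = seed),
                  connected = length(unique(graph_components(g))) == 1)
    list(graph = g, truth = truth)
  })
}

#' Block-structured synthetic expression matrix
#'
#' Emulates the correlation structure the pipeline assumes in real tumour
#' expression data: each sample group over-expresses its own disjoint
#' block of signal genes, on top of a per-gene baseline expression level
#' shared by all samples. values = baseline_g + effect * (signal gene of
#' the sample's group) + iid Gaussian noise. The per-gene baseline spread
#' (`gene_level_sd`, default 2) reproduces the strongly positive
#' correlation between *all* pairs of samples seen in real expression
#' data (every sample shares the same gene-level profile); without it,
#' samples from different groups would be anti-correlated and the
#' entropy-guided choice of the neighbour count k has no interior
#' optimum to find. The generator does not emulate platform artefacts,
#' probe effects or heavy-tailed microarray noise.
#'
#' @param groups number of sample groups.
#' @param samples_per_group samples in each group.
#' @param genes total number of genes.
#' @param signal_per_group signal genes per group (disjoint blocks; the
#'   remainder are pure-noise genes).
#' @param effect over-expression added on signal genes (default 5).
#' @param noise_sd Gaussian noise sd (default 1, so effect/sd = 5).
#' @param gene_level_sd sd of the per-gene baseline expression level
#'   (default 2).
#' @param baseline constant offset added to everything.
#' @param seed RNG seed.
#' @return list with `expr` (an `expression_matrix`), `truth`
#'   (`membership` per sample, `signal_genes` list of gene-id vectors per
#'   group, `params`).
#' @export
synthetic_expression <- function(groups = 3, samples_per_group = 12,
                                 genes = 600, signal_per_group = 100,
                                 effect = 5, noise_sd = 1,
                                 gene_level_sd = 2, baseline = 0,
                                 seed = NULL) {
  stopifnot(effect >= 0, groups * signal_per_group <= genes)
  n <- groups * samples_per_group
  member <- rep(seq_len(groups), each = samples_per_group)
  gene_ids <- paste0("g", seq_len(genes))
  sample_ids <- paste0("s", seq_len(n))
  with_seed(seed, {
    gene_level <- stats::rnorm(genes, 0, gene_level_sd)
    vals <- matrix(baseline + gene_level, genes, n) +
      matrix(stats::rnorm(genes * n, 0, noise_sd), genes, n)
    signal <- vector("list", groups)
    for (gr in seq_len(groups)) {
      rows <- ((gr - 1) * signal_per_group + 1):(gr * signal_per_group)
      vals[rows, member == gr] <- vals[rows, member == gr] + effect
      signal[[gr]] <- gene_ids[rows]
    }
    expr <- expression_matrix(vals, gene_ids, sample_ids)
    truth <- list(membership = member, signal_genes = signal,
                  params = list(groups = groups,
                                samples_per_group = samples_per_group,
                                genes = genes,
                                signal_per_group = signal_per_group,
                                effect = effect, noise_sd = noise_sd,
                                gene_level_sd = gene_level_sd,
                                baseline = baseline, seed = seed))
    list(expr = expr, truth = truth)
  })
}
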