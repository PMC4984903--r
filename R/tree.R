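# Partitioning trees and structural entropy of a graph given a partition
# (explicit two-level form) or a partitioning tree of any height.
#
# A partitioning tree is a rooted ordered tree whose root holds all
# vertices, whose leaves hold single vertices, and whose every level (after
# padding to uniform height) partitions the vertex set. Level 1 of the
# entropy-minimising tree gives the modules, level 2 the submodules.

#' Partitioning tree constructors
#'
#' A `partition_tree` stores, per node id: `parent` (0 for the root, node
#' 1), an ordered `children` list, `vertex` (the graph vertex index for a
#' leaf, NA otherwise) and the graph's vertex labels. Sibling order is
#' total and stable; dotted node paths ("2.1" = first child of the second
#' module) name nodes in all outputs.
#'
#' `singleton_tree` builds the root-over-singleton-leaves start tree of the
#' greedy minimiser; `tree_from_partition` builds the height-2 tree whose
#' level-1 nodes are the given modules.
#'
#' @param graph a `weighted_graph`.
#' @param partition a partition of the graph's vertices: a list of vertex
#'   label (or index) vectors, or a membership vector of length n.
#' @return a `partition_tree`.
#' @export
singleton_tree <- function(graph) {
  n <- length(graph$labels)
  new_tree(parent = c(0L, rep(1L, n)),
           children = c(list(seq_len(n) + 1L), rep(list(integer(0)), n)),
           vertex = c(NA_integer_, seq_len(n)),
           vlabels = graph$labels)
}

#' @rdname singleton_tree
#' @export
tree_from_partition <- function(graph, partition) {
  parts <- as_partition(partition, graph)
  n <- length(graph$labels)
  L <- length(parts)
  parent <- c(0L, rep(NA_integer_, L + n))
  children <- vector("list", 1 + L + n)
  vertex <- rep(NA_integer_, 1 + L + n)
  children[[1]] <- seq_len(L) + 1L
  nid <- 1L + L
  for (m in seq_len(L)) {
    parent[m + 1L] <- 1L
    kids <- integer(length(parts[[m]]))
    for (t in seq_along(parts[[m]])) {
      nid <- nid + 1L
      parent[nid] <- m + 1L
      vertex[nid] <- parts[[m]][t]
      children[[nid]] <- integer(0)
      kids[t] <- nid
    }
    children[[m + 1L]] <- kids
  }
  new_tree(parent, children, vertex, graph$labels)
}

new_tree <- function(parent, children, vertex, vlabels) {
  structure(list(parent = parent, children = children, vertex = vertex,
                 vlabels = vlabels),
            class = "partition_tree")
}

#' @export
print.partition_tree <- function(x, ...) {
  cat(sprintf("partition_tree: %d nodes, %d leaves, height %d\n",
              length(x$parent), sum(!is.na(x$vertex)), tree_height(x)))
  invisible(x)
}

# Coerce partition-like inputs to a list of integer vertex-index vectors.
as_partition <- function(x, graph) {
  n <- length(graph$labels)
  if (!is.list(x)) {  # membership vector
    if (length(x) != n) stop("membership vector length must equal vertex count")
    x <- split(seq_len(n), factor(x, levels = unique(x)))
    names(x) <- NULL
  } else {
    x <- lapply(x, function(s) {
      idx <- if (is.numeric(s)) as.integer(s) else match(as.character(s), graph$labels)
      if (anyNA(idx)) stop("partition refers to unknown vertex label")
      idx
    })
  }
  all_v <- unlist(x)
  if (any(lengths(x) == 0)) stop("partition sets must be non-empty")
  if (anyDuplicated(all_v)) stop("partition sets must be disjoint")
  if (length(all_v) != n || !setequal(all_v, seq_len(n)))
    stop("partition must cover all vertices")
  x
}

node_heights <- function(tree) {
  h <- integer(length(tree$parent))
  ord <- tree_preorder(tree)
  for (v in ord) if (tree$parent[v] > 0) h[v] <- h[tree$parent[v]] + 1L
  h
}

tree_preorder <- function(tree) {
  out <- integer(length(tree$parent))
  stack <- 1L; k <- 0L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    k <- k + 1L; out[k] <- v
    stack <- c(tree$children[[v]], stack)
  }
  out
}

#' Tree accessors
#'
#' `tree_height` is the maximum leaf depth (root depth 0);
#' `tree_vertex_sets` gives, per node, the integer vertex indices below it;
#' `node_paths` gives the dotted 1-based path label of each node ("" for
#' the root, "2.1" for the first child of the second level-1 node).
#'
#' @param tree a `partition_tree`.
#' @return see each description.
#' @export
tree_height <- function(tree) max(node_heights(tree)[!is.na(tree$vertex)])

#' @rdname tree_height
#' @export
tree_vertex_sets <- function(tree) {
  sets <- vector("list", length(tree$parent))
  for (v in rev(tree_preorder(tree))) {
    sets[[v]] <- if (!is.na(tree$vertex[v])) tree$vertex[v]
                 else unlist(sets[tree$children[[v]]], use.names = FALSE)
  }
  sets
}

#' @rdname tree_height
#' @export
node_paths <- function(tree) {
  paths <- character(length(tree$parent))
  for (v in tree_preorder(tree)) {
    p <- tree$parent[v]
    if (p == 0L) { paths[v] <- ""; next }
    idx <- match(v, tree$children[[p]])
    paths[v] <- if (paths[p] == "") as.character(idx)
                else paste(paths[p], idx, sep = ".")
  }
  paths
}

#' Validate a partitioning tree against a graph
#'
#' Checks the defining invariants: node 1 is the unique root; children
#' link back to their parent; every leaf holds exactly one vertex; each
#' vertex appears in exactly one leaf; every internal node has at least one
#' child. Signals an error naming the first offending node.
#'
#' @param tree a `partition_tree`.
#' @param graph the `weighted_graph` the tree partitions.
#' @return invisibly TRUE.
#' @export
validate_tree <- function(tree, graph) {
  N <- length(tree$parent)
  if (tree$parent[1] != 0L || any(tree$parent[-1] <= 0L))
    stop("node 1 must be the unique root")
  for (v in seq_len(N)) {
    for (c in tree$children[[v]])
      if (tree$parent[c] != v) stop(sprintf("node %d: child link broken", v))
    if (is.na(tree$vertex[v]) && length(tree$children[[v]]) == 0 && v != 1L)
      stop(sprintf("node %d: internal node without children", v))
    if (!is.na(tree$vertex[v]) && length(tree$children[[v]]) > 0)
      stop(sprintf("node %d: leaf with children", v))
  }
  leaves <- tree$vertex[!is.na(tree$vertex)]
  n <- length(graph$labels)
  if (length(leaves) != n || anyDuplicated(leaves) ||
      !setequal(leaves, seq_len(n)))
    stop("leaves must hold each graph vertex exactly once")
  invisible(TRUE)
}

# Volume V and cut g of every tree node. For each edge, weight is added to
# the cut of every node strictly below the lowest common ancestor of its
# two endpoints' leaves; volumes accumulate bottom-up from leaf degrees.
node_stats <- function(graph, tree) {
  N <- length(tree$parent)
  V <- numeric(N); g <- numeric(N)
  leaf_of <- integer(length(graph$labels))
  leaf_ids <- which(!is.na(tree$vertex))
  leaf_of[tree$vertex[leaf_ids]] <- leaf_ids
  for (v in rev(tree_preorder(tree))) {
    V[v] <- if (!is.na(tree$vertex[v])) graph$degree[tree$vertex[v]]
            else sum(V[tree$children[[v]]])
  }
  path_to_root <- function(node) {
    p <- node
    while (tree$parent[p[1]] > 0L) p <- c(tree$parent[p[1]], p)
    p
  }
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      pu <- path_to_root(leaf_of[graph$edges$i[e]])
      pv <- path_to_root(leaf_of[graph$edges$j[e]])
      d <- 1L
      while (d <= min(length(pu), length(pv)) && pu[d] == pv[d]) d <- d + 1L
      below <- c(pu[d:length(pu)], pv[d:length(pv)])
      g[below] <- g[below] + graph$edges$w[e]
    }
  }
  list(V = V, g = g)
}

#' Structural entropy of a graph under a partition (two-level form)
#'
#' The explicit two-dimensional form: with modules X_j of volume Vol_j and
#' cut g_j (total weight of edges leaving X_j), and vol the graph volume,
#'
#'   H = sum_j (Vol_j/vol) H(d_i/Vol_j : i in X_j)
#'     + sum_j (g_j/vol) log2(vol/Vol_j).
#'
#' A module consisting only of isolated vertices has zero volume and
#' contributes 0. The singleton partition and the one-module partition both
#' reduce to the one-dimensional entropy. The displayed source equation is
#' reconstructed; the height-2 tree identity test guards it.
#'
#' @param graph a `weighted_graph` with positive volume.
#' @param partition a partition (see [tree_from_partition()]).
#' @return entropy in bits.
#' @export
partition_entropy <- function(graph, partition) {
  if (graph$volume <= 0) stop("degenerate graph: volume is zero")
  parts <- as_partition(partition, graph)
  vol <- graph$volume
  H <- 0
  for (X in parts) {
    d <- graph$degree[X]
    Volj <- sum(d)
    if (Volj <= 0) next
    within <- sum(graph$edges$w[graph$edges$i %in% X & graph$edges$j %in% X])
    gj <- Volj - 2 * within
    H <- H + sum(xlog2ratio(d / vol, Volj / vol) * -1) +
      (gj / vol) * (log2(vol) - log2(Volj))
  }
  H
}

#' Structural entropy of a graph under a partitioning tree
#'
#' The general form: summing over all non-root nodes a with volume V_a,
#' cut g_a and parent volume V_parent,
#'
#'   H = sum_a (g_a/vol) log2(V_parent / V_a),
#'
#' where for a leaf holding vertex v, V_a = g_a = degree(v). Nodes of zero
#' volume contribute 0. For a height-2 tree this equals
#' [partition_entropy()] on the level-1 partition, and inserting a unary
#' pass-through node never changes the value.
#'
#' @param graph a `weighted_graph` with positive volume.
#' @param tree a valid `partition_tree` for the graph.
#' @return entropy in bits.
#' @export
tree_entropy <- function(graph, tree) {
  if (graph$volume <= 0) stop("degenerate graph: volume is zero")
  validate_tree(tree, graph)
  st <- node_stats(graph, tree)
  vol <- graph$volume
  H <- 0
  for (v in seq_along(tree$parent)[-1]) {
    p <- tree$parent[v]
    if (st$V[v] <= 0 || st$g[v] <= 0) next
    Vp <- if (p == 1L && tree$parent[1] == 0L) st$V[1] else st$V[p]
    H <- H + (st$g[v] / vol) * (log2(Vp) - log2(st$V[v]))
  }
  H
}

#' Extract the partition at a given tree level
#'
#' Level 1 yields the modules, level 2 the submodules. The tree must have
#' uniform leaf depth at least `level` (apply [pad_to_height()] first if
#' needed); sets are returned in tree (sibling) order.
#'
#' @param tree a `partition_tree` padded to uniform height >= `level`.
#' @param level positive integer depth.
#' @return list of integer vertex-index vectors covering all vertices.
#' @export
level_partition <- function(tree, level) {
  stopifnot(level >= 1)
  h <- node_heights(tree)
  leafh <- h[!is.na(tree$vertex)]
  if (any(leafh < level))
    stop("level exceeds the depth of some leaf; pad_to_height first")
  sets <- tree_vertex_sets(tree)
  at <- intersect(tree_preorder(tree), which(h == level))
  out <- sets[at]
  names(out) <- node_paths(tree)[at]
  out
}

#' Pad a partitioning tree to uniform height K
#'
#' Inserts unary pass-through nodes above shallow leaves so that every leaf
#' sits at depth exactly K; each inserted node has the same vertex set as
#' its single child, so the tree entropy is unchanged.
#'
#' @param tree a `partition_tree` of height <= K.
#' @param K target uniform height.
#' @return a `partition_tree` of uniform leaf depth K.
#' @export
pad_to_height <- function(tree, K) {
  h <- node_heights(tree)
  if (max(h[!is.na(tree$vertex)]) > K) stop("tree height exceeds K")
  parent <- tree$parent; children <- tree$children; vertex <- tree$vertex
  for (leaf in which(!is.na(tree$vertex))) {
    need <- K - h[leaf]
    if (need == 0) next
    above <- parent[leaf]
    pos <- match(leaf, children[[above]])
    cur_child <- leaf
    for (d in seq_len(need)) {      # chain of unary nodes above the leaf
      parent <- c(parent, 0L)
      vertex <- c(vertex, NA_integer_)
      nid <- length(parent)
      children <- c(children, list(cur_child))
      parent[cur_child] <- nid
      cur_child <- nid
    }
    children[[above]][pos] <- cur_child
    parent[cur_child] <- above
  }
  new_tree(parent, children, vertex, tree$vlabels)
}

# --- serialisation -----------------------------------------------------

#' Tree JSON input/output
#'
#' Nested objects `{label, children:[...]}` with leaves
#' `{label, vertex}`; `label` is the dotted 1-based path, `vertex` the
#' sample label. Round-trips preserve sibling order.
#'
#' @param tree a `partition_tree`.
#' @param path file path.
#' @return `read_tree_json` returns a `partition_tree` (vertex order taken
#'   from `labels` if given, else leaf order); `write_tree_json` invisibly
#'   returns the path.
#' @export
write_tree_json <- function(tree, path) {
  paths <- node_paths(tree)
  build <- function(v) {
    if (!is.na(tree$vertex[v]))
      list(label = paths[v], vertex = tree$vlabels[tree$vertex[v]])
    else
      list(label = paths[v],
           children = lapply(tree$children[[v]], build))
  }
  jsonlite::write_json(build(1L), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @param labels optional vertex label order for the rebuilt tree.
#' @export
read_tree_json <- function(path, labels = NULL) {
  obj <- jsonlite::read_json(path)
  leaves <- character(0)
  collect <- function(nd) {
    if (!is.null(nd$vertex)) leaves <<- c(leaves, nd$vertex)
    else for (ch in nd$children) collect(ch)
  }
  collect(obj)
  if (is.null(labels)) labels <- leaves
  parent <- integer(0); children <- list(); vertex <- integer(0)
  add <- function(nd, par) {
    parent <<- c(parent, par)
    vertex <<- c(vertex, NA_integer_)
    children[[length(parent)]] <<- integer(0)
    id <- length(parent)
    if (!is.null(nd$vertex)) {
      vi <- match(nd$vertex, labels)
      if (is.na(vi)) stop("tree leaf refers to unknown vertex: ", nd$vertex)
      vertex[id] <<- vi
    } else {
      kids <- vapply(nd$children, add, integer(1), par = id)
      children[[id]] <<- kids
    }
    id
  }
  add(obj, 0L)
  new_tree(parent, children, vertex, labels)
}

#' Write / read a sample-to-module partition table
#'
#' Two-column tab-separated `sample_id TAB module_path`, one row per
#' sample, in sample input order. The module path of a sample is the
#' dotted path of its leaf's parent (e.g. "2" at K = 2, "2.1" at K = 3).
#'
#' @param tree a `partition_tree` (for writing).
#' @param path file path.
#' @return `read_partition_tsv` returns a named character vector of module
#'   paths keyed by sample id.
#' @export
write_partition_tsv <- function(tree, path) {
  paths <- node_paths(tree)
  leaf_ids <- which(!is.na(tree$vertex))
  df <- data.frame(sample_id = tree$vlabels[tree$vertex[leaf_ids]],
                   module_path = paths[tree$parent[leaf_ids]])
  df <- df[match(tree$vlabels, df$sample_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  stats::setNames(df[[2]], df[[1]])
}
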