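# Merging and combining operators on partitioning trees, with their
# locally computable entropy-difference (delta) functions.
#
# Merging replaces two sibling nodes by one node holding the union of
# their vertex sets, concatenating their child subtrees in order (a
# merged leaf first gains a singleton leaf child holding its vertex, so
# leaves always stay singletons). Combining inserts a new parent over two
# siblings, keeping both as intact substructure. Together they let the
# greedy build hierarchy: merges grow modules (newly absorbed members sit
# as leaf children and may re-group into submodules one level deeper in
# later merges), combines pair substructures without destroying them.

siblings_check <- function(tree, alpha, beta) {
  if (alpha == beta) stop("alpha and beta must be distinct nodes")
  ga <- tree$parent[alpha]; gb <- tree$parent[beta]
  if (ga == 0L || gb == 0L) stop("root cannot be merged or combined")
  if (ga != gb) stop("alpha and beta must be siblings")
  kids <- tree$children[[ga]]
  if (match(alpha, kids) > match(beta, kids))
    stop("alpha must precede beta in sibling order")
  ga
}

#' Merge two sibling nodes of a partitioning tree
#'
#' The first sibling absorbs the second: its vertex set becomes the union
#' and its child list becomes its own children followed by the second's
#' children (subtrees re-parented, listing order preserved); the second
#' sibling is deleted and later siblings shift one position left. A
#' sibling that is a leaf first gains a singleton leaf child holding its
#' vertex, so merging two singleton modules yields one module with two
#' leaf children, and a vertex newly absorbed into a structured module
#' sits as a leaf child that may re-group one level deeper in later
#' merges.
#'
#' @param tree a `partition_tree`.
#' @param alpha,beta node ids of two siblings with `alpha` before `beta`
#'   in sibling order.
#' @return the updated `partition_tree`; node ids above `beta` shift down
#'   by one (new nodes created by leaf promotion take the highest ids).
#' @export
apply_merge <- function(tree, alpha, beta) {
  gam <- siblings_check(tree, alpha, beta)
  parent <- tree$parent; children <- tree$children; vertex <- tree$vertex
  up <- promote_leaf(parent, children, vertex, alpha)
  up <- promote_leaf(up[[1]], up[[2]], up[[3]], beta)
  parent <- up[[1]]; children <- up[[2]]; vertex <- up[[3]]
  moved <- children[[beta]]
  parent[moved] <- alpha
  children[[alpha]] <- c(children[[alpha]], moved)
  children[[beta]] <- integer(0)
  children[[gam]] <- setdiff(children[[gam]], beta)
  dn <- drop_node(parent, children, vertex, beta)
  new_tree(dn[[1]], dn[[2]], dn[[3]], tree$vlabels)
}

# Give a leaf node a singleton leaf child holding its vertex, making it
# internal; returns the updated tree pieces as a list.
promote_leaf <- function(parent, children, vertex, node) {
  if (is.na(vertex[node])) return(list(parent, children, vertex))
  parent <- c(parent, node)
  vertex <- c(vertex, vertex[node])
  children <- c(children, list(integer(0)))
  vertex[node] <- NA_integer_
  children[[node]] <- length(parent)
  list(parent, children, vertex)
}

# Remove a node id, shifting all higher ids down by one.
drop_node <- function(parent, children, vertex, node) {
  shift <- function(v) ifelse(v > node, v - 1L, v)
  parent <- shift(parent[-node])
  vertex <- vertex[-node]
  children <- lapply(children[-node], shift)
  list(parent, children, vertex)
}

#' Combine two sibling nodes under a new parent
#'
#' Creates a new node whose vertex set is the union of the two siblings'
#' sets and whose children are the two siblings in their original order;
#' the new node takes the first sibling's position under the common
#' parent. Every node at or below the two siblings must have height < K
#' before insertion, so that no leaf ends up deeper than K.
#'
#' @inheritParams apply_merge
#' @param K the height bound of the tree being built.
#' @return the updated `partition_tree`; the new node has the highest id.
#' @export
apply_combine <- function(tree, alpha, beta, K) {
  gam <- siblings_check(tree, alpha, beta)
  h <- node_heights(tree)
  desc <- function(v) {
    out <- v; stack <- tree$children[[v]]
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      out <- c(out, x); stack <- c(stack, tree$children[[x]])
    }
    out
  }
  if (any(h[c(desc(alpha), desc(beta))] >= K))
    stop("combine would exceed K: a node at or below the pair has height >= K")
  parent <- tree$parent; children <- tree$children; vertex <- tree$vertex
  parent <- c(parent, gam)
  vertex <- c(vertex, NA_integer_)
  children <- c(children, list(c(alpha, beta)))
  xi <- length(parent)
  kids <- children[[gam]]
  kids[match(alpha, kids)] <- xi
  children[[gam]] <- setdiff(kids, beta)
  parent[c(alpha, beta)] <- xi
  new_tree(parent, children, vertex, tree$vlabels)
}

# Total weight of edges with one endpoint in each of two vertex-index sets.
cross_weight <- function(graph, set_a, set_b) {
  e <- graph$edges
  sum(e$w[(e$i %in% set_a & e$j %in% set_b) |
          (e$i %in% set_b & e$j %in% set_a)])
}

safe_log2 <- function(x) ifelse(x > 0, log2(x), 0)

# Child-cut sum used by the local merge delta: for a leaf this is its own
# volume (its future promoted child's cut); for an internal node the sum
# of its children's cuts.
child_cut_sum <- function(tree, st, node) {
  if (!is.na(tree$vertex[node])) st$V[node]
  else sum(st$g[tree$children[[node]]])
}

#' Entropy decrease of a merge or combine, computed locally
#'
#' Both deltas are "entropy before minus entropy after" (positive =
#' improvement) and are evaluated from local quantities only: the volumes
#' and cuts of the two siblings, their parent and their children, and the
#' cross weight w between the two vertex sets. With V_a, g_a the volume
#' and cut of node a, S_a its child-cut sum (V_a for a leaf, since its
#' promoted child's cut is its own volume), gamma the common parent,
#' V_xi = V_a + V_b and g_xi = g_a + g_b - 2w:
#'
#'   vol * Delta_merge = g_a log2(V_g/V_a) + g_b log2(V_g/V_b)
#'                     - g_xi log2(V_g/V_xi)
#'                     + S_a log2(V_a) + S_b log2(V_b)
#'                     - (S_a + S_b) log2(V_xi)
#'
#' (only the two siblings' cut terms and their children's parent-volume
#' references change), and
#'
#'   vol * Delta_combine = 2 w log2(V_g / V_xi)
#'
#' (combining only re-points the two siblings' cut terms at the new
#' parent and adds its cut term). Zero-volume terms contribute 0. Both
#' closed forms are regression-tested against full before/after
#' recomputation of the tree entropy.
#'
#' @inheritParams apply_merge
#' @param graph the `weighted_graph` the tree partitions.
#' @return entropy decrease in bits.
#' @export
delta_merge <- function(graph, tree, alpha, beta) {
  gam <- siblings_check(tree, alpha, beta)
  st <- node_stats(graph, tree)
  sets <- tree_vertex_sets(tree)
  w <- cross_weight(graph, sets[[alpha]], sets[[beta]])
  Vg <- st$V[gam]
  Va <- st$V[alpha]; Vb <- st$V[beta]
  ga <- st$g[alpha]; gb <- st$g[beta]
  Sa <- child_cut_sum(tree, st, alpha)
  Sb <- child_cut_sum(tree, st, beta)
  Vxi <- Va + Vb
  gxi <- ga + gb - 2 * w
  d <- ga * (safe_log2(Vg) - safe_log2(Va)) +
       gb * (safe_log2(Vg) - safe_log2(Vb)) -
       gxi * (safe_log2(Vg) - safe_log2(Vxi)) +
       Sa * safe_log2(Va) + Sb * safe_log2(Vb) -
       (Sa + Sb) * safe_log2(Vxi)
  d / graph$volume
}

#' @rdname delta_merge
#' @export
delta_combine <- function(graph, tree, alpha, beta) {
  gam <- siblings_check(tree, alpha, beta)
  st <- node_stats(graph, tree)
  sets <- tree_vertex_sets(tree)
  w <- cross_weight(graph, sets[[alpha]], sets[[beta]])
  Vxi <- st$V[alpha] + st$V[beta]
  if (w <= 0 || Vxi <= 0) return(0)
  2 * w * (safe_log2(st$V[gam]) - safe_log2(Vxi)) / graph$volume
}
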