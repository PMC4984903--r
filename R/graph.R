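# Weighted undirected graph container and one-dimensional structural
# entropy. The graph is stored as an edge table over integer vertex
# indices (i < j), with weighted degrees and total volume cached; every
# entropy formula downstream is driven by degrees, volumes and cuts.

#' Construct a weighted undirected graph
#'
#' Builds the sample-network container used by all entropy computations.
#' Vertices are identified by unique labels whose input order is the global
#' tie-breaking order everywhere in the package. Edge weights must be
#' strictly positive; self-loops and duplicate pairs are rejected.
#'
#' @param labels character vector of unique vertex labels, in input order.
#' @param edges data frame (or NULL for an edgeless graph) with columns
#'   `from`, `to` (labels or integer indices) and `weight` (positive reals).
#' @return an object of class `weighted_graph` with components `labels`,
#'   `edges` (integer columns `i`, `j` with `i < j`, numeric `w`),
#'   `degree` (weighted degree per vertex) and `volume` (sum of degrees).
#' @examples
#' g <- weighted_graph(c("a", "b", "c"),
#'                     data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                weight = 1))
#' g$degree   # 1 2 1
#' one_dim_entropy(g)  # 1.5 bits
#' @export
weighted_graph <- function(labels, edges = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("vertex labels must be unique")
  n <- length(labels)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  } else {
    from <- edges[[1]]; to <- edges[[2]]; w <- as.numeric(edges[[3]])
    i <- if (is.numeric(from)) as.integer(from) else match(as.character(from), labels)
    j <- if (is.numeric(to))   as.integer(to)   else match(as.character(to), labels)
    if (anyNA(i) || anyNA(j)) stop("edge endpoint not found among vertex labels")
    if (any(i < 1L | i > n | j < 1L | j > n)) stop("vertex index out of range")
    if (any(i == j)) stop("self-loops are not allowed")
    if (any(!is.finite(w)) || any(w <= 0))
      stop("edge weights must be strictly positive and finite")
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1) * n + hi
    if (anyDuplicated(key)) stop("duplicate edges (at most one edge per vertex pair)")
    ord <- order(lo, hi)
    edges <- data.frame(i = lo[ord], j = hi[ord], w = w[ord])
  }
  degree <- numeric(n)
  if (nrow(edges)) {
    acc <- tapply(c(edges$w, edges$w), c(edges$i, edges$j), sum)
    degree[as.integer(names(acc))] <- as.numeric(acc)
  }
  structure(list(labels = labels, edges = edges, degree = degree,
                 volume = sum(degree)),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d vertices, %d edges, volume %.4g\n",
              length(x$labels), nrow(x$edges), x$volume))
  invisible(x)
}

#' Read / write a weighted edge list
#'
#' Three-column tab-separated `source TAB target TAB weight`, one line per
#' undirected edge; an optional header line is detected when the third
#' field is non-numeric. Duplicate pairs (in either orientation) are
#' rejected.
#'
#' @param path file path.
#' @param labels optional vertex labels fixing vertex order; defaults to
#'   first-appearance order in the file.
#' @return `read_edgelist`: a `weighted_graph`.
#' @export
read_edgelist <- function(path, labels = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) != 3) stop("edge list must have exactly three tab-separated columns")
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 3])))) df <- df[-1, , drop = FALSE]
  w <- suppressWarnings(as.numeric(df[[3]]))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop(sprintf("non-numeric weight at data line %d", bad))
  }
  if (is.null(labels)) labels <- unique(c(rbind(df[[1]], df[[2]])))
  weighted_graph(labels, data.frame(from = df[[1]], to = df[[2]], weight = w))
}

#' @rdname read_edgelist
#' @param graph a `weighted_graph`.
#' @param header write a header line (default TRUE).
#' @return `write_edgelist`: invisibly, the path.
#' @export
write_edgelist <- function(graph, path, header = TRUE) {
  df <- data.frame(source = graph$labels[graph$edges$i],
                   target = graph$labels[graph$edges$j],
                   weight = graph$edges$w)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

# Adjacency list: for each vertex, integer vector of neighbour indices.
adjacency_list <- function(graph) {
  n <- length(graph$labels)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (nrow(graph$edges)) {
    sp1 <- split(graph$edges$j, factor(graph$edges$i, levels = seq_len(n)))
    sp2 <- split(graph$edges$i, factor(graph$edges$j, levels = seq_len(n)))
    for (v in seq_len(n)) adj[[v]] <- c(sp1[[v]], sp2[[v]])
  }
  adj
}

#' Connected components of a weighted graph
#'
#' @param graph a `weighted_graph`.
#' @return integer vector of component ids (1-based, in order of first
#'   vertex encountered).
#' @export
graph_components <- function(graph) {
  n <- length(graph$labels)
  adj <- adjacency_list(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Stationary distribution of the random walk on a weighted graph
#'
#' The stationary probability of each vertex is its weighted degree divided
#' by the graph volume.
#'
#' @param graph a `weighted_graph` with at least one edge.
#' @return numeric probability vector over vertices (sums to 1).
#' @export
stationary_distribution <- function(graph) {
  if (graph$volume <= 0) stop("degenerate graph: volume is zero (no edges)")
  graph$degree / graph$volume
}

#' One-dimensional structural entropy (positioning entropy)
#'
#' The average number of bits needed to locate the vertex reached by a
#' stationary random walk. For a connected graph this is the Shannon
#' entropy of the stationary distribution, -sum p_v log2 p_v with
#' p_v = d_v / vol. For a disconnected graph it is the volume-weighted
#' average of the component entropies; isolated vertices carry no volume
#' and contribute 0, and an edgeless graph has entropy 0 (no random walk
#' can occur).
#'
#' The paper-level displayed formula is reconstructed here from the
#' stationary-random-walk description; the reconstruction is pinned by the
#' regression tests against the explicit two-level partition form.
#'
#' @param graph a `weighted_graph`.
#' @return entropy in bits (non-negative).
#' @export
one_dim_entropy <- function(graph) {
  if (graph$volume <= 0) return(0)
  comp <- graph_components(graph)
  vol <- graph$volume
  cvol <- tapply(graph$degree, comp, sum)
  compvol <- as.numeric(cvol)[comp]          # volume of own component, per vertex
  keep <- graph$degree > 0
  # sum over vertices of (d/vol) log2(compvol/d): component-weighted average
  sum((graph$degree[keep] / vol) *
        (log2(compvol[keep]) - log2(graph$degree[keep])))
}
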