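# Fixture graphs and random generators shared across the suite.
# All fixtures are built in code; vertex input order is the global
# tie-breaking order, so labels are chosen deliberately.

path3 <- function() {
  weighted_graph(c("a", "b", "c"),
                 data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1))
}

complete_graph <- function(n, weight = 1) {
  pr <- utils::combn(n, 2)
  weighted_graph(letters[seq_len(n)],
                 data.frame(from = pr[1, ], to = pr[2, ], weight = weight))
}

# two unit triangles a,b,c and d,e,f joined by bridge c-d
bridged_triangles <- function() {
  weighted_graph(letters[1:6],
                 data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                            to   = c("b", "c", "c", "e", "f", "f", "d"),
                            weight = 1))
}

two_triangles <- function() {
  weighted_graph(letters[1:6],
                 data.frame(from = c("a", "a", "b", "d", "d", "e"),
                            to   = c("b", "c", "c", "e", "f", "f"),
                            weight = 1))
}

# triangle a,b,c with pendant d hanging off c
triangle_pendant <- function() {
  weighted_graph(letters[1:4],
                 data.frame(from = c("a", "a", "b", "c"),
                            to   = c("b", "c", "c", "d"),
                            weight = 1))
}

# Erdos-Renyi-ish random connected-ish weighted graph on n vertices.
random_graph <- function(n, p = 0.5, weighted = TRUE) {
  pr <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pr)) < p
  if (!any(keep)) keep[sample(ncol(pr), 1)] <- TRUE
  w <- if (weighted) stats::runif(sum(keep), 0.2, 2) else rep(1, sum(keep))
  weighted_graph(paste0("v", seq_len(n)),
                 data.frame(from = pr[1, keep], to = pr[2, keep], weight = w))
}

# Random partition of 1..n into at most kmax non-empty parts.
random_partition <- function(n, kmax = 4) {
  repeat {
    m <- sample.int(min(kmax, n), n, replace = TRUE)
    if (length(unique(m)) >= 1) break
  }
  sp <- split(seq_len(n), factor(m, levels = unique(m)))
  names(sp) <- NULL
  sp
}

# Random valid partitioning tree of height <= K for a graph: start from a
# random height-2 tree and apply a few random legal combines.
random_tree <- function(graph, K = 3, n_combine = 2) {
  tr <- tree_from_partition(graph, random_partition(length(graph$labels)))
  for (i in seq_len(n_combine)) {
    parents <- which(vapply(tr$children, length, 1L) >= 2)
    if (!length(parents)) break
    p <- sample(parents, 1)
    kids <- tr$children[[p]]
    ij <- sort(sample(length(kids), 2))
    tr2 <- tryCatch(apply_combine(tr, kids[ij[1]], kids[ij[2]], K),
                    error = function(e) NULL)
    if (!is.null(tr2)) tr <- tr2
  }
  tr
}

membership_of <- function(partition, n) {
  m <- integer(n)
  for (j in seq_along(partition)) m[partition[[j]]] <- j
  m
}
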