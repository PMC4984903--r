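# Greedy K-dimensional structural-entropy minimisation.
#
# The algorithm starts from the root-over-singletons tree and repeatedly
# applies the strictly improving operator (merge or combine) with the
# largest entropy decrease, taking candidates at the shallowest tree
# level first: sibling pairs directly under the root are consolidated
# before any re-grouping one level deeper is considered, which realises
# the "first-level sets only ever grow" behaviour of the K-level
# procedure (modules form first, then their members re-group into
# submodules inside them). Within a level, merges win delta ties against
# combines. Candidate pairs are sibling pairs connected by at least one
# edge (all sibling pairs are scanned only when no connected pair
# improves); remaining ties are broken lexicographically by (parent,
# sibling index, sibling index), so the run is deterministic given the
# input vertex order. For K = 2 this coincides with the plain
# merge-until-done greedy.
#
# Internally the tree lives in flat growable arrays (parent, ordered child
# lists, volume V, cut g, child-cut sum S, height h, subtree max height)
# and the candidate scan is vectorised over edges: each edge is charged to
# the sibling pair where its endpoints' root paths diverge, which yields
# every connected sibling pair at every level together with its cross
# weight in one pass.

#' Greedy K-dimensional structural-entropy minimisation
#'
#' Finds a height-K partitioning tree of low structural entropy with the
#' merge/combine greedy. Level 1 of the result gives the modules, level 2
#' (for K = 3) the submodules. Entropy strictly decreases at every applied
#' step, so the final entropy never exceeds the one-dimensional entropy.
#'
#' @param graph a `weighted_graph`.
#' @param K tree height, 2 (modules) or 3 (modules + submodules). Larger
#'   values run but are unsupported in practice (cost grows steeply).
#' @param trace record the per-step operator trace (default TRUE).
#' @return a `partition_tree` of uniform height K with attributes
#'   `entropy` (bits) and, if requested, `trace` (data frame with columns
#'   step, operator, delta, entropy).
#' @examples
#' sim <- planted_partition_graph(c(5, 5), p_in = 1, p_out = 0, seed = 1,
#'                                bridge = TRUE)
#' tr <- minimize_entropy(sim$graph, K = 2)
#' lengths(level_partition(tr, 1))  # the two planted cliques
#' @export
minimize_entropy <- function(graph, K = 2, trace = TRUE) {
  stopifnot(K >= 2)
  n <- length(graph$labels)
  if (graph$volume <= 0) {
    warning("degenerate graph (no edges): returning the trivial single-module tree")
    tr <- pad_to_height(tree_from_partition_degenerate(graph), K)
    attr(tr, "entropy") <- 0
    return(tr)
  }
  st <- greedy_state_init(graph, K)
  steps <- list()
  repeat {
    cand <- greedy_candidates(st)
    mv <- NULL; op <- NULL
    if (!is.null(cand) && nrow(cand)) {
      pd <- st$h[st$par[cand$alpha]]
      for (d in sort(unique(pd))) {   # shallowest level with an improvement
        sub <- cand[pd == d, , drop = FALSE]
        mv_m <- greedy_pick(st, sub, "merge")
        mv_c <- greedy_pick(st, sub, "combine")
        if (!is.null(mv_m) && (is.null(mv_c) || mv_m$delta >= mv_c$delta)) {
          mv <- mv_m; op <- 1
        } else if (!is.null(mv_c)) {
          mv <- mv_c; op <- 2
        }
        if (!is.null(mv)) break
      }
    }
    if (is.null(mv)) {                # disconnected-pair merge fallback
      mv <- greedy_pick(st, greedy_all_sibling_pairs(st, cand), "merge")
      op <- 1
    }
    if (is.null(mv)) break
    if (op == 1) greedy_apply_merge(st, mv) else greedy_apply_combine(st, mv)
    steps[[length(steps) + 1L]] <- c(op = op, delta = mv$delta, entropy = st$E)
  }
  tr <- greedy_export_tree(st, graph)
  tr <- pad_to_height(tr, K)
  attr(tr, "entropy") <- st$E
  if (trace && length(steps)) {
    m <- do.call(rbind, steps)
    attr(tr, "trace") <- data.frame(step = seq_len(nrow(m)),
                                    operator = c("merge", "combine")[m[, 1]],
                                    delta = m[, 2], entropy = m[, 3])
  } else if (trace) {
    attr(tr, "trace") <- data.frame(step = integer(0), operator = character(0),
                                    delta = numeric(0), entropy = numeric(0))
  }
  tr
}

tree_from_partition_degenerate <- function(graph) {
  n <- length(graph$labels)
  parent <- c(0L, 1L, rep(2L, n))
  children <- c(list(2L), list(seq_len(n) + 2L), rep(list(integer(0)), n))
  vertex <- c(NA_integer_, NA_integer_, seq_len(n))
  new_tree(parent, children, vertex, graph$labels)
}

# --- internal greedy state (environment, mutated in place) -------------

greedy_state_init <- function(graph, K) {
  n <- length(graph$labels)
  st <- new.env(parent = emptyenv())
  st$K <- K
  st$vol <- graph$volume
  st$ei <- graph$edges$i; st$ej <- graph$edges$j; st$ew <- graph$edges$w
  N <- n + 1L
  st$par <- c(0L, rep(1L, n))
  st$kids <- c(list(seq_len(n) + 1L), rep(list(integer(0)), n))
  st$vert <- c(NA_integer_, seq_len(n))
  st$h <- c(0L, rep(1L, n))
  st$sub <- c(1L, rep(1L, n))            # max height within subtree
  st$V <- c(graph$volume, graph$degree)
  st$g <- c(0, graph$degree)             # leaf cut = leaf volume = degree
  st$S <- c(graph$volume, graph$degree)  # child-cut sum; leaves: own volume
  st$alive <- rep(TRUE, N)
  st$spos <- c(0L, seq_len(n))           # position within parent's child list
  st$leafnode <- seq_len(n) + 1L
  d <- graph$degree
  pos <- d > 0
  st$E <- sum((d[pos] / st$vol) * (log2(st$vol) - log2(d[pos])))
  st
}

# Ancestor-at-depth matrix for all vertices: A[v, d] is the node at depth
# min(d, leaf depth) on the root path of v's leaf.
greedy_ancestors <- function(st) {
  leaf <- st$leafnode
  n <- length(leaf)
  h0 <- st$h[leaf]
  maxh <- max(h0)
  climb <- matrix(0L, nrow = maxh, ncol = n)  # climb[s, v]: (s-1)-th ancestor
  climb[1, ] <- leaf
  if (maxh > 1) for (s in 2:maxh) {
    prev <- climb[s - 1, ]
    up <- st$par[prev]
    climb[s, ] <- ifelse(up > 0L, up, prev)
  }
  A <- matrix(0L, nrow = n, ncol = maxh)
  for (d in seq_len(maxh)) {
    steps_up <- pmax(h0 - d, 0L)
    A[, d] <- climb[cbind(steps_up + 1L, seq_len(n))]
  }
  A
}

# Connected sibling pairs at every level, with cross weights: each edge is
# charged to the sibling pair where its endpoints' root paths diverge.
greedy_candidates <- function(st) {
  m <- length(st$ew)
  if (m == 0) return(NULL)
  A <- greedy_ancestors(st)
  D <- ncol(A)
  Ai <- A[st$ei, , drop = FALSE]
  Aj <- A[st$ej, , drop = FALSE]
  neq <- Ai != Aj
  lev <- rep(1L, m); done <- neq[, 1]
  if (D > 1) for (d in 2:D) {
    fresh <- !done & neq[, d]
    lev[fresh] <- d
    done <- done | neq[, d]
  }
  a <- Ai[cbind(seq_len(m), lev)]
  b <- Aj[cbind(seq_len(m), lev)]
  swap <- st$spos[a] > st$spos[b]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b)
  first <- !duplicated(key)
  w <- as.numeric(rowsum(st$ew, key)[unique(key), ])
  data.frame(alpha = a[first], beta = b[first], w = w)
}

greedy_merge_delta <- function(st, alpha, beta, w) {
  Vg <- st$V[st$par[alpha]]
  Va <- st$V[alpha]; Vb <- st$V[beta]
  ga <- st$g[alpha]; gb <- st$g[beta]
  Sa <- st$S[alpha]; Sb <- st$S[beta]
  Vxi <- Va + Vb
  gxi <- ga + gb - 2 * w
  l2 <- safe_log2
  (ga * (l2(Vg) - l2(Va)) + gb * (l2(Vg) - l2(Vb)) -
     gxi * (l2(Vg) - l2(Vxi)) +
     Sa * l2(Va) + Sb * l2(Vb) - (Sa + Sb) * l2(Vxi)) / st$vol
}

# Best strictly improving move of the given kind among the candidate
# pairs, or NULL.
greedy_pick <- function(st, cand, kind) {
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  if (kind == "merge") {
    ok <- st$h[cand$alpha] < st$K
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    delta <- greedy_merge_delta(st, cand$alpha, cand$beta, cand$w)
  } else {
    ok <- st$sub[cand$alpha] < st$K & st$sub[cand$beta] < st$K
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    Vg <- st$V[st$par[cand$alpha]]
    Vxi <- st$V[cand$alpha] + st$V[cand$beta]
    delta <- ifelse(cand$w > 0 & Vxi > 0,
                    2 * cand$w * (log2(Vg) - log2(Vxi)) / st$vol, 0)
  }
  imp <- delta > 1e-12          # strict improvement, guarded against noise
  if (!any(imp)) return(NULL)
  cand <- cand[imp, , drop = FALSE]; delta <- delta[imp]
  best <- delta >= max(delta) - 1e-12
  ord <- order(st$par[cand$alpha], st$spos[cand$alpha], st$spos[cand$beta])
  pick <- ord[best[ord]][1]
  list(alpha = cand$alpha[pick], beta = cand$beta[pick],
       w = cand$w[pick], delta = delta[pick])
}

# All sibling pairs (per parent), with cross weights taken from the
# connected-candidate table (0 when disconnected).
greedy_all_sibling_pairs <- function(st, cand) {
  parents <- which(st$alive & vapply(st$kids, length, 1L) >= 2 &
                     is.na(st$vert))
  rows <- list()
  wmap <- new.env(parent = emptyenv())
  if (!is.null(cand) && nrow(cand)) {
    for (r in seq_len(nrow(cand)))
      assign(paste(cand$alpha[r], cand$beta[r]), cand$w[r], envir = wmap)
  }
  for (p in parents) {
    kk <- st$kids[[p]]
    if (length(kk) > 60) next   # quadratic fallback only at small fan-out
    cmb <- utils::combn(kk, 2)
    for (c2 in seq_len(ncol(cmb))) {
      a <- cmb[1, c2]; b <- cmb[2, c2]
      key <- paste(a, b)
      w <- if (exists(key, envir = wmap, inherits = FALSE))
        get(key, envir = wmap) else 0
      rows[[length(rows) + 1L]] <- c(a, b, w)
    }
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  data.frame(alpha = as.integer(m[, 1]), beta = as.integer(m[, 2]),
             w = m[, 3])
}

greedy_new_node <- function(st) {
  id <- length(st$par) + 1L
  st$par[id] <- 0L
  st$kids[[id]] <- integer(0)
  st$vert[id] <- NA_integer_
  st$h[id] <- 0L; st$sub[id] <- 0L
  st$V[id] <- 0; st$g[id] <- 0; st$S[id] <- 0
  st$alive[id] <- TRUE; st$spos[id] <- 0L
  id
}

greedy_promote <- function(st, node) {
  if (is.na(st$vert[node])) return(invisible())
  nu <- greedy_new_node(st)
  st$par[nu] <- node
  st$vert[nu] <- st$vert[node]
  st$vert[node] <- NA_integer_
  st$kids[[node]] <- nu
  st$h[nu] <- st$h[node] + 1L
  st$sub[nu] <- st$h[nu]
  st$sub[node] <- st$h[nu]
  st$V[nu] <- st$V[node]; st$g[nu] <- st$V[node]; st$S[nu] <- st$V[node]
  st$spos[nu] <- 1L
  st$leafnode[st$vert[nu]] <- nu
  invisible()
}

greedy_apply_merge <- function(st, mv) {
  a <- mv$alpha; b <- mv$beta; w <- mv$w
  gam <- st$par[a]
  greedy_promote(st, a)
  greedy_promote(st, b)
  moved <- st$kids[[b]]
  base <- length(st$kids[[a]])
  st$par[moved] <- a
  st$spos[moved] <- base + seq_along(moved)
  st$kids[[a]] <- c(st$kids[[a]], moved)
  st$V[a] <- st$V[a] + st$V[b]
  st$g[a] <- st$g[a] + st$g[b] - 2 * w
  st$S[a] <- st$S[a] + st$S[b]
  st$sub[a] <- max(st$sub[a], st$sub[b])
  st$S[gam] <- st$S[gam] - 2 * w
  kk <- st$kids[[gam]]
  kk <- kk[kk != b]
  st$kids[[gam]] <- kk
  st$spos[kk] <- seq_along(kk)
  st$alive[b] <- FALSE
  st$kids[[b]] <- integer(0)
  st$E <- st$E - mv$delta
  greedy_refresh_sub(st, gam)
  invisible()
}

greedy_apply_combine <- function(st, mv) {
  a <- mv$alpha; b <- mv$beta; w <- mv$w
  gam <- st$par[a]
  xi <- greedy_new_node(st)
  st$par[xi] <- gam
  st$h[xi] <- st$h[gam] + 1L
  st$V[xi] <- st$V[a] + st$V[b]
  st$g[xi] <- st$g[a] + st$g[b] - 2 * w
  st$S[xi] <- st$g[a] + st$g[b]
  st$S[gam] <- st$S[gam] - 2 * w
  kk <- st$kids[[gam]]
  kk[match(a, kk)] <- xi
  kk <- kk[kk != b]
  st$kids[[gam]] <- kk
  st$spos[kk] <- seq_along(kk)
  st$par[c(a, b)] <- xi
  st$kids[[xi]] <- c(a, b)
  st$spos[a] <- 1L; st$spos[b] <- 2L
  # depths below the pair increase by one
  stack <- c(a, b)
  while (length(stack)) {
    x <- stack[[1]]; stack <- stack[-1]
    st$h[x] <- st$h[x] + 1L
    st$sub[x] <- st$sub[x] + 1L
    stack <- c(stack, st$kids[[x]])
  }
  st$sub[xi] <- max(st$sub[a], st$sub[b], st$h[xi])
  st$E <- st$E - mv$delta
  greedy_refresh_sub(st, gam)
  invisible()
}

# Walk from the operation's parent to the root, refreshing subtree max
# heights.
greedy_refresh_sub <- function(st, node) {
  while (node > 0L) {
    kk <- st$kids[[node]]
    st$sub[node] <- if (length(kk)) max(st$sub[kk]) else st$h[node]
    node <- st$par[node]
  }
  invisible()
}

greedy_export_tree <- function(st, graph) {
  remap <- integer(length(st$par))
  # renumber in preorder for stable, readable node ids
  order_out <- integer(0)
  stack <- 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    order_out <- c(order_out, v)
    stack <- c(st$kids[[v]], stack)
  }
  remap[order_out] <- seq_along(order_out)
  N <- length(order_out)
  parent <- integer(N); children <- vector("list", N); vertex <- rep(NA_integer_, N)
  for (v in order_out) {
    nv <- remap[v]
    parent[nv] <- if (st$par[v] > 0L) remap[st$par[v]] else 0L
    children[[nv]] <- remap[st$kids[[v]]]
    vertex[nv] <- st$vert[v]
  }
  new_tree(parent, children, vertex, graph$labels)
}

# --- brute-force oracle ------------------------------------------------

#' Exact minimum two-level structural entropy by enumeration
#'
#' Enumerates every set partition of the vertices (restricted-growth
#' strings, so Bell(n) candidates) and evaluates the two-level entropy of
#' each; the test oracle for the greedy. Refuses n > 10.
#'
#' @param graph a `weighted_graph` with at most 10 vertices.
#' @return list with `partition` (list of vertex index vectors, first
#'   minimiser in enumeration order), `entropy` (bits) and `considered`
#'   (number of partitions enumerated).
#' @export
brute_force_min_partition <- function(graph) {
  n <- length(graph$labels)
  if (n > 10) stop("brute force refuses n > 10 (Bell-number enumeration)")
  if (graph$volume <= 0) stop("degenerate graph: volume is zero")
  d <- graph$degree; vol <- graph$volume
  ei <- graph$edges$i; ej <- graph$edges$j; ew <- graph$edges$w
  best <- Inf; best_m <- rep(1L, n); considered <- 0L
  a <- rep(1L, n)                      # restricted growth string, 1-based
  bmax <- c(1L, rep(2L, max(n - 1, 0)))  # bmax[i] = 1 + max(a[1..i-1])
  repeat {
    considered <- considered + 1L
    # two-level entropy of membership a
    Volj <- rowsum(d, a)
    within <- rowsum(ew * (a[ei] == a[ej]), a[ei])
    win <- numeric(nrow(Volj)); names(win) <- rownames(Volj)
    win[rownames(within)] <- within
    gj <- Volj[, 1] - 2 * win
    pos <- d > 0
    Hin <- sum((d[pos] / vol) * (log2(Volj[a, 1][pos]) - log2(d[pos])))
    vpos <- Volj[, 1] > 0
    Hcut <- sum((gj[vpos] / vol) * (log2(vol) - log2(Volj[vpos, 1])))
    H <- Hin + Hcut
    if (H < best - 1e-15) { best <- H; best_m <- a }
    # next restricted growth string
    i <- n
    while (i > 1L && a[i] >= bmax[i]) i <- i - 1L
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) {
      nb <- max(bmax[i], a[i] + 1L)
      a[(i + 1L):n] <- 1L
      bmax[(i + 1L):n] <- nb
    }
  }
  parts <- split(seq_len(n), factor(best_m, levels = unique(best_m)))
  names(parts) <- NULL
  list(partition = parts, entropy = best, considered = considered)
}
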