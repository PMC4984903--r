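# Merging / combining operators and their locally computable deltas.

test_that("apply_merge follows the re-grouping semantics", {
  g <- weighted_graph(c("a", "b", "c"),
                      data.frame(from = c("a", "b", "a"),
                                 to = c("b", "c", "c"), weight = 1))
  tr <- singleton_tree(g)             # root 1, leaves 2,3,4 (a,b,c)
  m1 <- apply_merge(tr, 2, 3)         # merge singleton modules {a},{b}
  expect_equal(sum(is.na(m1$vertex)), 2)   # root + one module node
  mod <- setdiff(which(is.na(m1$vertex)), 1)
  expect_equal(length(m1$children[[mod]]), 2)
  expect_equal(sort(m1$vlabels[m1$vertex[m1$children[[mod]]]]), c("a", "b"))
  # child list order: alpha's children then beta's children
  m2 <- apply_merge(m1, m1$children[[1]][1], m1$children[[1]][2])
  mod2 <- m2$children[[1]][1]
  expect_equal(m2$vlabels[m2$vertex[m2$children[[mod2]]]], c("a", "b", "c"))
  # later siblings shift left but keep their subtree
  g4 <- weighted_graph(letters[1:4],
                       data.frame(from = c("a", "b", "c"),
                                  to = c("b", "c", "d"), weight = 1))
  t4 <- singleton_tree(g4)
  m3 <- apply_merge(t4, 2, 3)
  expect_equal(length(t4$children[[1]]), 4)
  expect_equal(length(m3$children[[1]]), 3)
  # the last root child still holds vertex d
  last <- m3$children[[1]][3]
  expect_equal(m3$vlabels[m3$vertex[last]], "d")
  expect_error(apply_merge(t4, 3, 2), "precede")
  expect_error(apply_merge(t4, 1, 2), "root")
})

test_that("apply_combine keeps both substructures and enforces K", {
  g <- weighted_graph(letters[1:4],
                      data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "d"), weight = 1))
  tr <- singleton_tree(g)
  c1 <- apply_combine(tr, 2, 3, K = 2)   # two singleton leaves
  xi <- c1$children[[1]][1]
  expect_equal(sort(c1$vlabels[c1$vertex[c1$children[[xi]]]]), c("a", "b"))
  # multi-leaf modules under the root at K = 3: subtypes kept within
  t2 <- tree_from_partition(g, list(c("a", "b"), c("c", "d")))
  c2 <- apply_combine(t2, 2, 3, K = 3)
  xi2 <- c2$children[[1]][1]
  expect_equal(length(c2$children[[xi2]]), 2)
  expect_true(all(is.na(c2$vertex[c2$children[[xi2]]])))
  # below an already-height-K subtree the combine is rejected
  expect_error(apply_combine(t2, 2, 3, K = 2), "exceed K")
  validate_tree(c2, g)
})

test_that("delta_merge worked example: triangle with pendant", {
  g <- triangle_pendant()
  tr <- singleton_tree(g)             # leaves 2..5 = a..d
  expect_equal(delta_merge(g, tr, 2, 3), 0.25, tolerance = 1e-9)
  # matches full before/after recomputation (1.9056 - 1.6556)
  expect_equal(tree_entropy(g, tr), 1.905639, tolerance = 1e-6)
  after <- apply_merge(tr, 2, 3)
  expect_equal(tree_entropy(g, after), 1.655639, tolerance = 1e-6)
})

test_that("local deltas equal global recomputation on random instances", {
  set.seed(31)
  n_checked_m <- 0; n_checked_c <- 0
  while (n_checked_m < 60 || n_checked_c < 60) {
    g <- random_graph(sample(5:10, 1))
    tr <- random_tree(g, K = 3)
    parents <- which(vapply(tr$children, length, 1L) >= 2)
    if (!length(parents)) next
    p <- sample(parents, 1)
    kids <- tr$children[[p]]
    ij <- sort(sample(length(kids), 2))
    a <- kids[ij[1]]; b <- kids[ij[2]]
    E0 <- tree_entropy(g, tr)
    if (n_checked_m < 60) {
      d_local <- delta_merge(g, tr, a, b)
      d_global <- E0 - tree_entropy(g, apply_merge(tr, a, b))
      expect_equal(d_local, d_global, tolerance = 1e-9)
      n_checked_m <- n_checked_m + 1
    }
    comb <- tryCatch(apply_combine(tr, a, b, K = 4), error = function(e) NULL)
    if (!is.null(comb) && n_checked_c < 60) {
      d_local <- delta_combine(g, tr, a, b)
      d_global <- E0 - tree_entropy(g, comb)
      expect_equal(d_local, d_global, tolerance = 1e-9)
      n_checked_c <- n_checked_c + 1
    }
  }
})

test_that("degenerate deltas: zero-volume and whole-set unions", {
  # merging two isolated-vertex modules changes nothing
  g <- weighted_graph(letters[1:4],
                      data.frame(from = "a", to = "b", weight = 2))
  tr <- singleton_tree(g)             # leaves 2..5; c,d isolated
  expect_equal(delta_merge(g, tr, 4, 5), 0)
  # combining two modules whose union is V with total cut 0
  g2 <- weighted_graph(letters[1:4],
                       data.frame(from = c("a", "c"), to = c("b", "d"),
                                  weight = 1))
  t2 <- tree_from_partition(g2, list(c("a", "b"), c("c", "d")))
  expect_equal(delta_combine(g2, t2, 2, 3), 0)
})
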