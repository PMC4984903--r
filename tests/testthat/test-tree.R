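# Partitioning trees, the two-level partition entropy and the general
# tree entropy, plus padding, level extraction and serialisation.

test_that("partition entropy: worked examples", {
  g <- bridged_triangles()
  # hand evaluation: module volumes 7/7 of 14, cuts 1/1
  expect_equal(partition_entropy(g, list(c("a", "b", "c"), c("d", "e", "f"))),
               1.699514, tolerance = 1e-6)
  # singleton and whole-set partitions both reduce to H1
  H1 <- one_dim_entropy(g)
  expect_equal(partition_entropy(g, as.list(letters[1:6])), H1,
               tolerance = 1e-12)
  expect_equal(partition_entropy(g, list(letters[1:6])), H1,
               tolerance = 1e-12)
  expect_error(partition_entropy(g, list(c("a", "b"))), "cover")
})

test_that("tree entropy equals partition entropy on height-2 trees", {
  set.seed(21)
  for (i in 1:60) {
    g <- random_graph(sample(4:12, 1))
    P <- random_partition(length(g$labels))
    tr <- tree_from_partition(g, P)
    expect_equal(tree_entropy(g, tr), partition_entropy(g, P),
                 tolerance = 1e-9)
  }
})

test_that("unary padding never changes tree entropy", {
  set.seed(22)
  for (i in 1:20) {
    g <- random_graph(sample(4:9, 1))
    tr <- random_tree(g, K = 3)
    K <- tree_height(tr)
    padded <- pad_to_height(tr, K + sample(1:2, 1))
    expect_equal(tree_entropy(g, padded), tree_entropy(g, tr),
                 tolerance = 1e-12)
  }
  g <- path3()
  tr <- singleton_tree(g)
  expect_error(pad_to_height(tr, 0), "exceeds")
})

test_that("level_partition respects padding and covers all vertices", {
  g <- weighted_graph(c("a", "b", "c", "d"),
                      data.frame(from = c("a", "c"), to = c("b", "d"),
                                 weight = 1))
  tr <- tree_from_partition(g, list(c("a", "b"), c("c", "d")))
  # keep {c,d} together one level down: nodes 6,7 are its leaves
  tr2 <- apply_combine(tr, 6, 7, K = 3)
  l1 <- level_partition(pad_to_height(tr2, 3), 1)
  expect_equal(lapply(l1, function(i) sort(g$labels[i])),
               list(c("a", "b"), c("c", "d")), ignore_attr = TRUE)
  padded <- pad_to_height(tr2, 3)
  l2 <- level_partition(padded, 2)
  expect_equal(lapply(l2, function(i) sort(g$labels[i])),
               list("a", "b", c("c", "d")), ignore_attr = TRUE)
  expect_error(level_partition(tr, 5), "exceeds|pad")
  # deepest level: leaves are singletons covering V
  lK <- level_partition(pad_to_height(tr, 2), 2)
  expect_true(all(lengths(lK) == 1))
})

test_that("tree entropy is invariant under sibling permutation and rescaling", {
  set.seed(23)
  g <- random_graph(8)
  P <- random_partition(8, 3)
  tr <- tree_from_partition(g, P)
  trp <- tree_from_partition(g, rev(P))
  expect_equal(tree_entropy(g, trp), tree_entropy(g, tr), tolerance = 1e-12)
  g2 <- weighted_graph(g$labels, data.frame(from = g$edges$i, to = g$edges$j,
                                            weight = g$edges$w * 0.37))
  expect_equal(tree_entropy(g2, tr), tree_entropy(g, tr), tolerance = 1e-12)
})

test_that("tree JSON and partition table round-trip", {
  g <- bridged_triangles()
  tr <- pad_to_height(tree_from_partition(g, list(c("a", "b", "c"),
                                                  c("d", "e", "f"))), 2)
  f <- tempfile(fileext = ".json")
  write_tree_json(tr, f)
  tr2 <- read_tree_json(f, labels = g$labels)
  # node ids may be renumbered; structure, leaf paths and sibling order
  # must survive, and a second write is byte-identical
  leaf_paths <- function(t) {
    lv <- which(!is.na(t$vertex))
    stats::setNames(node_paths(t)[lv], t$vlabels[t$vertex[lv]])
  }
  expect_equal(leaf_paths(tr2)[g$labels], leaf_paths(tr)[g$labels])
  expect_equal(tree_entropy(g, tr2), tree_entropy(g, tr))
  f2 <- tempfile(fileext = ".json")
  write_tree_json(tr2, f2)
  expect_identical(readLines(f2), readLines(f))
  fp <- tempfile(fileext = ".tsv")
  write_partition_tsv(tr, fp)
  asg <- read_partition_tsv(fp)
  expect_equal(unname(asg[c("a", "d")]), c("1", "2"))
  expect_equal(names(asg), g$labels)
})

test_that("validate_tree reports broken invariants", {
  g <- path3()
  tr <- singleton_tree(g)
  bad <- tr
  bad$vertex[4] <- 1L   # duplicate vertex
  expect_error(validate_tree(bad, g), "exactly once")
})
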