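# Normalisation, gene assignment, gene map and partition similarity.

test_that("normalise_gene: worked examples and postconditions", {
  expect_equal(normalise_gene(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(normalise_gene(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(normalise_gene(c(0, 0, 10)), c(-0.5, -0.5, 1))
  set.seed(61)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    v <- switch(sample(3, 1),
                rnorm(n, sd = sample(c(1e-6, 1, 1e4), 1)),
                rep(runif(1), n),
                rpois(n, 3))
    cc <- normalise_gene(v)
    expect_equal(mean(cc), 0, tolerance = 1e-12)
    expect_true(max(abs(cc)) %in% c(0, 1))
    expect_true(all(cc >= -1 & cc <= 1))
  }
})

test_that("group means and row-mean identity", {
  m <- rbind(g1 = c(0.5, 0.5, -0.5, -0.5), g2 = c(-1, 1, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  gm <- group_mean_expression(m, list(c("s1", "s2"), c("s3", "s4")))
  expect_equal(gm["g1", ], c(0.5, -0.5), ignore_attr = TRUE)
  expect_equal(gm["g2", ], c(0, 0), ignore_attr = TRUE)
  # singleton group mean equals the single value
  gm2 <- group_mean_expression(m, list("s1", c("s2", "s3", "s4")))
  expect_equal(gm2["g2", 1], -1, ignore_attr = TRUE)
  expect_error(group_mean_expression(m, list(character(0), colnames(m))),
               "empty|unknown")
  # size-weighted row mean of group means is 0 for coded rows
  set.seed(62)
  M <- normalise_matrix(matrix(rnorm(50 * 8), 50, 8,
                               dimnames = list(paste0("g", 1:50),
                                               paste0("s", 1:8))))
  P <- list(paste0("s", 1:3), paste0("s", 4:8))
  gmm <- group_mean_expression(M, P)
  wm <- (gmm[, 1] * 3 + gmm[, 2] * 5) / 8
  expect_equal(max(abs(wm)), 0, tolerance = 1e-12)
})

test_that("assign_genes: argmax blocks, tie to lowest index, ordered", {
  means <- rbind(a = c(0.9, -0.1, -0.2),
                 b = c(0.3, 0.8, 0.1),
                 c = c(0.8, 0.2, 0.0),
                 d = c(0.5, 0.5, 0.5))   # tie -> group 1
  asg <- assign_genes(means)
  expect_equal(asg$blocks[[1]], c(1L, 3L, 4L))  # 0.9 > 0.8 > 0.5
  expect_equal(asg$blocks[[2]], 2L)
  expect_equal(asg$blocks[[3]], integer(0))
  expect_equal(asg$table$gene_id, c("a", "c", "d", "b"))
  expect_equal(sort(unlist(asg$blocks)), 1:4)   # blocks partition genes
})

test_that("gene_map reorders into visible blocks on planted data", {
  sim <- synthetic_expression(groups = 3, samples_per_group = 8,
                              genes = 300, signal_per_group = 60, seed = 7)
  norm <- normalise_matrix(sim$expr)
  truthP <- split(colnames(sim$expr), sim$truth$membership)
  gm <- gene_map(norm, truthP)
  expect_s3_class(gm, "gene_map")
  expect_equal(dim(gm$matrix), dim(norm))
  expect_equal(sort(unlist(gm$gene_blocks)), sort(rownames(norm)))
  # >= 90% of each planted signal set lands in its group's block
  for (gr in 1:3) {
    expect_gte(mean(sim$truth$signal_genes[[gr]] %in% gm$gene_blocks[[gr]]),
               0.9)
  }
  # in-block mean exceeds off-block mean (block-diagonal pattern)
  rb <- c(0, gm$row_boundaries); cb <- c(0, gm$col_boundaries)
  inb <- c(); offb <- c()
  for (i in 1:3) for (j in 1:3) {
    blk <- gm$matrix[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    if (i == j) inb <- c(inb, mean(blk)) else offb <- c(offb, mean(blk))
  }
  expect_gt(min(inb), max(offb))
  # single group: one block holding every gene
  gm1 <- gene_map(norm, list(colnames(norm)))
  expect_equal(length(gm1$gene_blocks), 1)
  expect_equal(length(gm1$gene_blocks[[1]]), nrow(norm))
})

test_that("gene_map on a padded tree matches the direct partition", {
  sim <- synthetic_expression(groups = 2, samples_per_group = 6,
                              genes = 120, signal_per_group = 30, seed = 8)
  norm <- normalise_matrix(sim$expr)
  net <- build_network(sim$expr, k = 5)
  tr <- minimize_entropy(net$graph, K = 2)
  lp <- lapply(level_partition(tr, 1), function(i) tr$vlabels[i])
  gm_tree <- gene_map(norm, tr, level = 1)
  gm_part <- gene_map(norm, lp)
  expect_equal(gm_tree$matrix, gm_part$matrix)
  expect_equal(gm_tree$gene_blocks, gm_part$gene_blocks)
})

test_that("set and partition similarity", {
  expect_equal(set_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(set_similarity(c("a"), c("b")), 0)
  expect_equal(set_similarity(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(set_similarity(c("a", "b"), c("b", "c"), metric = "recall"),
               1 / 2)
  expect_warning(z <- set_similarity(character(0), character(0)), "empty")
  expect_equal(z, 0)

  P <- list(letters[1:3], letters[4:6])
  st <- partition_similarity(P, P)
  expect_equal(st$scores$score, c(1, 1))
  expect_equal(st$weighted_average, 1)
  # all singletons vs one class of size n
  found <- as.list(letters[1:5])
  truth <- list(letters[1:5])
  st2 <- partition_similarity(found, truth)
  expect_equal(st2$scores$score, 1 / 5)
  expect_error(partition_similarity(list(c("a", "b")), list(c("a", "z"))),
               "universes differ")
  # named membership vectors are accepted
  fm <- stats::setNames(c(1, 1, 2, 2), letters[1:4])
  tm <- stats::setNames(c("x", "x", "y", "y"), letters[1:4])
  st3 <- partition_similarity(fm, tm)
  expect_equal(st3$weighted_average, 1)
})
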