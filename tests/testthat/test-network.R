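# Sample-network construction: Pearson weights, noise amplification,
# top-k retention and the entropy-curve k-chooser.

toy_expr <- function() {
  expression_matrix(rbind(c(1, 2, 3), c(2, 4, 1), c(5, 1, 2), c(1, 3, 4)),
                    paste0("g", 1:4), c("s1", "s2", "s3"))
}

test_that("pearson_weights matches direct correlation and validates", {
  e <- expression_matrix(cbind(a = c(1, 2, 3), b = c(1, 2, 3),
                               c = c(3, 2, 1), d = c(1, 2, 4)),
                         paste0("g", 1:3))
  W <- pearson_weights(e)
  expect_true(all(is.na(diag(W))))
  expect_equal(W["a", "b"], 1)
  expect_equal(W["a", "c"], -1)
  expect_equal(W["a", "d"], 0.9819805, tolerance = 1e-6)
  e0 <- expression_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3),
                                c = c(2, 1, 3)), paste0("g", 1:3))
  expect_error(pearson_weights(e0), "zero-variance.*a")
})

test_that("amplify implements the modifier conventions", {
  set.seed(51)
  W <- matrix(runif(38 * 38, -0.2, 0.9), 38, 38)
  W <- (W + t(W)) / 2; diag(W) <- NA
  a <- amplify(W)
  expect_equal(a$modifier, 1 / 37)     # n = 38 < 1000
  expect_equal(a$weights[2, 5], W[2, 5] + 1 / 37)
  a2 <- amplify(W, sigma = 0.5)
  expect_equal(a2$modifier, 0.5 * mean(W[upper.tri(W)]))
  a3 <- amplify(W, modifier = 0)
  expect_equal(a3$weights[upper.tri(W)], W[upper.tri(W)])
  # large n uses 1/n
  Wbig <- matrix(0.5, 1200, 1200); diag(Wbig) <- NA
  expect_equal(amplify(Wbig)$modifier, 1 / 1200)
})

test_that("topk_graph: retention, symmetrisation and tie order", {
  # n = 3, k = 2 keeps every pair
  W <- pearson_weights(toy_expr())
  g <- topk_graph(W, 2)
  expect_equal(nrow(g$edges), sum(W[upper.tri(W)] > 0))
  # two perfectly-correlated twin pairs, k = 1 -> two disjoint edges
  e <- expression_matrix(cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                               c = c(4, 3, 2, 1), d = c(8, 6, 4, 2)),
                         paste0("g", 1:4))
  W2 <- pearson_weights(e)
  g2 <- topk_graph(W2, 1)
  expect_equal(nrow(g2$edges), 2)
  expect_setequal(paste(g2$labels[g2$edges$i], g2$labels[g2$edges$j]),
                  c("a b", "c d"))
  # ties on the k-th weight break by sample input order
  Wt <- matrix(0.5, 4, 4); diag(Wt) <- NA
  gt <- topk_graph(Wt, 1, labels = letters[1:4])
  expect_true(all(gt$edges$i == 1 | gt$edges$j == 1) == FALSE ||
                nrow(gt$edges) >= 2)
  expect_equal(gt$edges$i[1], 1L)  # first vertex selects the first other
  expect_error(topk_graph(Wt, 4), "k must be")
  # non-positive weights are dropped and counted
  Wn <- matrix(c(NA, 0.5, -0.2, 0.5, NA, 0.4, -0.2, 0.4, NA), 3, 3)
  gn <- topk_graph(Wn, 2, labels = letters[1:3])
  expect_equal(attr(gn, "dropped"), 1L)
})

test_that("stable points are strict interior local minima", {
  curve <- data.frame(k = 2:6, H = c(3.1, 2.9, 3.0, 2.7, 2.8),
                      stable = FALSE)
  curve$stable[2:4] <- curve$H[2:4] < curve$H[1:3] &
    curve$H[2:4] < curve$H[3:5]
  class(curve) <- c("entropy_curve", class(curve))
  expect_equal(curve$k[curve$stable], c(3L, 5L))
  expect_equal(select_k(curve), 5L)    # H = 2.7 < 2.9
  mono <- data.frame(k = 2:6, H = 5:1, stable = FALSE)
  class(mono) <- c("entropy_curve", class(mono))
  expect_warning(k <- select_k(mono), "no stable point")
  expect_equal(k, 6L)
})

test_that("entropy_curve computes H(k) of the top-k graph and flags minima", {
  sim <- synthetic_expression(groups = 2, samples_per_group = 6,
                              genes = 150, signal_per_group = 40, seed = 3)
  amp <- amplify(pearson_weights(sim$expr))
  cv <- entropy_curve(amp$weights, 2:11)
  expect_equal(cv$H[1], one_dim_entropy(topk_graph(amp$weights, 2)))
  expect_equal(cv$H[7], one_dim_entropy(topk_graph(amp$weights, 8)))
  interior <- 2:(nrow(cv) - 1)
  expect_equal(cv$stable[interior],
               cv$H[interior] < cv$H[interior - 1] &
                 cv$H[interior] < cv$H[interior + 1])
  expect_false(cv$stable[1] || cv$stable[nrow(cv)])
  # constant curve has no stable point (strict inequalities)
  cst <- data.frame(k = 2:5, H = rep(1, 4), stable = FALSE)
  class(cst) <- c("entropy_curve", class(cst))
  expect_warning(select_k(cst), "no stable point")
  expect_error(entropy_curve(amp$weights, integer(0)), "empty")
})

test_that("amplification never changes top-k neighbour sets", {
  set.seed(52)
  sim <- synthetic_expression(groups = 3, samples_per_group = 6,
                              genes = 200, signal_per_group = 50, seed = 9)
  W <- pearson_weights(sim$expr)
  amp <- amplify(W)
  for (k in c(2, 5, 9)) {
    g1 <- topk_graph(W, k)
    g2 <- topk_graph(amp$weights, k)
    expect_equal(g2$edges[, c("i", "j")], g1$edges[, c("i", "j")])
  }
  # edge set monotone non-decreasing in k
  keys <- function(g) paste(g$edges$i, g$edges$j)
  for (k in 2:8) {
    expect_true(all(keys(topk_graph(W, k)) %in% keys(topk_graph(W, k + 1))))
  }
})

test_that("build_network composes the pipeline and reports provenance", {
  sim <- synthetic_expression(seed = 4)
  net <- build_network(sim$expr)
  expect_s3_class(net, "sample_network")
  expect_false(net$report$k_forced)
  expect_true(net$report$k %in% net$report$stable_points)
  expect_equal(net$report$modifier, 1 / 35)
  # final network carries raw Pearson weights
  W <- pearson_weights(sim$expr)
  e1 <- net$graph$edges[1, ]
  expect_equal(e1$w, W[e1$i, e1$j])
  # forced k skips the chooser
  net2 <- build_network(sim$expr, k = 5)
  expect_true(net2$report$k_forced)
  expect_null(net2$report$curve)
  # determinism
  net3 <- build_network(sim$expr)
  expect_identical(net3$graph$edges, net$graph$edges)
  expect_identical(net3$report$k, net$report$k)
})
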