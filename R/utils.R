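# Internal numeric helpers shared across the entropy code.

# x * log2(x) with the entropy convention 0 * log2(0) = 0.
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# a * log2(a / b), 0 when a == 0 (b may then be 0 as well).
xlog2ratio <- function(a, b) {
  b <- rep_len(b, length(a))
  out <- numeric(length(a))
  pos <- a > 0
  out[pos] <- a[pos] * (log2(a[pos]) - log2(b[pos]))
  out
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' given as label vectors. 1 means identical partitions; values near 0 are
#' expected for unrelated labellings.
#'
#' @param x,y vectors of cluster labels of equal length.
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  n <- length(x)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_idx <- (sum_i + sum_j) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
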