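#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same elements,
#' computed from the contingency table under the permutation model
#' (Hubert–Arabie form). Identical partitions score 1; independent ones
#' score about 0; the index is symmetric in its arguments and can be
#' negative for systematically crossed partitions.
#'
#' @param p1,p2 Cluster label vectors of equal length (>= 2 elements); any
#'   atomic label type.
#' @return A scalar in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("Partitions must label the same elements.", call. = FALSE)
  }
  n <- length(p1)
  if (n < 2) stop("ARI needs at least two elements.", call. = FALSE)
  # contingency counts via tabulate (hot path: called once per bootstrap
  # replicate and Q)
  f1 <- match(p1, unique(p1))
  f2 <- match(p2, unique(p2))
  k2 <- max(f2)
  choose2 <- function(x) sum(x * (x - 1)) / 2
  sum_ij <- choose2(tabulate((f1 - 1L) * k2 + f2, max(f1) * k2))
  sum_a <- choose2(tabulate(f1, max(f1)))
  sum_b <- choose2(tabulate(f2, k2))
  total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}
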