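#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones. Used to quantify recovery of planted co-expression modules.
#'
#' @param a,b label vectors of equal length
#' @return numeric ARI
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
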