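#' Two-sided Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with a > b plus half the ties. With both
#' groups of size at most 8 the two-sided p-value is computed by exact
#' enumeration over all assignments of the pooled ranks (valid under ties);
#' otherwise the tie-corrected normal approximation is used. The exact
#' two-sided p is the probability, under the permutation null, of a U at
#' least as far from its mean as observed.
#'
#' @param a,b numeric vectors.
#' @param exact_max largest per-group size for which the exact enumeration
#'   is used (default 8).
#' @return list with `U` (statistic for group `a`), `p`, `method`.
#' @keywords internal
mann_whitney <- function(a, b, exact_max = 8L) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  list(U = U, p = min(1, p), method = method)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order preserved. `m` defaults to the number of
#' p-values but can be set to the size of the full test family.
#'
#' @param p_values p-values in \[0, 1\].
#' @param m number of tests in the family.
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(0.03, m = 10)   # 0.3
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  pmin(1, m * p_values)
}
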