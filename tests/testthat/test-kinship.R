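sim_genotypes <- function(n, n_snp, seed = 1) {
  set.seed(seed)
  p <- runif(n_snp, 0.05, 0.5)
  G <- matrix(rbinom(n * n_snp, 2L, rep(p, each = n)), nrow = n)
  rownames(G) <- sprintf("S%02d", seq_len(n))
  list(G = G, p = p)
}

test_that("duplicate samples give kinship exactly 0.5", {
  g <- sim_genotypes(1, 500, seed = 71)$G
  G <- rbind(g, g)
  rownames(G) <- c("A", "B")
  phi <- king_kinship(G)
  expect_identical(unname(phi["A", "B"]), 0.5)
  expect_identical(unname(diag(phi)), c(0.5, 0.5))
  expect_equal(phi, t(phi), ignore_attr = TRUE)
})

test_that("unrelated pairs estimate near zero; parent-offspring near 0.25", {
  sg <- sim_genotypes(4, 20000, seed = 72)
  phi <- king_kinship(sg$G)
  off <- phi[upper.tri(phi)]
  expect_true(all(abs(off) < 0.02))

  set.seed(73)
  p <- sg$p
  parent <- sg$G[1, ]
  transmitted <- rbinom(length(p), 1L, parent / 2)
  child <- transmitted + rbinom(length(p), 1L, p)
  G <- rbind(parent = parent, child = child)
  phi_po <- king_kinship(G)["parent", "child"]
  expect_gt(phi_po, 0.177); expect_lt(phi_po, 0.354)
})

test_that("kinship is invariant to SNP order and allele-label swaps", {
  sg <- sim_genotypes(5, 2000, seed = 74)
  phi <- king_kinship(sg$G)
  set.seed(75)
  perm <- sample(ncol(sg$G))
  expect_equal(king_kinship(sg$G[, perm]), phi)
  swapped <- sg$G
  flip <- seq(1, ncol(swapped), by = 2)
  swapped[, flip] <- 2L - swapped[, flip]
  expect_equal(king_kinship(swapped), phi)
})

test_that("SNP filters drop high-missingness and rare sites", {
  sg <- sim_genotypes(4, 3000, seed = 76)
  phi <- king_kinship(sg$G)
  junk_rare <- matrix(0L, 4, 300)            # MAF 0 -> filtered
  junk_miss <- matrix(NA_integer_, 4, 300)   # all missing -> filtered
  junk_miss[1, ] <- 1L
  G2 <- cbind(sg$G, junk_rare, junk_miss)
  expect_equal(king_kinship(G2), phi)
})

test_that("a pair without heterozygous sites is undefined", {
  G <- rbind(A = rep(c(0L, 2L), 50), B = rep(c(2L, 0L), 50))
  expect_warning(phi <- king_kinship(G), "undefined")
  expect_true(is.na(phi["A", "B"]))
})

test_that("carrier kinship comparison separates sibships from random carriers", {
  set.seed(77)
  n <- 40
  phi <- matrix(rnorm(n * n, 0, 0.005), n, n)
  phi <- (phi + t(phi)) / 2
  diag(phi) <- 0.5
  rownames(phi) <- colnames(phi) <- sprintf("S%02d", 1:n)
  class(phi) <- c("kinship_matrix", class(phi))
  rand <- kinship_compare(phi, sample(rownames(phi), 8))
  expect_gt(rand$p, 0.05)

  sib <- phi
  sib[1:4, 1:4] <- 0.25; diag(sib) <- 0.5
  cmp <- kinship_compare(sib, rownames(phi)[1:4])
  expect_gt(cmp$median_carrier, cmp$median_noncarrier)
  expect_error(kinship_compare(phi, rownames(phi)), "degenerate")
  expect_error(kinship_compare(phi, "S01"), ">= 2 carriers")
})

test_that("relative pruning removes one member of each close pair", {
  phi <- diag(0.5, 4)
  rownames(phi) <- colnames(phi) <- c("A", "B", "C", "D")
  phi["A", "B"] <- phi["B", "A"] <- 0.25
  phi["C", "D"] <- phi["D", "C"] <- 0.1
  kept <- prune_relatives(phi)
  expect_length(kept, 2)
  expect_true("A" %in% kept)     # ties drop the later-sorted id
  kept2 <- prune_relatives(phi, missingness = c(A = 0.05, B = 0.01,
                                                C = 0, D = 0.02))
  expect_true("B" %in% kept2 && !("A" %in% kept2))
})

test_that("2x2 association reproduces hand arithmetic and corrections", {
  null <- assoc_2x2(10, 10, 10, 10)
  expect_equal(null$or_hat, 1)
  expect_gt(null$p_raw, 0.95)

  res <- assoc_2x2(22, 5, 210, 150)
  expect_equal(res$or_hat, (22 * 150) / (5 * 210), tolerance = 1e-12)
  expect_equal(res$test, "chi2")
  expect_true(res$ci95[1] < res$or_hat && res$or_hat < res$ci95[2])

  zc <- assoc_2x2(1, 0, 10, 10)
  expect_equal(zc$test, "fisher")
  expect_true(is.finite(zc$or_hat))
  expect_equal(zc$or_hat, (1.5 * 10.5) / (0.5 * 10.5), tolerance = 1e-12)

  expect_error(assoc_2x2(0, 0, 5, 5), "zero margin")
})

test_that("2x2 p-values match exact enumeration and the Pearson formula", {
  for (a in c(0, 1, 3, 6)) for (b in c(0, 2, 6)) {
    for (c_ in c(1, 4, 6)) for (d in c(1, 5, 6)) {
      if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
      res <- assoc_2x2(a, b, c_, d)
      if (res$test == "fisher") {
        expect_equal(res$p_raw, fisher_enumeration_oracle(a, b, c_, d),
                     tolerance = 1e-9)
      } else {
        n <- a + b + c_ + d
        exp_tab <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
        chi <- sum((matrix(c(a, c_, b, d), 2) - exp_tab)^2 / exp_tab)
        expect_equal(res$p_raw, pchisq(chi, 1, lower.tail = FALSE),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("expected carrier cases and Bonferroni behave as printed", {
  e <- expected_carrier_cases(27, 0.60)
  expect_equal(e$expected, 16.2)
  expect_equal(e$expected_rounded, 16L)
  expect_equal(expected_carrier_cases(100, 0)$expected, 0)
  expect_equal(expected_carrier_cases(100, 0.5)$expected_rounded, 50L)

  expect_equal(bonferroni_adjust(0.005, m = 10), 0.05)
  expect_equal(bonferroni_adjust(c(0.2, 0.9)), c(0.4, 1.0))
  expect_equal(bonferroni_adjust(0.03, m = 10), 0.3)
})

test_that("minimum detectable frequency is monotone and matches the design", {
  f <- min_detectable_frequency(387, 0.60, or_target = 10)
  expect_gte(f, 0.015); expect_lte(f, 0.03)
  # antitone in n and in the target odds ratio
  grid_n <- c(200, 400, 800, 1600)
  fs <- vapply(grid_n, function(n)
    min_detectable_frequency(n, 0.6, 10), numeric(1))
  expect_true(all(diff(fs) < 0))
  grid_or <- c(3, 5, 10, 20)
  fo <- vapply(grid_or, function(or)
    min_detectable_frequency(400, 0.6, or), numeric(1))
  expect_true(all(diff(fo) < 0))
  # vanishing power requirement -> vanishing frequency threshold
  expect_lt(min_detectable_frequency(387, 0.6, 10, power = 0.01), f)
})

test_that("kinship-adjusted association degenerates to plain logistic when unrelated", {
  set.seed(78)
  n <- 150
  carrier <- rbinom(n, 1, 0.2)
  age <- runif(n, 20, 70)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * carrier + 0.01 * age))
  K <- diag(0.5, n)
  rownames(K) <- colnames(K) <- sprintf("S%03d", 1:n)
  res <- kinship_adjusted_assoc(y, carrier, age, sex, K)
  ref <- glm(y ~ carrier + age + I(sex == "M"), family = binomial())
  expect_equal(log(res$or_hat), unname(coef(ref)["carrier"]),
               tolerance = 1e-6)
  expect_equal(res$n_eigenvectors, 0L)
  expect_error(kinship_adjusted_assoc(y, rep(1, n), age, sex, K),
               "no variation")
})

test_that("kinship-adjusted association covers the true OR under sibship structure", {
  set.seed(79)
  n_fam <- 50; fam_size <- 4; n <- n_fam * fam_size
  K <- kronecker(diag(n_fam), matrix(0.25, fam_size, fam_size))
  diag(K) <- 0.5
  rownames(K) <- colnames(K) <- sprintf("S%03d", 1:n)
  fam <- rep(seq_len(n_fam), each = fam_size)
  cover <- replicate(100, {
    carrier_fam <- sample(n_fam, 12)
    carrier <- as.integer(fam %in% carrier_fam & runif(n) < 0.5)
    fam_eff <- rnorm(n_fam, 0, 0.5)[fam]
    y <- rbinom(n, 1, plogis(qlogis(0.3) + log(3) * carrier + fam_eff))
    if (sum(carrier) < 3 || var(y) == 0) return(NA)
    res <- kinship_adjusted_assoc(y, carrier, runif(n, 20, 60),
                                  sample(c("M", "F"), n, TRUE), K)
    res$ci95[1] <= 3 && 3 <= res$ci95[2]
  })
  expect_gte(mean(cover, na.rm = TRUE), 0.9)
})

test_that("separation triggers the penalized fallback", {
  set.seed(80)
  n <- 60
  carrier <- rep(c(1, 0), c(10, 50))
  y <- c(rep(1, 10), rbinom(50, 1, 0.4))   # carriers all cases: separation
  K <- diag(0.5, n)
  rownames(K) <- colnames(K) <- sprintf("S%03d", 1:n)
  res <- kinship_adjusted_assoc(y, carrier, runif(n, 20, 60),
                                sample(c("M", "F"), n, TRUE), K)
  expect_equal(res$test, "kinship_adjusted_firth")
  expect_true(is.finite(res$or_hat) && res$or_hat > 1)
})
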