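test_that("flanking SNP selection returns outward-ordered windows", {
  fx <- trace_fixture(n_haps = 2, n_snp = 200, locus_after = 100)
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 60)
  expect_length(w$upstream, 60)
  expect_length(w$downstream, 60)
  expect_false(w$truncated_5 || w$truncated_3)
  # outward ordering: first index is the SNP adjacent to the locus
  expect_equal(w$upstream[1], 100)
  expect_equal(w$upstream[60], 41)
  expect_equal(w$downstream[1], 101)

  # truncation near the chromosome edge
  fx2 <- trace_fixture(n_haps = 2, n_snp = 70, locus_after = 10)
  w2 <- select_flanking_snps(fx2$locus, fx2$haps, k_per_side = 60)
  expect_length(w2$upstream, 10)
  expect_true(w2$truncated_5)
  expect_false(w2$truncated_3)

  w3 <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 1)
  expect_length(w3$upstream, 1)

  edge <- list(chrom = "chr1", start = 1, end = 50)
  expect_error(select_flanking_snps(edge, fx$haps), "5'")
})

# plant mismatches (allele 1 against an all-zero reference) at outward
# window indices of the trace fixture
plant_into <- function(m, fx, hap, down_idx = integer(),
                       up_idx = integer()) {
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 100)
  m[hap, w$downstream[down_idx]] <- 1L
  m[hap, w$upstream[up_idx]] <- 1L
  m
}

plant <- function(fx, hap, down_idx = integer(), up_idx = integer()) {
  plant_into(fx$haps$alleles, fx, hap, down_idx, up_idx)
}

trace_breaks <- function(fx, m, rescue_len = 5) {
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 100)
  max_shared_haplotype(m, w, rescue_len = rescue_len,
                       reference = rep(0L, ncol(m)))$breaks
}

test_that("shared-haplotype extension applies the five-SNP rescue rule", {
  fx <- trace_fixture(n_haps = 3, n_snp = 60, locus_after = 15)
  # perfect sharing: censored at the window edge
  b <- trace_breaks(fx, fx$haps$alleles)
  expect_true(all(b$censored_3))
  expect_true(all(b$bp3 == 45))

  # isolated mismatch at SNP 7 followed by matches: rescued
  m <- plant(fx, 1, down_idx = 7)
  b <- trace_breaks(fx, m)
  expect_gt(b$bp3[1], 7)
  expect_true(b$censored_3[1])

  # mismatches at SNPs 7 and 9 (within the rescue span): stop at SNP 6
  m <- plant(fx, 1, down_idx = c(7, 9))
  b <- trace_breaks(fx, m)
  expect_equal(b$bp3[1], 6)
  expect_false(b$censored_3[1])

  # with rescue disabled the first mismatch terminates
  m <- plant(fx, 1, down_idx = 7)
  b <- trace_breaks(fx, m, rescue_len = 0)
  expect_equal(b$bp3[1], 6)

  # mismatch on the first flanking SNP, unrescued: breakpoint index 0
  m <- plant(fx, 2, down_idx = c(1, 3))
  b <- trace_breaks(fx, m)
  expect_equal(b$bp3[2], 0)

  # missing alleles never terminate the extension
  m <- fx$haps$alleles
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 100)
  m[3, w$downstream[2:12]] <- NA_integer_
  b <- trace_breaks(fx, m)
  expect_true(b$censored_3[3])
})

test_that("all-missing haplotypes are excluded with a warning", {
  fx <- trace_fixture(n_haps = 3, n_snp = 60, locus_after = 15)
  m <- fx$haps$alleles
  m[5, ] <- NA_integer_
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 20)
  expect_warning(res <- max_shared_haplotype(m, w, reference = rep(0L, 60)),
                 "all-missing")
  expect_equal(nrow(res$breaks), 5)
})

test_that("weighted mean shared length groups by breakpoint signature", {
  fx <- trace_fixture(n_haps = 4, n_snp = 80, locus_after = 30,
                      spacing = 1e5)
  map <- uniform_map(1e7)
  m <- fx$haps$alleles
  # haplotypes 1-3: breakpoints (up 2, down 4); haplotype 4: (up 5, down 10)
  for (h in 1:3) m <- plant_into(m, fx, h, up_idx = c(3, 4), down_idx = c(5, 6))
  m <- plant_into(m, fx, 4, up_idx = c(6, 7), down_idx = c(11, 12))
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 25)
  sh <- max_shared_haplotype(m[1:4, ], w, rescue_len = 0,
                             reference = rep(0L, 80))
  summ <- weighted_mean_length(sh, fx$haps, map)
  expect_equal(sort(summ$groups$weight), c(1, 3))
  # hand-computed lengths under the uniform 1 cM/Mb map
  g <- function(bp) (bp - 1) / 1e6
  len_up <- function(k) g(fx$locus$start) - g(fx$positions[30 - k + 1])
  len_down <- function(k) g(fx$positions[30 + k]) - g(fx$locus$end)
  l1 <- len_up(2) + len_down(4)
  l2 <- len_up(5) + len_down(10)
  expect_equal(summ$l_ave, ((3 * l1 + 1 * l2) / 4) / 100, tolerance = 1e-9)
  # with all-distinct breakpoints the weighted mean is the simple mean
  expect_equal(summ$l_ave, mean(summ$per_hap$total_cM) / 100,
               tolerance = 1e-12)
})

test_that("censored sides contribute the window extent; full censoring errors", {
  fx <- trace_fixture(n_haps = 2, n_snp = 60, locus_after = 15)
  map <- uniform_map(1e7)
  w <- select_flanking_snps(fx$locus, fx$haps, k_per_side = 10)
  m <- fx$haps$alleles
  m <- plant_into(m, fx, 1, up_idx = c(1, 2), down_idx = c(1, 2))
  sh <- max_shared_haplotype(m[1:2, ], w, rescue_len = 0,
                             reference = rep(0L, 60))
  expect_error(weighted_mean_length(
    max_shared_haplotype(fx$haps$alleles[1:2, ], w, rescue_len = 0,
                         reference = rep(0L, 60)), fx$haps, map),
    "censored")
  summ <- weighted_mean_length(sh, fx$haps, map)
  expect_equal(summ$censoring_fraction, 0.5)
  g <- function(bp) (bp - 1) / 1e6
  win_len <- (g(fx$positions[25]) - g(fx$locus$end)) +
    (g(fx$locus$start) - g(fx$positions[6]))
  expect_equal(summ$per_hap$total_cM[2], win_len, tolerance = 1e-9)
})

test_that("Gamma-method point estimate and CI follow the independence model", {
  expect_equal(estimate_age(0.02, 10)$tau_hat, 100)
  expect_equal(estimate_age(0.004, 10)$tau_hat, 500)
  est <- estimate_age(0.02, n_haplotypes = 10)
  expect_equal(est$ci,
               qgamma(c(0.025, 0.975), shape = 20) / (10 * 0.02),
               tolerance = 1e-12)
  # CI contains the point estimate; width shrinks with n
  expect_true(est$ci[1] <= est$tau_hat && est$tau_hat <= est$ci[2])
  wide <- diff(estimate_age(0.02, 10)$ci)
  narrow <- diff(estimate_age(0.02, 10000)$ci)
  expect_lt(narrow, wide / 10)
  # strictly antitone in l_ave
  taus <- vapply(seq(0.001, 0.1, length.out = 30),
                 function(l) estimate_age(l, 10)$tau_hat, numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_warning(estimate_age(0.02, 10, censoring_fraction = 0.3),
                 "censoring")
  expect_error(estimate_age(0.5, 10, region_span_M = 0.3), "span")
  expect_equal(estimate_age(0.02, 10,
                            years_per_generation = 28)$years, 2800)
})

test_that("age comparison matches exact and approximate references", {
  expect_equal(compare_ages(c(3, 1, 2), c(1, 2, 3))$p, 1.0)
  res <- compare_ages(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  set.seed(61)
  for (i in 1:20) {
    a <- runif(sample(2:8, 1)); b <- runif(sample(2:8, 1))
    expect_equal(compare_ages(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(20, 0.3)
    expect_equal(compare_ages(a, b)$p,
                 wilcox.test(a, b, exact = FALSE,
                             correct = FALSE)$p.value, tolerance = 1e-10)
  }
  expect_error(compare_ages(numeric(0), 1), "empty")
})

test_that("old loci separate from young loci in the rank comparison", {
  set.seed(62)
  hits <- replicate(30, {
    age_group <- function(tau, n_loci = 10, n_hap = 20) {
      vapply(seq_len(n_loci), function(i) {
        2 / mean(rgamma(n_hap, shape = 2, rate = tau))
      }, numeric(1))
    }
    compare_ages(age_group(1000), age_group(100))$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("age-abundance correlation behaves on trivial and null inputs", {
  ages <- c(100, 200, 300, 400)
  expect_equal(age_abundance_correlation(ages, 0.001 * ages)$r, 1)
  res <- age_abundance_correlation(ages, rev(ages) / 1000)
  expect_lt(res$r, 0)
  expect_error(age_abundance_correlation(ages, rep(0.1, 4)), "variance")
  set.seed(63)
  reps <- replicate(200, {
    r <- age_abundance_correlation(rnorm(20), rnorm(20))
    c(r$r, r$p)
  })
  expect_lt(mean(abs(reps[1, ])), 0.3)
  rate <- mean(reps[2, ] < 0.05)
  expect_gt(rate, 0.005); expect_lt(rate, 0.12)
})

test_that("dating pipeline recovers the simulated age and flags support", {
  cfg <- sim_config(seed = 64, n_samples = 50, n_carriers = 50,
                    tau_true = 100, snp_density = 100,
                    genotyping_error = 0)
  sim <- simulate_cohort(cfg)
  locus <- list(chrom = "chr1", start = sim$truth$cnv_interval[1],
                end = sim$truth$cnv_interval[2])
  fit <- date_rcnv(locus, sim$haps, sim$map,
                   carriers = sim$truth$carrier_ids, k_per_side = 1000)
  expect_true(fit$ci[1] <= 100 && 100 <= fit$ci[2])
  expect_equal(unname(coef(fit)), fit$tau_hat)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), fit$ci)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_haplotypes, 3))
  expect_true(all(sims > 0))
  # rate sensitivity band brackets the estimate
  expect_lt(fit$tau_sensitivity["lo"], fit$tau_hat)
  expect_gt(fit$tau_sensitivity["hi"], fit$tau_hat)
})

test_that("shared-background support separates IBD carriers from random haplotypes", {
  cfg <- sim_config(seed = 65, n_samples = 60, n_carriers = 30,
                    tau_true = 50, snp_density = 100, genotyping_error = 0)
  sim <- simulate_cohort(cfg)
  locus <- list(chrom = "chr1", start = sim$truth$cnv_interval[1],
                end = sim$truth$cnv_interval[2])
  w <- select_flanking_snps(locus, sim$haps, k_per_side = 50)
  carrier_rows <- paste0(sim$truth$carrier_ids, "|1")
  s_carrier <- share_support(sim$haps$alleles[carrier_rows, ], w)
  non <- setdiff(sim$haps$sample_ids, sim$truth$carrier_ids)
  s_random <- share_support(sim$haps$alleles[paste0(non, "|1"), ], w)
  expect_gt(s_carrier, 0.9)
  expect_lt(s_random, 0.5)
})
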