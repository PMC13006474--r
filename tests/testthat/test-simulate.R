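test_that("the generator is a deterministic function of its config", {
  cfg <- sim_config(seed = 101, n_samples = 30, n_carriers = 10)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$haps$alleles, s2$haps$alleles)
  expect_identical(s1$truth$breakpoints, s2$truth$breakpoints)
  expect_identical(as.data.frame(s1$phenotypes),
                   as.data.frame(s2$phenotypes))
  c1 <- emit_callsets(s1$truth, s1$haps, seed = 7)
  c2 <- emit_callsets(s2$truth, s2$haps, seed = 7)
  expect_identical(as.data.frame(c1$caller_a), as.data.frame(c2$caller_a))
})

test_that("tau = 0 transmits the founder haplotype unrecombined", {
  cfg <- sim_config(seed = 102, n_samples = 20, n_carriers = 8,
                    tau_true = 0, genotyping_error = 0)
  sim <- simulate_cohort(cfg)
  interior <- sim$haps$positions >= cfg$cnv_interval[1] &
    sim$haps$positions <= cfg$cnv_interval[2]
  for (s in sim$truth$carrier_ids) {
    hap <- sim$haps$alleles[paste0(s, "|1"), ]
    expect_identical(unname(hap[!interior]),
                     sim$truth$founder_haplotype[!interior])
    expect_true(all(is.na(hap[interior])))   # hemizygous deletion
  }
})

test_that("duplication carriers keep interior genotypes", {
  cfg <- sim_config(seed = 103, n_samples = 10, n_carriers = 4,
                    cnv_state = "duplication", genotyping_error = 0)
  sim <- simulate_cohort(cfg)
  interior <- sim$haps$positions >= cfg$cnv_interval[1] &
    sim$haps$positions <= cfg$cnv_interval[2]
  hap <- sim$haps$alleles[paste0(sim$truth$carrier_ids[1], "|1"), ]
  expect_false(anyNA(hap[interior]))
})

test_that("true breakpoints sit outside the CNV and average 1/tau Morgans", {
  cfg <- sim_config(seed = 104, n_samples = 1000, n_carriers = 1000,
                    tau_true = 100, snp_density = 5)
  sim <- simulate_cohort(cfg)
  bp <- sim$truth$breakpoints
  expect_true(all(bp$b5_pos <= cfg$cnv_interval[1]))
  expect_true(all(bp$b3_pos >= cfg$cnv_interval[2]))
  sides <- c(bp$d5_M, bp$d3_M)       # 2000 independent sides
  expect_lt(abs(mean(sides) - 0.01) / 0.01, 0.10)
})

test_that("star-genealogy total shared lengths are Gamma(2, tau)", {
  cfg <- sim_config(seed = 105, n_samples = 1000, n_carriers = 1000,
                    tau_true = 200, snp_density = 5)
  sim <- simulate_cohort(cfg)
  totals <- sim$truth$breakpoints$d5_M + sim$truth$breakpoints$d3_M
  ks <- suppressWarnings(ks.test(totals, pgamma, shape = 2, rate = 200))
  expect_gt(ks$p.value, 0.01)
})

test_that("tree genealogy produces correlated but valid shared lengths", {
  cfg <- sim_config(seed = 106, n_samples = 40, n_carriers = 20,
                    genealogy = "tree", snp_density = 10)
  sim <- simulate_cohort(cfg)
  bp <- sim$truth$breakpoints
  expect_true(all(bp$d5_M >= 0 & bp$d3_M >= 0))
  expect_equal(nrow(bp), 20)
})

test_that("a null phenotype model equalizes carrier and noncarrier prevalence", {
  cfg <- sim_config(seed = 107, n_samples = 10000, n_carriers = 2000,
                    tau_true = 500, snp_density = 0.2, region_length = 5e6,
                    cnv_interval = c(2e6, 2.5e6),
                    phenotype_model = list(baseline_prevalence = 0.4,
                                           carrier_odds_ratio = 1,
                                           other_diag_prevalence = 0.2))
  sim <- simulate_cohort(cfg)
  carrier <- sim$phenotypes$sample_id %in% sim$truth$carrier_ids
  p1 <- mean(sim$phenotypes$aud[carrier])
  p0 <- mean(sim$phenotypes$aud[!carrier])
  se <- sqrt(p0 * (1 - p0) * (1 / sum(carrier) + 1 / sum(!carrier)))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("the phenotype generator recovers the configured odds ratio", {
  cfg <- sim_config(seed = 108, n_samples = 50000, n_carriers = 5000,
                    tau_true = 500, snp_density = 0.2, region_length = 5e6,
                    cnv_interval = c(2e6, 2.5e6),
                    phenotype_model = list(baseline_prevalence = 0.3,
                                           carrier_odds_ratio = 3,
                                           other_diag_prevalence = 0.2))
  sim <- simulate_cohort(cfg)
  carrier <- as.integer(sim$phenotypes$sample_id %in% sim$truth$carrier_ids)
  fit <- glm(sim$phenotypes$aud ~ carrier, family = binomial())
  or_hat <- exp(coef(fit)["carrier"])
  expect_lt(abs(or_hat - 3) / 3, 0.10)
})

test_that("caller noise behaves at its limits", {
  cfg <- sim_config(seed = 109, n_samples = 30, n_carriers = 12)
  sim <- simulate_cohort(cfg)
  clean <- emit_callsets(sim$truth, sim$haps,
                         noise = list(jitter_sd = 0, fn_rate = 0,
                                      fp_rate = 0), seed = 1)
  expect_equal(nrow(clean$caller_a), 12)
  expect_true(all(clean$caller_a$start == sim$truth$cnv_interval[1]))
  expect_true(all(clean$caller_b$end == sim$truth$cnv_interval[2]))

  # caller B drops everything -> consensus is empty
  half <- list(
    caller_a = clean$caller_a,
    caller_b = emit_callsets(sim$truth, sim$haps,
                             noise = list(jitter_sd = 0, fn_rate = 1,
                                          fp_rate = 0), seed = 2)$caller_b)
  expect_equal(nrow(half$caller_b), 0)
  expect_equal(nrow(merge_consensus(half$caller_a, half$caller_b)), 0)
})

test_that("moderate jitter keeps paired calls above the 0.5 overlap rule", {
  # 100-probe CNV (500 kb at 200 SNPs/cM under 1 cM/Mb -> 5 kb spacing);
  # jitter_sd = 5 probe spacings
  cfg <- sim_config(seed = 110, n_samples = 100, n_carriers = 100,
                    snp_density = 200)
  sim <- simulate_cohort(cfg)
  ros <- unlist(lapply(1:10, function(s) {
    cs <- emit_callsets(sim$truth, sim$haps,
                        noise = list(jitter_sd = 25000, fn_rate = 0,
                                     fp_rate = 0), seed = s)
    a <- cs$caller_a[order(cs$caller_a$sample_id), ]
    b <- cs$caller_b[order(cs$caller_b$sample_id), ]
    reciprocal_overlap(a$start, a$end, b$start, b$end)
  }))
  expect_length(ros, 1000)
  expect_gt(mean(ros), 0.5)
})

test_that("a window too narrow for the expected breakpoints warns", {
  expect_warning(
    simulate_cohort(sim_config(seed = 111, n_samples = 10, n_carriers = 4,
                               tau_true = 5, region_length = 5e6,
                               cnv_interval = c(2e6, 2.5e6),
                               snp_density = 5)),
    "widen the region")
})
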