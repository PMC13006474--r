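# rcnvclock

Recurrent copy-number variants (rCNVs) in founder populations — CNVs seen
in many individuals on a single shared haplotype background — carry a
record of their own history: the ancestral haplotype flanking the variant
is whittled down by recombination at a rate proportional to its age.
`rcnvclock` implements the analysis chain for SNP-array CNV studies of such
cohorts:

1. **Dual-caller consensus** — merge two callers' segment calls per sample,
   keeping same-state pairs with ≥ 50% reciprocal overlap
   (`min(|a∩b|/|a|, |a∩b|/|b|)`), spanning ≥ 10 probes and ≥ 10 kb.
2. **rCNV detection** — single-linkage clustering of consensus calls
   across individuals into loci with carrier rosters, carrier frequencies,
   cross-population sharing and gene annotation.
3. **Coalescence dating** (the package core, `date_rcnv()`) — extract each
   carrier's maximum shared haplotype around the locus (extension stops at
   the first unrescued mismatch against a running-majority estimate of the
   ancestral haplotype; an isolated mismatch is "rescued" when the next
   five SNPs match), convert breakpoints to genetic lengths on a local
   recombination map, and estimate the age by the Gamma method: with
   *l*<sub>ave</sub> the weighted mean of per-haplotype total (5′ + 3′)
   shared lengths in Morgans,

   τ̂ = 2 / *l*<sub>ave</sub>,

   with confidence intervals from the independence model in which the
   total shared length over *n* haplotypes is Gamma(2*n*, τ) distributed.
4. **Kinship & association** — KING-robust kinship from SNP dosages,
   relative pruning, carrier–phenotype 2×2 tests (χ²/Fisher, Bonferroni),
   a kinship-eigenvector-adjusted logistic model, and the power-based
   minimum detectable carrier frequency.
5. **Burden** — per-individual CNV counts and gene loads with
   nonparametric case–control comparison.
6. **Synthetic cohorts** — `simulate_cohort()` generates a CNV-bearing
   founder haplotype transmitted τ generations under recombination against
   a genetic map, with genotyping error, two noisy caller outputs and
   binary phenotypes, so the whole chain is testable with known truth.

## Worked example

Simulate a 120-person cohort in which 30 individuals carry a 500 kb
deletion inherited from a founder 100 generations ago, run the chain, and
date the locus:

```r
library(rcnvclock)

cfg <- sim_config(seed = 42, n_samples = 120, n_carriers = 30,
                  tau_true = 100, snp_density = 100)
sim  <- simulate_cohort(cfg)
cs   <- emit_callsets(sim$truth, sim$haps, seed = 42)
cons <- merge_consensus(cs$caller_a, cs$caller_b)
summarize_calls(cons, 120)
#> CNV cohort summary: 28 events in 120 individuals (0.2 per person)
#>   deletions:    28 (100%)
#>   duplications: 0 (0%)
#>   mean size:    494 kb

loci <- group_recurrent(cons, cohort_size = 120)
top  <- loci[which.max(loci$carrier_count), ]
fit  <- date_rcnv(top, sim$haps, sim$map, carriers = top$carriers[[1]],
                  k_per_side = 1000)
summary(fit)
#> rCNV coalescence dating: chr1:12255001-12745000
#>   n = 28 carrier haplotypes, l_ave = 0.0168 M (1.68 cM)
#>   tau_hat = 118.9 generations (95% CI 89.8-152.0)
#>   ~3330 years at 28 years/generation
#>   rate sensitivity (+/-20%): tau in 99.1-148.7
#>   censoring fraction 0.00; shared-background support 0.82
#>   28 breakpoint-signature group(s); largest weight 1
```

Two callers found 28 of the 30 carriers concordantly (the rest were
false-negative dropouts); the carriers' shared haplotypes average 1.68 cM,
giving τ̂ = 2/0.0168 ≈ 119 generations, whose 95% interval covers the
simulated truth of 100. The carrier–phenotype table is tested directly:

```r
carrier <- sim$phenotypes$sample_id %in% top$carriers[[1]]
aud     <- sim$phenotypes$aud
assoc_2x2(sum(carrier & aud), sum(carrier & !aud),
          sum(!carrier & aud), sum(!carrier & !aud))
#> OR = 2.15 (95% CI 0.79-5.83), chi2 p = 0.127
```

`date_rcnv()` returns a classed fit: `coef()`, `confint()`, `simulate()`
(parametric bootstrap draws from the fitted Gamma model) and `plot()`
(shared-length histogram with the fitted density) all work on it.

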