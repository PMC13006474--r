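---
title: "Dating recurrent CNVs from shared haplotypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating recurrent CNVs from shared haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnvclock)
```

# The problem

In founder populations — cohorts descended from a small number of
ancestors, with limited subsequent immigration — individual copy-number
variants can reach carrier frequencies of several percent because a single
ancestral mutation drifted up, not because the event recurred. Such
recurrent CNVs (rCNVs) are recognizable by two signatures: concordant
breakpoints across carriers, and a shared flanking haplotype on which the
variant arose. The shared haplotype also dates the variant: each meiosis
gives recombination a chance to shorten the ancestral segment, so older
variants sit on shorter conserved flanks.

`rcnvclock` implements this chain — dual-caller consensus filtering,
clustering into rCNV loci, shared-haplotype extraction, Gamma-method age
estimation, kinship-aware association and burden statistics — together with
a synthetic cohort generator that provides ground truth for every stage.

# Consensus calling and rCNV loci

Array CNV calls are noisy, so calls are retained only when two independent
callers agree: same state (deletion/duplication), reciprocal overlap
$\min(|a\cap b|/|a|,\,|a\cap b|/|b|) \ge 0.5$, at least 10 probes, at
least 10 kb. Matching within a sample is greedy by descending overlap with
deterministic tie-breaks (leftmost start, then shortest call), each call
used at most once, which makes `merge_consensus(A, B)` symmetric in its
arguments. The consensus interval is the *intersection* of the matched
pair — the conservative choice, and the one that keeps the probe-count
filter meaningful; union and single-caller-priority endpoints are easy to
add but are not the default. When probe positions are available the
consensus probe count is recounted; otherwise it is the smaller caller
count scaled by the fraction of each call retained.

Consensus calls from different individuals are clustered into loci by
single-linkage on reciprocal overlap (`group_recurrent()`), after a
canonical sort so input order is irrelevant. The locus interval is the
coordinate-wise median of member endpoints, which is robust to breakpoint
jitter of a few probes. A locus with at least two distinct carriers is
recurrent. Because array platforms differ in probe content, the same
ancestral event can be printed at non-overlapping coordinates in two
cohorts while falling in one cytogenetic band; cross-population sharing
therefore defaults to the `band_or_overlap` rule, and the strict-overlap
rule is available when band labels are untrusted.

# The Gamma method

Let each of $n$ carrier haplotypes descend independently from the founder
haplotype $\tau$ generations ago (a star genealogy). On each side of the
CNV, the genetic distance to the nearest historical recombination is
exponential with rate $\tau$ (distances in Morgans), so the per-haplotype
total (5′ + 3′) shared length is Gamma(2, $\tau$) and the total over $n$
haplotypes is Gamma($2n$, $\tau$). With $l_{\text{ave}}$ the weighted mean
of per-haplotype totals,

$$\hat\tau = \frac{2}{l_{\text{ave}}}, \qquad
\text{CI} = \left(\frac{q_{\alpha/2}(2n)}{n\,l_{\text{ave}}},\,
\frac{q_{1-\alpha/2}(2n)}{n\,l_{\text{ave}}}\right),$$

where $q_p(k)$ is the unit-rate Gamma quantile. The CI follows from the
pivot $\tau \sum_i l_i \sim \Gamma(2n, 1)$; it always contains $\hat\tau$
and shrinks as $n^{-1/2}$. Haplotypes are grouped by identical (5′, 3′)
breakpoint signatures and groups are weighted by their haplotype counts;
algebraically this equals the simple mean of per-haplotype totals, but the
grouping is reported because breakpoint-sharing structure is itself
evidence of common descent. A side-wise grouping variant
(`side_grouping = TRUE`) sums the two sides' weighted means instead; the
default is per-haplotype totals, the scale on which
$E[l_{\text{ave}}] = 2/\tau$ holds exactly.

## Estimating the ancestral haplotype

Extension needs a reference. The founder haplotype is unobserved, so it is
estimated by majority vote — but a naive column-wise majority over all
carriers fails in an instructive way: at genetic distance $d$ from the
CNV, only $e^{-\tau d}$ of carriers still share the founder segment, so
beyond $d \approx \ln 2/\tau$ the vote is dominated by recombined
haplotypes and collapses to the *population's* modal alleles. The longest
shared segments — exactly the observations carrying the most information —
are then truncated at spurious mismatches, and $\hat\tau$ is biased upward
by tens of percent. `max_shared_haplotype()` therefore votes only among
haplotypes that are still unbroken at each SNP, scanning outward: shared
haplotypes are enriched for the founder alleles at every distance, so the
running majority tracks the founder far beyond the half-sharing point.
When fewer than two haplotypes remain unbroken the vote falls back to the
all-carrier majority (ties break to allele 0). A known founder haplotype
can be supplied directly via `reference=`.

## The rescue rule

A single discordant SNP inside an otherwise intact shared segment is more
likely a point mutation or genotyping error than a recombination. During
extension, a mismatch at position $p$ is forgiven iff the next five SNPs
(all remaining SNPs, near the window edge) match; rescued positions do not
terminate extension, and missing alleles never terminate (they are
match-neutral, defensible because post-QC array missingness is rare).
Disabling the rescue (`rescue_len = 0`) truncates segments at every
genotyping error; since errors arrive at a rate proportional to segment
length, the un-rescued estimator is biased upward — the package's test
suite demonstrates both the bias and the rescue's correction of it.

## Censoring and sensitivity

A haplotype with no unrescued mismatch inside the window is censored on
that side and contributes the window's genetic extent as a lower bound.
The estimator warns when more than 20% of haplotypes are censored, since
$\hat\tau$ is then biased downward and the window should be widened. The
confidence interval reflects shared-length sampling only; recombination-map
uncertainty is reported separately as a ±20% rate sensitivity band
($\hat\tau/(1\pm0.2)$), since no closed form combines the two without a
model of map error. Years are reported as $\hat\tau \times 28$ by default;
the generation time is configurable and no particular calendar claim is
built in. When a kinship matrix is supplied, `date_rcnv()` first prunes
pairs with $\phi \ge 2^{-7/2} \approx 0.0884$ (second-degree cutoff),
dropping the member with more missingness, because first- and
second-degree relatives share flanks through recent pedigree descent
rather than through the variant's age.

# Kinship and association

`king_kinship()` implements the KING-robust between-family estimator
$\hat\phi_{ij} = (N_{Aa,Aa} - 2N_{AA,aa})/(N^{(i)}_{Aa} + N^{(j)}_{Aa})$
over pairwise-complete sites, after dropping SNPs with missing rate
> 0.1 or MAF < 0.01. It is exact at 0.5 for duplicates, invariant to SNP
order and allele-label swaps, and robust to population structure.

`assoc_2x2()` forms the carrier × case table: OR with Haldane–Anscombe 0.5
correction on any zero cell, Woolf log-OR Wald 95% CI, and a Pearson χ²
p-value when every expected cell exceeds 5 (the test's validity
condition), otherwise Fisher's exact test — the test used is recorded.
Bonferroni adjustment is $\min(1, m\,p)$ within each test family.

A full logistic mixed model with a dense kinship random effect is not
attempted. `kinship_adjusted_assoc()` instead adds the leading
eigenvectors of the kinship matrix (diagonal removed; enough to capture
80% of off-diagonal variance, at most 10) as fixed effects to a logistic
regression with age and sex — a standard spectral approximation whose
limiting case (no relatedness) is exactly plain logistic regression. On
separation it falls back to Firth-penalized logistic regression
(Jeffreys-prior IRLS), flagged in the result. Numeric equality with a
mixed-model fit on any particular real dataset is not claimed.

## Power-based frequency threshold

`min_detectable_frequency()` returns the smallest carrier frequency at
which a two-sided Wald test on the log OR reaches target power. The
carrier and noncarrier case rates are chosen to preserve the overall case
fraction at the target OR; the critical value uses the log-OR variance at
the null (same margins) and the power is evaluated under the
alternative-variance normal — the classical case-control sample-size
formulation. A pure alternative-variance formulation was considered and
rejected: it is far more conservative (roughly doubling the threshold for
a design of ~400 samples at OR 10) and does not correspond to how such
thresholds are conventionally derived. Power is not monotone in carrier
frequency over (0, 1) — it falls again as noncarriers vanish — so the
search brackets the rising flank on a coarse grid before bisecting to
1e-4.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the estimator
assumes: a founder haplotype carrying one CNV, transmitted $\tau$
generations with recombination against a genetic map; per-SNP independent
background haplotypes drawn from site frequencies; per-allele genotyping
error; hemizygous (missing) interior genotypes on deletion haplotypes; two
caller outputs with breakpoint jitter snapped to probes, false negatives
and false positives; and a logistic phenotype model with a configurable
carrier odds ratio. Same config + seed gives bit-identical output.

Defaults describe a plausible founder-population study: 387 individuals,
27 carriers, $\tau = 100$ (founder variants in such cohorts are typically
hundreds of generations old), a 25 Mb region at a uniform 1 cM/Mb with 30
SNPs/cM (array-scale density around a 500 kb event), MAF ~ U(0.05, 0.5),
genotyping error 0.002, 5 kb caller jitter with 5% FN/FP rates, noncarrier
phenotype prevalence 0.60 with carrier OR 3.2, and 28 years per
generation.

What it deliberately does **not** emulate: background linkage
disequilibrium (the LD-free background is the conservative easy case for
shared-haplotype detection — real LD creates chance haplotype matches that
lengthen apparent sharing; an LD panel option is future work), sex
chromosomes, raw LRR/BAF intensities, and phasing error (haplotypes are
emitted phased; switch errors would shorten apparent sharing). Passing
tests on these simulations therefore validate the estimator under its own
model plus the listed nuisances, not under every property of real array
data. The `genealogy = "tree"` option replaces the star by a Kingman
coalescent (scaled to TMRCA $\tau$) with recombination accumulated along
shared branches, producing the correlated shared lengths that are the
independence assumption's known failure mode — useful for robustness
probes, not the default.

# Numerical and interface conventions

* Coordinates are 1-based inclusive bp everywhere internally; BED export
  converts to 0-based half-open at the boundary only. Genetic positions
  are cM at interfaces and Morgans inside the age math.
* Genetic-map interpolation is piecewise linear between knots;
  extrapolation beyond the terminal knots continues the terminal
  interval's rate. Plateaus (recombination deserts) are accepted; inverse
  lookup inside a plateau returns its left edge.
* Ties in consensus matching break by leftmost start then shortest call;
  clustering sorts canonically first; reference votes break to allele 0 —
  all outputs are deterministic functions of inputs.
* Degenerate inputs fail loudly: zero-margin tables, empty comparison
  groups, loci with no flanking SNPs on a side, maps with decreasing cM
  (named row), unphased genotypes in a phased VCF (named sample and site),
  fully censored shared-length summaries.

# Validation scales

The test suite validates the estimator at a fixed design: star genealogy,
$\tau = 100$, 50 carrier haplotypes, uniform 1 cM/Mb map, 100 SNPs/cM and
1000-SNP (10 cM) windows per side — chosen so that SNP discretization
(half a probe spacing, ~0.005 cM) and the chance-extension overshoot past
a true breakpoint (a few probes) are both small against the 1 cM mean
breakpoint distance. Over 100 replicate cohorts the median $\hat\tau$
falls within a few percent of truth and the empirical 95% CI coverage sits
near nominal; with genotyping error 0.005 the rescue rule roughly halves
the mean absolute error relative to rescue-disabled extension, which
overestimates in essentially every replicate. Statistical operations are
checked against independent oracles (exhaustive rank enumeration,
hypergeometric enumeration, brute-force probe counting) and the
association test's type-I error is verified at nominal level on null
simulations.

# Limitations

* The independence (star) assumption overstates the information in
  correlated lineages; under a deep tree genealogy the effective number of
  independent lineages is smaller and intervals are anti-conservative.
  Relative pruning mitigates the recent-pedigree part of this only.
* Ages are only as good as the map: local map error propagates directly
  into $\hat\tau$, which is why the rate band is reported.
* With narrow windows or very young variants most haplotypes censor and
  the estimate degrades to a lower bound; the censoring warning should be
  treated as a stop sign.
* The kinship-eigenvector association adjustment approximates, not
  reproduces, a mixed model; burden comparisons are unadjusted and
  explicitly exploratory.
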