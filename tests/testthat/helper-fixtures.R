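# Fixture builders shared across test files. Everything is generated in
# code; no data files.

random_callset <- function(n = 100, n_samples = 10, caller = "callerX",
                           seed = 1) {
  set.seed(seed)
  start <- sample.int(1e8, n)
  len <- sample.int(5e5, n) + 1e4
  cnv_calls(sample_id = sprintf("S%02d", sample.int(n_samples, n,
                                                    replace = TRUE)),
            chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
            start = start, end = start + len,
            copy_number = sample(c(0L, 1L, 3L, 4L), n, replace = TRUE),
            n_probes = sample(10:200, n, replace = TRUE),
            caller = caller)
}

# hap_set with fully controlled alleles: `rows` is a haplotype x SNP matrix
# (two rows per sample).
manual_hapset <- function(rows, positions = seq_len(ncol(rows))) {
  n_samp <- nrow(rows) / 2
  hap_set(rows, positions, sprintf("C%02d", seq_len(n_samp)))
}

# Carriers-only hap matrix for breakpoint rule tracing: a reference of all
# zeros over `n_snp` SNPs at positions 1..n_snp * spacing, a locus sitting
# between `locus_after` and `locus_after + 1` SNPs, and planted mismatch
# positions per haplotype (outward index on the downstream side).
trace_fixture <- function(n_haps = 4, n_snp = 40, locus_after = 10,
                          spacing = 1e5) {
  positions <- seq_len(n_snp) * spacing
  locus <- list(chrom = "chr1",
                start = positions[locus_after] + 1,
                end = positions[locus_after + 1] - 1)
  rows <- matrix(0L, nrow = 2 * n_haps, ncol = n_snp)
  haps <- manual_hapset(rows, positions)
  list(haps = haps, locus = locus, positions = positions)
}

uniform_map <- function(length_bp = 1e7, rate = 1) {
  pos <- seq(0, length_bp, length.out = 11)
  genetic_map("chr1", pos + 1, pos * rate / 1e6)
}

# Independent Mann-Whitney oracle: exhaustive enumeration over all
# assignments of pooled ranks (handles ties), two-sided.
mw_enumeration_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  list(U = U_obs, p = mean(abs(us - mu) >= abs(U_obs - mu) - 1e-9))
}

# Exact Fisher p by direct hypergeometric enumeration (oracle independent
# of fisher.test).
fisher_enumeration_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
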