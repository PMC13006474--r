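#' Select flanking SNP windows around a locus
#'
#' Returns the `k_per_side` SNPs nearest the locus on each side, ordered
#' outward from the CNV (so index 1 is the SNP immediately adjacent to the
#' boundary). SNPs inside the locus are never included: dating uses flanking
#' information only, because the deleted haplotype carries no genotype
#' inside a deletion. When fewer than `k_per_side` SNPs are available on a
#' side, all of them are returned and the side is flagged truncated.
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`.
#' @param haps a [hap_set].
#' @param k_per_side SNPs to take on each side (default 60).
#' @return list of class `flank_windows`: `upstream`, `downstream` (column
#'   indices into `haps$alleles`, ordered outward), `truncated_5`,
#'   `truncated_3`, `locus`.
#' @export
select_flanking_snps <- function(locus, haps, k_per_side = 60L) {
  stopifnot(k_per_side >= 1)
  on_chrom <- haps$chrom == locus$chrom
  pos <- haps$positions
  left <- which(on_chrom & pos < locus$start)
  right <- which(on_chrom & pos > locus$end)
  if (length(left) == 0 || length(right) == 0) {
    stop("no flanking SNPs on the ",
         if (length(left) == 0) "5'" else "3'", " side of ", locus$chrom,
         ":", locus$start, "-", locus$end)
  }
  up <- rev(left)[seq_len(min(k_per_side, length(left)))]    # outward: high->low bp
  down <- right[seq_len(min(k_per_side, length(right)))]     # outward: low->high bp
  structure(list(upstream = up, downstream = down,
                 truncated_5 = length(left) < k_per_side,
                 truncated_3 = length(right) < k_per_side,
                 locus = list(chrom = locus$chrom, start = locus$start,
                              end = locus$end)),
            class = "flank_windows")
}

# Ancestral-haplotype estimate for one side: scanning outward, the
# reference allele at each SNP is the majority vote among carrier
# haplotypes that have matched the reference at every SNP so far ("still
# shared"). Haplotypes that have recombined onto the population background
# drop out of the vote at their first mismatch, so the reference tracks the
# founder haplotype well beyond the point where recombined carriers
# outnumber shared ones — where a plain column-wise majority over all
# carriers would decay to the population's modal alleles and truncate the
# longest shared segments. Once fewer than two haplotypes remain unbroken
# the vote falls back to the majority over all carriers. Missing alleles
# are excluded from votes; ties break to allele 0.
running_modal <- function(h) {
  n <- nrow(h); k <- ncol(h)
  ref <- integer(k)
  active <- rep(TRUE, n)
  for (j in seq_len(k)) {
    col <- h[, j]
    voters <- if (sum(active) >= 2L) col[active] else col
    cm <- mean(voters, na.rm = TRUE)
    ref[j] <- if (is.nan(cm)) 0L else as.integer(cm > 0.5)
    active <- active & (is.na(col) | col == ref[j])
  }
  ref
}

# Breakpoint scan for one side. m: logical matrix (haplotypes x window SNPs,
# ordered outward), TRUE = matches the reference (missing alleles are
# match-neutral and coded TRUE). Returns per haplotype the index of the last
# shared SNP (0 if the first SNP already mismatches unrescued) and a
# censored flag (no unrescued mismatch inside the window). A mismatch at
# position p is rescued iff the next `rescue_len` SNPs (all remaining ones,
# near the window edge) match; rescued positions do not stop the extension.
scan_breakpoints <- function(m, rescue_len = 5L) {
  k <- ncol(m)
  t(apply(m, 1, function(row) {
    mis <- which(!row)
    for (p in mis) {
      rescued <- rescue_len > 0L && p < k &&
        all(row[seq(p + 1L, min(k, p + rescue_len))])
      if (!rescued) return(c(p - 1L, 0L))
    }
    c(k, 1L)
  }))
}

#' Maximum shared haplotypes among rCNV carriers
#'
#' For each carrier haplotype, extends outward from the CNV boundary on each
#' side, comparing against a reference haplotype (by default the per-window
#' modal carrier haplotype, an estimate of the ancestral haplotype). The
#' haplotype's breakpoint on a side is the SNP before the first unrescued
#' mismatch: a mismatch is forgiven ("rescued") when the next `rescue_len`
#' SNPs all match, attributing the isolated mismatch to point mutation or
#' genotyping error rather than recombination. Missing alleles never
#' terminate the extension. A haplotype with no unrescued mismatch inside
#' the window is censored on that side and contributes the window's extent
#' as a lower bound.
#'
#' @param carrier_haps integer matrix of carrier haplotypes (rows) over all
#'   SNPs of `windows`' parent [hap_set] (columns), as from
#'   [sample_haplotypes()] or a [hap_set]'s `alleles`.
#' @param windows a [select_flanking_snps()] result.
#' @param rescue_len number of consecutive matches required to rescue a
#'   mismatch (default 5); `0` disables the rescue rule.
#' @param reference `"modal"` (default) compares every haplotype to a
#'   running-majority estimate of the ancestral haplotype (the majority
#'   allele among carrier haplotypes still unbroken at each SNP, scanning
#'   outward); or an integer vector of reference alleles over the full SNP
#'   set (e.g. a known founder haplotype).
#' @return list of class `shared_lengths`: per-haplotype data.frame
#'   `breaks` with `bp5`, `bp3` (outward SNP indices of the last shared
#'   SNP on each side; 0 when the first flanking SNP already mismatches) and
#'   `censored_5`, `censored_3`; plus `windows` and `rescue_len`.
#' @export
max_shared_haplotype <- function(carrier_haps, windows, rescue_len = 5L,
                                 reference = "modal") {
  if (nrow(carrier_haps) < 2) stop("need >= 2 carrier haplotypes")
  all_missing <- rowSums(!is.na(carrier_haps[, c(windows$upstream,
                                                 windows$downstream),
                                             drop = FALSE])) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing haplotype(s) excluded")
    carrier_haps <- carrier_haps[!all_missing, , drop = FALSE]
  }
  side <- function(idx) {
    h <- carrier_haps[, idx, drop = FALSE]
    ref <- if (identical(reference, "modal")) {
      running_modal(h)
    } else {
      reference[idx]
    }
    m <- sweep(h, 2, ref, `==`)
    m[is.na(m)] <- TRUE                       # missing: match-neutral
    scan_breakpoints(m, rescue_len)
  }
  b5 <- side(windows$upstream)
  b3 <- side(windows$downstream)
  breaks <- data.frame(
    hap_id = rownames(carrier_haps) %||% paste0("hap", seq_len(nrow(carrier_haps))),
    bp5 = as.integer(b5[, 1]), bp3 = as.integer(b3[, 1]),
    censored_5 = b5[, 2] == 1L, censored_3 = b3[, 2] == 1L,
    stringsAsFactors = FALSE)
  structure(list(breaks = breaks, windows = windows,
                 rescue_len = as.integer(rescue_len)),
            class = "shared_lengths")
}

#' Weighted mean shared genetic length
#'
#' Converts each haplotype's 5' and 3' breakpoints to genetic lengths
#' (distance in cM from the locus boundary to the last shared SNP,
#' interpolated on `map`), sums the two sides into a per-haplotype total,
#' groups haplotypes by identical (5', 3') breakpoint signature, and returns
#' the weighted average l_ave = sum(w_g * l_g) / sum(w_g) in Morgans, the
#' weights w_g being the number of haplotypes sharing the breakpoint pair.
#' Censored sides contribute the window's genetic extent as a lower bound.
#'
#' @param shared a [max_shared_haplotype()] result.
#' @param haps the [hap_set] the breakpoints were computed on.
#' @param map a [genetic_map].
#' @param side_grouping if `TRUE`, group and weight each side separately
#'   and sum the two sides' weighted means instead of grouping by the
#'   (5',3') pair.
#' @return list of class `shared_summary`: `per_hap` (hap_id, len5_cM,
#'   len3_cM, total_cM, censored flags), `groups` (signature, weight, total
#'   cM), `l_ave` (Morgans), `n_haplotypes`, `censoring_fraction`.
#' @export
weighted_mean_length <- function(shared, haps, map, side_grouping = FALSE) {
  w <- shared$windows
  b <- shared$breaks
  chrom <- w$locus$chrom
  g_start <- genetic_position(map, chrom, w$locus$start)
  g_end <- genetic_position(map, chrom, w$locus$end)
  len_side <- function(idx, win_idx, edge_g) {
    out <- numeric(length(idx))
    nz <- idx > 0
    pos <- haps$positions[win_idx]
    out[nz] <- abs(genetic_position(map, chrom, pos[idx[nz]]) - edge_g)
    out
  }
  len5 <- len_side(b$bp5, w$upstream, g_start)
  len3 <- len_side(b$bp3, w$downstream, g_end)
  per_hap <- data.frame(hap_id = b$hap_id, len5_cM = len5, len3_cM = len3,
                        total_cM = len5 + len3,
                        censored_5 = b$censored_5, censored_3 = b$censored_3,
                        stringsAsFactors = FALSE)
  if (all(per_hap$censored_5 & per_hap$censored_3)) {
    stop("all haplotypes censored on both sides: no recombination observed in the window")
  }
  if (side_grouping) {
    # weighting each side's breakpoint groups by their haplotype counts
    # reduces algebraically to the per-side mean
    l_ave_cM <- mean(len5) + mean(len3)
    groups <- data.frame(signature = c(paste0("5:", names(table(b$bp5))),
                                       paste0("3:", names(table(b$bp3)))),
                         weight = c(as.integer(table(b$bp5)),
                                    as.integer(table(b$bp3))))
  } else {
    sig <- paste(b$bp5, b$bp3, sep = "/")
    tab <- tapply(per_hap$total_cM, sig, mean)
    wt <- table(sig)[names(tab)]
    groups <- data.frame(signature = names(tab),
                         weight = as.integer(wt),
                         total_cM = as.numeric(tab),
                         stringsAsFactors = FALSE)
    l_ave_cM <- sum(groups$weight * groups$total_cM) / sum(groups$weight)
  }
  structure(list(per_hap = per_hap, groups = groups,
                 l_ave = l_ave_cM / 100,
                 n_haplotypes = nrow(per_hap),
                 censoring_fraction = mean(b$censored_5 | b$censored_3)),
            class = "shared_summary")
}

#' Gamma-method allele age estimate
#'
#' Under lineage independence (a star genealogy), each carrier haplotype's
#' total shared genetic length (5' + 3', in Morgans) is the minimum over tau
#' generations of recombination, so the total over n haplotypes is
#' Gamma-distributed with shape 2n and rate tau. The point estimate is
#' tau_hat = 2 / l_ave; the confidence interval inverts the Gamma pivot:
#' `ci = qgamma(c(a/2, 1-a/2), shape = 2n) / (n * l_ave)`.
#'
#' @param l_ave weighted mean shared length in Morgans (or a
#'   [weighted_mean_length()] result).
#' @param n_haplotypes number of carrier haplotypes.
#' @param level confidence level (default 0.95).
#' @param region_span_M optional genetic span of the surveyed region in
#'   Morgans; an `l_ave` exceeding it is an input inconsistency.
#' @param years_per_generation optional scale for a years figure.
#' @param censoring_fraction fraction of haplotypes censored on at least one
#'   side; above 0.2 the estimate is flagged as biased downward.
#' @return list of class `age_estimate`: `tau_hat`, `ci` (lo, hi), `level`,
#'   `n_haplotypes`, `l_ave`, `years`, `censoring_fraction`.
#' @examples
#' estimate_age(0.02, n_haplotypes = 10)   # tau_hat = 100 generations
#' @export
estimate_age <- function(l_ave, n_haplotypes = NULL, level = 0.95,
                         region_span_M = NULL, years_per_generation = NULL,
                         censoring_fraction = 0) {
  if (inherits(l_ave, "shared_summary")) {
    s <- l_ave
    n_haplotypes <- n_haplotypes %||% s$n_haplotypes
    censoring_fraction <- s$censoring_fraction
    l_ave <- s$l_ave
  }
  stopifnot(l_ave > 0, n_haplotypes >= 2, level > 0, level < 1)
  if (!is.null(region_span_M) && l_ave > region_span_M) {
    stop("l_ave exceeds the region's genetic span: inconsistent inputs")
  }
  if (censoring_fraction > 0.2) {
    warning(sprintf(
      "censoring fraction %.2f > 0.2: tau_hat is biased downward (window too narrow)",
      censoring_fraction))
  }
  tau_hat <- 2 / l_ave
  a <- 1 - level
  shape <- 2 * n_haplotypes
  ci <- stats::qgamma(c(a / 2, 1 - a / 2), shape = shape) /
    (n_haplotypes * l_ave)
  structure(list(tau_hat = tau_hat, ci = ci, level = level,
                 n_haplotypes = as.integer(n_haplotypes), l_ave = l_ave,
                 years = if (!is.null(years_per_generation))
                   tau_hat * years_per_generation else NULL,
                 years_per_generation = years_per_generation,
                 censoring_fraction = censoring_fraction),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("tau_hat = %.1f generations (%d%% CI %.1f-%.1f), n = %d haplotypes\n",
              x$tau_hat, round(100 * x$level), x$ci[1], x$ci[2],
              x$n_haplotypes))
  if (!is.null(x$years)) {
    cat(sprintf("  ~%.0f years at %.0f years/generation\n", x$years,
                x$years_per_generation))
  }
  invisible(x)
}

#' Compare allele ages of two locus groups
#'
#' Two-sided Mann-Whitney U comparison of coalescence-time estimates, e.g.
#' loci shared between populations versus population-specific loci. Exact
#' enumeration when both groups have at most 8 values, tie-corrected normal
#' approximation otherwise.
#'
#' @param ages_a,ages_b numeric vectors of tau_hat values (>= 1 each).
#' @return list with `U`, `p`, `method`.
#' @export
compare_ages <- function(ages_a, ages_b) {
  if (length(ages_a) == 0 || length(ages_b) == 0) stop("empty age group")
  mann_whitney(ages_a, ages_b)
}

#' Correlation of allele age with carrier abundance
#'
#' Pearson correlation and least-squares slope of carrier frequency (or
#' count) on estimated age, with a t-test p-value on n - 2 degrees of
#' freedom.
#'
#' @param ages tau_hat values per locus.
#' @param carrier_freq carrier frequency (or count) per locus.
#' @return list with `r`, `slope`, `p`, `n`.
#' @export
age_abundance_correlation <- function(ages, carrier_freq) {
  stopifnot(length(ages) == length(carrier_freq), length(ages) >= 3)
  if (stats::sd(ages) == 0 || stats::sd(carrier_freq) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(ages, carrier_freq)
  fit <- stats::lm(carrier_freq ~ ages)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       p = ct$p.value, n = length(ages))
}

#' Shared-background support of an rCNV
#'
#' Fraction of carrier haplotypes whose alleles match the modal carrier
#' haplotype over the nearest `k` SNPs on each side of the locus (missing
#' alleles match-neutral). A high value (> 0.9 on simulated single-origin
#' rCNVs) supports a common ancestral haplotype; pooled non-IBD haplotypes
#' fall well below. Used to confirm that calls grouped into one locus sit on
#' the same haplotype background.
#'
#' @param carrier_haps carrier haplotype matrix over the full SNP set.
#' @param windows a [select_flanking_snps()] result.
#' @param k SNPs checked per side (default 10).
#' @return fraction in \[0, 1\].
#' @export
share_support <- function(carrier_haps, windows, k = 10L) {
  idx <- c(windows$upstream[seq_len(min(k, length(windows$upstream)))],
           windows$downstream[seq_len(min(k, length(windows$downstream)))])
  h <- carrier_haps[, idx, drop = FALSE]
  cm <- colMeans(h, na.rm = TRUE)
  ref <- as.integer(cm > 0.5); ref[is.nan(cm)] <- 0L
  m <- sweep(h, 2, ref, `==`)
  m[is.na(m)] <- TRUE
  mean(rowSums(!m) == 0)
}
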