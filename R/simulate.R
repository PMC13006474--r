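#' Simulation configuration for a founder-population rCNV cohort
#'
#' Bundles every knob of the cohort generator. The defaults describe a
#' founder-population study cohort of the kind the pipeline targets: 387
#' individuals of whom 27 carry a single ancestral CNV haplotype introduced
#' tau = 100 generations ago (founder variants in such populations are
#' typically hundreds of generations old), a 25 Mb region under a uniform
#' 1 cM/Mb map, 30 SNPs per cM (array-scale density), per-allele genotyping
#' error 0.002, a 500 kb deletion in the middle of the region, dual-caller
#' noise of 5 kb breakpoint jitter with 5% false-negative and false-positive
#' rates, and a binary phenotype with noncarrier prevalence 0.60 and
#' carrier odds ratio 3.2.
#'
#' @param seed integer RNG seed; the full output is a deterministic
#'   function of the config including the seed.
#' @param n_samples cohort size.
#' @param n_carriers number of CNV carriers (<= n_samples).
#' @param tau_true generations since the founder haplotype (>= 0; 0 means
#'   no recombination has occurred).
#' @param region_length simulated region length in bp.
#' @param snp_density SNPs per cM.
#' @param map_profile either `list(kind = "uniform", rate = <cM/Mb>)` or
#'   `list(kind = "piecewise", breaks_bp = <boundaries incl. 0 and region
#'   end>, rates = <cM/Mb per segment>)`.
#' @param maf_range range of per-SNP minor allele frequencies, in (0, 0.5].
#' @param genotyping_error per-allele flip probability.
#' @param cnv_interval `(start, end)` bp of the CNV; default centers a
#'   500 kb event.
#' @param cnv_state `"deletion"` or `"duplication"`; deletion carriers have
#'   the CNV haplotype's interior SNPs set missing (hemizygous).
#' @param caller_noise `list(jitter_sd = bp, fn_rate, fp_rate)`.
#' @param phenotype_model `list(baseline_prevalence, carrier_odds_ratio,
#'   other_diag_prevalence)`; the baseline is the noncarrier prevalence and
#'   the extra independent diagnosis flag feeds the "any psychiatric
#'   diagnosis" union.
#' @param genealogy `"star"` (independent lineages, matching the Gamma
#'   method's independence assumption) or `"tree"` (a Kingman coalescent
#'   tree with per-branch recombination, giving correlated shared lengths —
#'   the estimator's known failure mode).
#' @param years_per_generation scale for reporting ages in years.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 387L, n_carriers = 27L,
                       tau_true = 100, region_length = 25e6,
                       snp_density = 30,
                       map_profile = list(kind = "uniform", rate = 1),
                       maf_range = c(0.05, 0.5),
                       genotyping_error = 0.002,
                       cnv_interval = NULL, cnv_state = "deletion",
                       caller_noise = list(jitter_sd = 5000, fn_rate = 0.05,
                                           fp_rate = 0.05),
                       phenotype_model = list(baseline_prevalence = 0.60,
                                              carrier_odds_ratio = 3.2,
                                              other_diag_prevalence = 0.2),
                       genealogy = c("star", "tree"),
                       years_per_generation = 28) {
  genealogy <- match.arg(genealogy)
  if (is.null(cnv_interval)) {
    cnv_interval <- round(region_length / 2 + c(-250e3, 250e3))
  }
  stopifnot(n_carriers <= n_samples, n_carriers >= 1, tau_true >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            genotyping_error >= 0, genotyping_error <= 1,
            caller_noise$fn_rate >= 0, caller_noise$fn_rate <= 1,
            caller_noise$fp_rate >= 0, caller_noise$fp_rate <= 1,
            phenotype_model$baseline_prevalence >= 0,
            phenotype_model$baseline_prevalence <= 1,
            cnv_interval[1] > 1, cnv_interval[2] < region_length,
            cnv_state %in% c("deletion", "duplication"))
  structure(as.list(environment()), class = "sim_config")
}

build_map <- function(config) {
  mp <- config$map_profile
  if (mp$kind == "uniform") {
    pos <- seq(0, config$region_length, length.out = 26)
    genetic_map("chr1", pos + 1, pos * mp$rate / 1e6)
  } else {
    pos <- mp$breaks_bp
    cM <- c(0, cumsum(diff(pos) * mp$rates / 1e6))
    genetic_map("chr1", pos + 1, cM)
  }
}

#' Simulate a founder-population cohort carrying one ancestral CNV
#'
#' Generates phased haplotypes for `n_samples` diploid individuals, of whom
#' `n_carriers` carry a CNV haplotype descended from a single founder
#' haplotype `tau_true` generations ago. Each carrier's CNV haplotype
#' equals the founder haplotype from the CNV outward until its first
#' recombination breakpoint; under the star genealogy each side's
#' breakpoint genetic distance is an independent Exp(tau_true) draw (in
#' Morgans), so per-haplotype total shared lengths are Gamma(2, tau_true).
#' Beyond the breakpoint, and on every non-CNV haplotype, alleles are
#' independent per-SNP draws from the site frequency (no background LD).
#' Genotyping errors flip alleles after descent. For deletions, the CNV
#' haplotype's interior SNPs are set missing (hemizygous carriers).
#' Phenotypes follow a logistic model with log-odds increment
#' `log(carrier_odds_ratio)` for carriers.
#'
#' SNPs are placed on a regular grid in genetic distance (`snp_density` per
#' cM) and mapped to physical positions through the map.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `haps` ([hap_set]), `map`
#'   ([genetic_map]), `truth` (carrier ids, founder haplotype, per-carrier
#'   true breakpoint distances in Morgans and positions, tau_true,
#'   cnv_interval, state), `phenotypes` ([phenotype_table]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- build_map(config)
  g_end_region <- genetic_position(map, "chr1", config$region_length)
  n_snp <- max(10L, round(config$snp_density * g_end_region))
  g_grid <- seq(g_end_region / n_snp / 2, g_end_region - g_end_region / n_snp / 2,
                length.out = n_snp)
  pos <- round(physical_position(map, "chr1", g_grid))
  pos <- pmax(2, pmin(pos, config$region_length - 1))
  pos <- unique(pos)
  n_snp <- length(pos)
  g_snp <- genetic_position(map, "chr1", pos)

  g_cnv <- genetic_position(map, "chr1", config$cnv_interval)
  flank5_M <- (g_cnv[1] - g_snp[1]) / 100
  flank3_M <- (g_snp[n_snp] - g_cnv[2]) / 100
  if (config$tau_true > 0 &&
      min(flank5_M, flank3_M) < 2 / config$tau_true) {
    warning(sprintf(
      "flanking span (%.3f M) is under twice the expected breakpoint distance (1/tau = %.3f M); widen the region",
      min(flank5_M, flank3_M), 1 / config$tau_true))
  }

  maf <- stats::runif(n_snp, config$maf_range[1], config$maf_range[2])
  p1 <- ifelse(stats::runif(n_snp) < 0.5, maf, 1 - maf)
  founder <- stats::rbinom(n_snp, 1L, p1)

  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  carrier_ids <- sort(sample(sample_ids, config$n_carriers))
  is_carrier <- sample_ids %in% carrier_ids

  H <- matrix(stats::rbinom(2L * n * n_snp, 1L, rep(p1, each = 2L * n)),
              nrow = 2L * n, ncol = n_snp)

  d <- breakpoint_distances(config)         # Morgans, per carrier, 5' and 3'
  d5 <- pmin(d$d5, flank5_M); d3 <- pmin(d$d3, flank3_M)
  carrier_rows <- 2L * match(carrier_ids, sample_ids) - 1L  # haplotype 1
  for (k in seq_along(carrier_ids)) {
    lo_cM <- g_cnv[1] - 100 * d5[k]
    hi_cM <- g_cnv[2] + 100 * d3[k]
    seg <- g_snp >= lo_cM & g_snp <= hi_cM
    H[carrier_rows[k], seg] <- founder[seg]
  }

  if (config$genotyping_error > 0) {
    flip <- matrix(stats::runif(length(H)) < config$genotyping_error,
                   nrow = nrow(H))
    H[flip] <- 1L - H[flip]
  }

  if (config$cnv_state == "deletion") {
    interior <- pos >= config$cnv_interval[1] & pos <= config$cnv_interval[2]
    H[carrier_rows, interior] <- NA_integer_
  }

  haps <- hap_set(H, pos, sample_ids, chrom = "chr1")

  pm <- config$phenotype_model
  eta <- stats::qlogis(pm$baseline_prevalence) +
    log(pm$carrier_odds_ratio) * is_carrier
  aud <- stats::runif(n) < stats::plogis(eta)
  other <- stats::runif(n) < (pm$other_diag_prevalence %||% 0.2)
  pheno <- phenotype_table(sample_ids,
                           age = round(stats::runif(n, 18, 80)),
                           sex = ifelse(stats::runif(n) < 0.5, "M", "F"),
                           aud = aud, other_diag = other)

  b5_pos <- physical_position(map, "chr1", g_cnv[1] - 100 * d5)
  b3_pos <- physical_position(map, "chr1", g_cnv[2] + 100 * d3)
  truth <- structure(list(
    carrier_ids = carrier_ids, tau_true = config$tau_true,
    cnv_interval = config$cnv_interval, state = config$cnv_state,
    founder_haplotype = founder, snp_positions = pos,
    breakpoints = data.frame(sample_id = carrier_ids, d5_M = d5, d3_M = d3,
                             b5_pos = b5_pos, b3_pos = b3_pos,
                             stringsAsFactors = FALSE),
    config = config), class = "sim_truth")

  structure(list(haps = haps, map = map, truth = truth, phenotypes = pheno),
            class = "sim_cohort")
}

# Per-carrier genetic distances (Morgans) from the CNV to the first
# recombination on each side. Star: independent Exp(tau). Tree: a Kingman
# coalescent over the carriers scaled to TMRCA = tau; walking root-to-leaf,
# each branch of t generations contributes an Exp(t) candidate distance and
# a leaf's distance is the minimum along its path, so leaves sharing
# branches share breakpoints.
breakpoint_distances <- function(config) {
  nc <- config$n_carriers
  tau <- config$tau_true
  rexp_safe <- function(n, rate) {
    if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
  }
  if (config$genealogy == "star" || nc == 1L) {
    return(list(d5 = rexp_safe(nc, tau), d3 = rexp_safe(nc, tau)))
  }
  tr <- ape::rcoal(nc)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (tau / depth)
  n_node <- nc + tr$Nnode
  edge_order <- rev(ape::postorder(tr))     # parents before children
  one_side <- function() {
    dmin <- rep(Inf, n_node)
    for (k in edge_order) {
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      dmin[child] <- min(dmin[par], rexp_safe(1, tr$edge.length[k]))
    }
    dmin[seq_len(nc)]
  }
  list(d5 = one_side(), d3 = one_side())
}

#' Emit two noisy caller call sets from simulation truth
#'
#' Each carrier yields, per caller, one call whose endpoints are the true
#' CNV endpoints plus independent Gaussian jitter snapped to the nearest
#' simulated probe (with `jitter_sd = 0` the true endpoints are emitted
#' exactly), dropped with probability `fn_rate`. Each non-carrier sample
#' receives, per caller, a spurious same-length call at a random position
#' with probability `fp_rate`. `n_probes` counts simulated probes inside
#' the call; degenerate jittered intervals are clipped to at least one
#' probe.
#'
#' @param truth `truth` element of a [simulate_cohort()] result.
#' @param haps matching [hap_set] (provides the probe positions).
#' @param noise `list(jitter_sd, fn_rate, fp_rate)`; defaults to the
#'   config's `caller_noise`.
#' @param seed RNG seed for the caller noise.
#' @return list with [cnv_calls] elements `caller_a` and `caller_b`.
#' @export
emit_callsets <- function(truth, haps, noise = NULL, seed = 1L) {
  noise <- noise %||% truth$config$caller_noise
  set.seed(seed)
  pos <- haps$positions
  cn <- if (truth$state == "deletion") 1L else 3L
  all_ids <- haps$sample_ids
  one_caller <- function(name) {
    rows <- list()
    for (s in truth$carrier_ids) {
      if (stats::runif(1) < noise$fn_rate) next
      se <- jitter_interval(truth$cnv_interval, noise$jitter_sd, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, start = se[1], end = se[2], cn = cn,
        n_probes = max(1L, sum(pos >= se[1] & pos <= se[2])),
        stringsAsFactors = FALSE)
    }
    for (s in setdiff(all_ids, truth$carrier_ids)) {
      if (stats::runif(1) >= noise$fp_rate) next
      len <- truth$cnv_interval[2] - truth$cnv_interval[1]
      st <- round(stats::runif(1, min(pos), max(pos) - len))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, start = st, end = st + len,
        cn = sample(c(1L, 3L), 1),
        n_probes = max(1L, sum(pos >= st & pos <= st + len)),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) {
      return(cnv_calls(character(), character(), integer(), integer(),
                       integer(), integer(), character()))
    }
    df <- do.call(rbind, rows)
    cnv_calls(df$sample_id, "chr1", df$start, df$end, df$cn, df$n_probes,
              name)
  }
  list(caller_a = one_caller("callerA"), caller_b = one_caller("callerB"))
}

jitter_interval <- function(interval, sd, pos) {
  if (sd == 0) return(interval)
  snap <- function(x) pos[which.min(abs(pos - x))]
  s <- snap(interval[1] + stats::rnorm(1, 0, sd))
  e <- snap(interval[2] + stats::rnorm(1, 0, sd))
  if (s > e) { tmp <- s; s <- e; e <- tmp }
  c(s, e)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d samples (%d carriers), tau = %g, %s %s:%d-%d\n",
    length(x$haps$sample_ids), length(x$truth$carrier_ids),
    x$truth$tau_true, x$truth$state, "chr1", x$truth$cnv_interval[1],
    x$truth$cnv_interval[2]))
  invisible(x)
}
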