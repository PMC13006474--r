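#' KING-robust pairwise kinship
#'
#' Between-family KING-robust estimator from SNP genotype dosages: for a
#' pair (i, j),
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))`,
#' where `N_Aa,Aa` counts SNPs at which both are heterozygous, `N_AA,aa`
#' counts opposite homozygotes, and `N_Aa(i)` counts heterozygous sites of
#' sample i — all over the pair's complete (non-missing in both) sites. The
#' estimator is robust to population structure, invariant to SNP order and
#' to allele-label swaps (0/2 recoding), and gives phi = 0.5 for duplicate
#' samples, ~0.25 for first-degree relatives, ~0 for unrelated pairs.
#'
#' SNPs are filtered before estimation: missing rate above `miss_max` or
#' minor allele frequency below `maf_min` (computed from the data) are
#' dropped.
#'
#' @param genotypes integer matrix, samples x SNPs, dosages in
#'   `{0, 1, 2, NA}`; rownames are sample ids.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum per-SNP missing rate (default 0.1).
#' @return symmetric matrix of class `kinship_matrix` with phi on the
#'   off-diagonal and 0.5 on the diagonal; a pair in which either member has
#'   no heterozygous site gets `NA` with a warning.
#' @export
king_kinship <- function(genotypes, maf_min = 0.01, miss_max = 0.1) {
  G <- as.matrix(genotypes)
  if (nrow(G) < 2) stop("need >= 2 samples")
  miss <- colMeans(is.na(G))
  p <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- miss <= miss_max & !is.na(maf) & maf >= maf_min
  G <- G[, keep, drop = FALSE]
  if (ncol(G) == 0) stop("no SNPs pass the MAF/missingness filters")
  V <- (!is.na(G)) * 1                       # validity mask
  H <- (G == 1L); H[is.na(H)] <- FALSE; H <- H * 1
  A <- (G == 0L); A[is.na(A)] <- FALSE; A <- A * 1
  B <- (G == 2L); B[is.na(B)] <- FALSE; B <- B * 1
  N_hethet <- H %*% t(H)
  N_opp <- A %*% t(B) + B %*% t(A)
  D <- H %*% t(V) + V %*% t(H)               # N_Aa(i)|pair + N_Aa(j)|pair
  phi <- (N_hethet - 2 * N_opp) / D
  if (any(D == 0 & upper.tri(D))) {
    warning("pair(s) with no heterozygous sites: kinship undefined (NA)")
    phi[D == 0] <- NA_real_
  }
  diag(phi) <- 0.5
  ids <- rownames(G) %||% paste0("S", seq_len(nrow(G)))
  dimnames(phi) <- list(ids, ids)
  class(phi) <- c("kinship_matrix", class(phi))
  phi
}

#' Compare kinship among rCNV carriers versus noncarriers
#'
#' Contrasts the distribution of pairwise kinship coefficients among
#' carrier pairs with that among noncarrier pairs (both members
#' noncarriers), with a two-sided rank-sum comparison. In a founder cohort
#' an ancient rCNV segregates across many pedigree branches, so the two
#' distributions largely overlap; a recent familial CNV concentrates high
#' phi among carrier pairs.
#'
#' @param kin a [king_kinship()] matrix.
#' @param carriers character vector of carrier sample ids (>= 2, and not
#'   the whole cohort).
#' @return list of class `kinship_comparison`: `carrier_phi`,
#'   `noncarrier_phi`, medians, `U`, `p`.
#' @export
kinship_compare <- function(kin, carriers) {
  ids <- rownames(kin)
  carriers <- intersect(carriers, ids)
  if (length(carriers) < 2) stop("need >= 2 carriers present in the kinship matrix")
  non <- setdiff(ids, carriers)
  if (length(non) < 2) stop("fewer than 2 noncarriers: comparison degenerate")
  off <- function(sub) {
    m <- kin[sub, sub, drop = FALSE]
    m[upper.tri(m)]
  }
  cp <- off(carriers); np <- off(non)
  mw <- mann_whitney(cp, np)
  structure(list(carrier_phi = cp, noncarrier_phi = np,
                 median_carrier = stats::median(cp, na.rm = TRUE),
                 median_noncarrier = stats::median(np, na.rm = TRUE),
                 U = mw$U, p = mw$p),
            class = "kinship_comparison")
}

#' @export
print.kinship_comparison <- function(x, ...) {
  cat(sprintf(
    "kinship phi: carrier-pair median %.4f (n=%d), noncarrier-pair median %.4f (n=%d), rank-sum p = %.3g\n",
    x$median_carrier, length(x$carrier_phi), x$median_noncarrier,
    length(x$noncarrier_phi), x$p))
  invisible(x)
}

#' Prune close relatives
#'
#' Greedy pruning of pairs with kinship at or above `phi_cutoff` (default
#' 0.0884, the conventional second-degree boundary), dropping the member of
#' each pair with more genotype missingness. Applied before coalescence
#' dating so that shared-haplotype lengths come from effectively independent
#' lineages.
#'
#' @param kin a [king_kinship()] matrix.
#' @param phi_cutoff kinship threshold (default `2^(-7/2)` ~ 0.0884).
#' @param missingness optional named per-sample missing fraction used to
#'   pick which member of a related pair to drop; ties drop the
#'   later-sorted id.
#' @return character vector of retained sample ids.
#' @export
prune_relatives <- function(kin, phi_cutoff = 2^(-7 / 2),
                            missingness = NULL) {
  ids <- rownames(kin)
  keep <- rep(TRUE, length(ids)); names(keep) <- ids
  m <- kin; diag(m) <- 0
  repeat {
    mm <- m[keep, keep, drop = FALSE]
    if (all(is.na(mm)) || max(mm, na.rm = TRUE) < phi_cutoff) break
    idx <- which(mm == max(mm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- rownames(mm)[idx]
    drop <- if (!is.null(missingness) &&
                !isTRUE(all.equal(missingness[[pair[1]]],
                                  missingness[[pair[2]]]))) {
      pair[which.max(c(missingness[[pair[1]]], missingness[[pair[2]]]))]
    } else {
      sort(pair)[2]
    }
    keep[drop] <- FALSE
  }
  ids[keep]
}
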