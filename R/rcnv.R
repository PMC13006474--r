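#' Cluster consensus calls into recurrent CNV loci
#'
#' Same-state calls from different individuals are clustered by
#' single-linkage on reciprocal overlap: two calls are linked when their
#' reciprocal overlap is at least `grouping_ro` (and, optionally, also when
#' both endpoints agree within `endpoint_tol` bp, accommodating the ~10 kb
#' breakpoint uncertainty of array calls). Input order is irrelevant: calls
#' are canonically sorted before clustering. Each call belongs to exactly
#' one cluster; the locus interval is the coordinate-wise median of member
#' starts/ends (robust to caller jitter). A locus with two or more distinct
#' carriers is flagged recurrent. A sample contributing two member calls to
#' one cluster is counted once as a carrier, with a warning.
#'
#' @param calls consensus [cnv_calls] from one cohort.
#' @param cohort_size number of individuals in the cohort (denominator of
#'   the carrier frequency).
#' @param grouping_ro reciprocal-overlap linkage threshold (default 0.5).
#' @param endpoint_tol optional bp tolerance: calls whose starts and ends
#'   both differ by at most this are linked regardless of overlap fraction.
#'   `NULL` (default) disables the rule.
#' @param bands optional band table (`chrom`, `start`, `end`, `band`,
#'   1-based inclusive) used to label each locus with the cytogenetic band
#'   of its midpoint.
#' @return data.frame of class `rcnv_loci`: `locus_id`, `chrom`, `start`,
#'   `end`, `band`, `state`, `carrier_count`, `carrier_frequency`,
#'   `recurrent`, and a list column `carriers`.
#' @export
group_recurrent <- function(calls, cohort_size, grouping_ro = 0.5,
                            endpoint_tol = NULL, bands = NULL) {
  stopifnot(cohort_size >= 1)
  calls <- validate_cnv_calls(calls)
  calls <- calls[order(calls$chrom, calls$state, calls$start, calls$end,
                       calls$sample_id), , drop = FALSE]
  rownames(calls) <- NULL
  if (nrow(calls) == 0) {
    return(empty_loci())
  }
  grp_key <- paste(calls$chrom, calls$state)
  loci <- list()
  for (key in unique(grp_key)) {
    idx <- which(grp_key == key)
    sub <- calls[idx, , drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        if (sub$start[j] > sub$end[i] &&
            (is.null(endpoint_tol) || sub$start[j] - sub$start[i] >
               endpoint_tol)) break
        link <- reciprocal_overlap(sub$start[i], sub$end[i], sub$start[j],
                                   sub$end[j]) >= grouping_ro
        if (!link && !is.null(endpoint_tol)) {
          link <- abs(sub$start[i] - sub$start[j]) <= endpoint_tol &&
            abs(sub$end[i] - sub$end[j]) <= endpoint_tol
        }
        if (link) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      mem <- sub[roots == r, , drop = FALSE]
      if (anyDuplicated(mem$sample_id)) {
        warning("sample(s) with multiple member calls in one locus counted once: ",
                paste(unique(mem$sample_id[duplicated(mem$sample_id)]),
                      collapse = ", "))
      }
      carriers <- sort(unique(mem$sample_id))
      loci[[length(loci) + 1L]] <- data.frame(
        chrom = mem$chrom[1],
        start = as.integer(round(stats::median(mem$start))),
        end = as.integer(round(stats::median(mem$end))),
        state = mem$state[1],
        carrier_count = length(carriers),
        carrier_frequency = length(carriers) / cohort_size,
        recurrent = length(carriers) >= 2L,
        n_member_calls = nrow(mem),
        carriers = I(list(carriers)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start, out$state), , drop = FALSE]
  out$band <- if (!is.null(bands)) band_of(bands, out$chrom,
                                           (out$start + out$end) %/% 2)
    else NA_character_
  out$locus_id <- sprintf("%s:%d-%d_%s", out$chrom, out$start, out$end,
                          substr(out$state, 1, 3))
  rownames(out) <- NULL
  cols <- c("locus_id", "chrom", "start", "end", "band", "state",
            "carrier_count", "carrier_frequency", "recurrent",
            "n_member_calls", "carriers")
  out <- out[, cols]
  class(out) <- unique(c("rcnv_loci", class(out)))
  out
}

empty_loci <- function() {
  out <- data.frame(locus_id = character(), chrom = character(),
                    start = integer(), end = integer(), band = character(),
                    state = character(), carrier_count = integer(),
                    carrier_frequency = numeric(), recurrent = logical(),
                    n_member_calls = integer(), stringsAsFactors = FALSE)
  out$carriers <- I(list())
  class(out) <- unique(c("rcnv_loci", class(out)))
  out
}

band_of <- function(bands, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    hit <- bands$chrom == chrom[i] & bands$start <= pos[i] &
      bands$end >= pos[i]
    if (any(hit)) bands$band[which(hit)[1]] else NA_character_
  }, character(1))
}

#' @export
print.rcnv_loci <- function(x, ...) {
  cat(sprintf("<rcnv_loci> %d loci (%d recurrent)\n", nrow(x),
              sum(x$recurrent)))
  show <- as.data.frame(x)[, setdiff(names(x), "carriers")]
  print(utils::head(show, 12), row.names = FALSE)
  if (nrow(x) > 12) cat(sprintf("... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' Cross-population sharing of rCNV loci
#'
#' Matches loci between two cohorts one-to-one, best overlap first. Under
#' `rule = "overlap"` a pair qualifies when same-state loci reach the
#' reciprocal-overlap threshold `share_ro`; under `"band"` when their
#' cytogenetic band labels agree (same state); `"band_or_overlap"` (the
#' default) accepts either, which accommodates array platforms whose probe
#' sets place breakpoints of the same ancestral event at non-overlapping
#' printed coordinates within one band. Counts partition all loci.
#'
#' @param loci_a,loci_b [group_recurrent()] outputs for the two cohorts.
#' @param rule `"band_or_overlap"`, `"overlap"` or `"band"`.
#' @param share_ro reciprocal-overlap threshold for the overlap rule.
#' @return list of class `share_result`: `pairs` (data.frame of matched
#'   locus ids with their reciprocal overlap and band match flag),
#'   `n_shared`, `n_a_only`, `n_b_only`, `n_distinct` (= a_only + b_only +
#'   shared).
#' @export
cross_population_share <- function(loci_a, loci_b,
                                   rule = c("band_or_overlap", "overlap",
                                            "band"),
                                   share_ro = 0.5) {
  rule <- match.arg(rule)
  if (rule %in% c("band", "band_or_overlap")) {
    if (rule == "band" &&
        (any(is.na(loci_a$band)) || any(is.na(loci_b$band)))) {
      stop("rule='band' requires band labels on every locus")
    }
  }
  cand <- expand.grid(i = seq_len(nrow(loci_a)), j = seq_len(nrow(loci_b)))
  cand <- cand[loci_a$state[cand$i] == loci_b$state[cand$j], , drop = FALSE]
  if (nrow(cand)) {
    cand$ro <- reciprocal_overlap(loci_a$start[cand$i], loci_a$end[cand$i],
                                  loci_b$start[cand$j], loci_b$end[cand$j],
                                  loci_a$chrom[cand$i], loci_b$chrom[cand$j])
    cand$band_match <- !is.na(loci_a$band[cand$i]) &
      !is.na(loci_b$band[cand$j]) &
      loci_a$band[cand$i] == loci_b$band[cand$j]
    keep <- switch(rule,
                   overlap = cand$ro >= share_ro,
                   band = cand$band_match,
                   band_or_overlap = cand$ro >= share_ro | cand$band_match)
    cand <- cand[keep, , drop = FALSE]
  }
  pairs <- data.frame(locus_a = character(), locus_b = character(),
                      ro = numeric(), band_match = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(cand)) {
    cand <- cand[order(-cand$ro, cand$i, cand$j), , drop = FALSE]
    used_a <- logical(nrow(loci_a)); used_b <- logical(nrow(loci_b))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        locus_a = loci_a$locus_id[i], locus_b = loci_b$locus_id[j],
        ro = cand$ro[k], band_match = cand$band_match[k],
        stringsAsFactors = FALSE))
    }
  }
  n_shared <- nrow(pairs)
  structure(list(pairs = pairs, n_shared = n_shared,
                 n_a_only = nrow(loci_a) - n_shared,
                 n_b_only = nrow(loci_b) - n_shared,
                 n_distinct = nrow(loci_a) + nrow(loci_b) - n_shared),
            class = "share_result")
}

#' @export
print.share_result <- function(x, ...) {
  cat(sprintf("rCNV sharing: %d shared, %d cohort-A only, %d cohort-B only (%d distinct)\n",
              x$n_shared, x$n_a_only, x$n_b_only, x$n_distinct))
  invisible(x)
}

#' Annotate a locus with overlapping genes
#'
#' A gene fully contained in the locus is classified `full`; a gene
#' overlapping but not contained is `partial`; the locus is flagged genic
#' when either class is non-empty.
#'
#' @param locus a single row of an [group_recurrent()] result, or any list
#'   with `chrom`, `start`, `end`.
#' @param genes gene intervals as from [read_genes_bed()] (`chrom`, `start`,
#'   `end`, `gene`, 1-based inclusive).
#' @return list of class `gene_annotation`: `full`, `partial` (character
#'   vectors of gene names), `genic` (logical).
#' @export
annotate_genes <- function(locus, genes) {
  bad <- which(genes$end < genes$start)
  if (length(bad)) {
    stop("zero-length gene interval(s) at row(s): ",
         paste(bad, collapse = ", "))
  }
  same <- genes$chrom == locus$chrom
  ov <- same & genes$start <= locus$end & genes$end >= locus$start
  full <- ov & genes$start >= locus$start & genes$end <= locus$end
  partial <- ov & !full
  structure(list(full = genes$gene[full], partial = genes$gene[partial],
                 genic = any(ov)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  if (!x$genic) {
    cat("non-genic locus\n")
  } else {
    cat(sprintf("genic locus: %d fully contained, %d partially overlapped\n",
                length(x$full), length(x$partial)))
    if (length(x$full)) cat("  full:    ", paste(x$full, collapse = ", "), "\n")
    if (length(x$partial)) cat("  partial: ", paste(x$partial, collapse = ", "), "\n")
  }
  invisible(x)
}
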