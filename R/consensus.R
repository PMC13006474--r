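#' Reciprocal overlap of two genomic intervals
#'
#' For 1-based inclusive intervals a and b on the same chromosome, the
#' reciprocal overlap is `min(|a∩b|/|a|, |a∩b|/|b|)`: the overlap fraction
#' computed with respect to the larger interval. It is symmetric, 1 for
#' identical intervals and 0 for disjoint ones; intervals on different
#' chromosomes return 0. The ">= 50% reciprocal overlap" rule used for
#' dual-caller consensus and recurrent-locus grouping is applied to this
#' quantity. Vectorized over intervals.
#'
#' @param a_start,a_end,b_start,b_end 1-based inclusive endpoints.
#' @param a_chrom,b_chrom optional chromosome labels; if given, mismatching
#'   chromosomes yield 0.
#' @return numeric fraction in \[0, 1\].
#' @examples
#' reciprocal_overlap(1, 100, 51, 150)   # 0.5
#' @export
reciprocal_overlap <- function(a_start, a_end, b_start, b_end,
                               a_chrom = NULL, b_chrom = NULL) {
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
  ro <- pmin(ov / (a_end - a_start + 1), ov / (b_end - b_start + 1))
  if (!is.null(a_chrom) && !is.null(b_chrom)) ro[a_chrom != b_chrom] <- 0
  ro
}

#' Consensus filtering parameters
#'
#' Defaults follow the standard array-CNV QC recipe: calls must be detected
#' by both callers with at least 50% reciprocal overlap, span at least ten
#' adjacent SNP probes, and be at least 10 kb long.
#'
#' @param min_reciprocal_overlap fraction in (0, 1\].
#' @param min_probes minimum probe support of the consensus call.
#' @param min_size minimum consensus length in bp.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(min_reciprocal_overlap = 0.5, min_probes = 10L,
                             min_size = 10000L) {
  stopifnot(min_reciprocal_overlap > 0, min_reciprocal_overlap <= 1,
            min_probes >= 1, min_size >= 1)
  structure(list(min_reciprocal_overlap = min_reciprocal_overlap,
                 min_probes = as.integer(min_probes),
                 min_size = as.integer(min_size)),
            class = "consensus_params")
}

#' Merge two callers' CNV call sets into consensus calls
#'
#' Within each sample, same-state calls from the two callers are paired
#' greedily by descending reciprocal overlap (ties: leftmost start, then
#' shortest call), each input call used at most once; pairs at or above the
#' reciprocal-overlap threshold yield one consensus call whose endpoints are
#' the intersection of the pair. Consensus calls failing the probe-count or
#' size filter are dropped. The procedure is symmetric in its two arguments.
#'
#' The consensus probe count is recounted from `probe_positions` when
#' supplied; otherwise it is the smaller of the two callers' counts scaled
#' by the fraction of each call retained in the intersection.
#'
#' @param set_a,set_b [cnv_calls] data.frames from the two callers.
#' @param params a [consensus_params] list.
#' @param probe_positions optional list mapping chromosome label to a sorted
#'   vector of probe positions, used to recount probes in the consensus
#'   interval.
#' @return A [cnv_calls] data.frame with `caller = "consensus"`.
#' @export
merge_consensus <- function(set_a, set_b, params = consensus_params(),
                            probe_positions = NULL) {
  set_a <- dedup_calls(validate_cnv_calls(set_a), "caller A")
  set_b <- dedup_calls(validate_cnv_calls(set_b), "caller B")
  samples <- union(set_a$sample_id, set_b$sample_id)
  out <- list()
  for (s in samples) {
    a <- set_a[set_a$sample_id == s, , drop = FALSE]
    b <- set_b[set_b$sample_id == s, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    pairs <- pairs[a$state[pairs$i] == b$state[pairs$j] &
                   a$chrom[pairs$i] == b$chrom[pairs$j], , drop = FALSE]
    if (nrow(pairs) == 0) next
    pairs$ro <- reciprocal_overlap(a$start[pairs$i], a$end[pairs$i],
                                   b$start[pairs$j], b$end[pairs$j])
    pairs <- pairs[pairs$ro >= params$min_reciprocal_overlap, , drop = FALSE]
    if (nrow(pairs) == 0) next
    # greedy best-overlap matching; deterministic tie-breaks
    pairs$istart <- pmax(a$start[pairs$i], b$start[pairs$j])
    pairs$ilen <- pmin(a$end[pairs$i], b$end[pairs$j]) - pairs$istart + 1
    pairs <- pairs[order(-pairs$ro, pairs$istart, pairs$ilen), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      cs <- max(a$start[i], b$start[j]); ce <- min(a$end[i], b$end[j])
      np <- consensus_probes(a[i, ], b[j, ], cs, ce, probe_positions)
      if (np < params$min_probes) next
      if (ce - cs + 1 < params$min_size) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, chrom = a$chrom[i], start = cs, end = ce,
        state = a$state[i], copy_number = a$copy_number[i],
        n_probes = np, caller = "consensus", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    res <- cnv_calls(character(), character(), integer(), integer(),
                     integer(), integer(), character())
  } else {
    res <- validate_cnv_calls(do.call(rbind, out))
  }
  res[order(res$sample_id, res$chrom, res$start), , drop = FALSE]
}

consensus_probes <- function(a, b, cs, ce, probe_positions) {
  if (!is.null(probe_positions) && !is.null(probe_positions[[a$chrom]])) {
    pp <- probe_positions[[a$chrom]]
    return(max(1L, sum(pp >= cs & pp <= ce)))
  }
  fa <- (ce - cs + 1) / (a$end - a$start + 1)
  fb <- (ce - cs + 1) / (b$end - b$start + 1)
  max(1L, as.integer(round(min(a$n_probes * fa, b$n_probes * fb))))
}

#' Summarize a cohort's CNV profile
#'
#' @param calls a [cnv_calls] data.frame (typically consensus calls).
#' @param n_individuals cohort size the calls were drawn from.
#' @return list of class `cohort_summary`: `n_events`, `mean_per_person`
#'   (unrounded; `print` shows 1 dp), `n_del`, `n_dup`, `pct_del`, `pct_dup`
#'   (unrounded percentages), `mean_size_kb` (`NA` for an empty call set).
#' @examples
#' \dontrun{summarize_calls(consensus, n_individuals = 387)}
#' @export
summarize_calls <- function(calls, n_individuals) {
  stopifnot(n_individuals >= 1)
  n <- nrow(calls)
  n_del <- sum(calls$state == "deletion")
  n_dup <- n - n_del
  structure(list(
    n_events = n,
    n_individuals = as.integer(n_individuals),
    mean_per_person = n / n_individuals,
    n_del = n_del, n_dup = n_dup,
    pct_del = if (n > 0) 100 * n_del / n else NA_real_,
    pct_dup = if (n > 0) 100 * n_dup / n else NA_real_,
    mean_size_kb = if (n > 0) mean(calls$end - calls$start + 1) / 1000 else
      NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("CNV cohort summary: %d events in %d individuals (%.1f per person)\n",
              x$n_events, x$n_individuals, x$mean_per_person))
  if (x$n_events > 0) {
    cat(sprintf("  deletions:    %d (%d%%)\n", x$n_del, round(x$pct_del)))
    cat(sprintf("  duplications: %d (%d%%)\n", x$n_dup, round(x$pct_dup)))
    cat(sprintf("  mean size:    %.0f kb\n", x$mean_size_kb))
  }
  invisible(x)
}
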