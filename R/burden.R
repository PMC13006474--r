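#' Per-individual CNV burden
#'
#' Two burden metrics per sample: the number of consensus CNV events and
#' the gene load — the number of distinct genes whose copy number any of
#' the sample's CNVs alters (any overlap, full or partial; each gene counted
#' once per sample). Samples listed in `sample_ids` but absent from the
#' call set get zeros; individuals whose CNVs touch no gene are a real
#' class and report gene_load 0.
#'
#' @param calls consensus [cnv_calls].
#' @param genes gene intervals (`chrom`, `start`, `end`, `gene`), 1-based
#'   inclusive, as from [read_genes_bed()].
#' @param sample_ids optional full cohort roster; defaults to the samples
#'   present in `calls`.
#' @return data.frame: `sample_id`, `cnv_count`, `gene_load`.
#' @export
burden_metrics <- function(calls, genes, sample_ids = NULL) {
  calls <- validate_cnv_calls(calls)
  sample_ids <- sample_ids %||% sort(unique(calls$sample_id))
  out <- data.frame(sample_id = sample_ids, cnv_count = 0L, gene_load = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(sample_ids)) {
    sub <- calls[calls$sample_id == sample_ids[k], , drop = FALSE]
    out$cnv_count[k] <- nrow(sub)
    if (nrow(sub) == 0) next
    hit <- logical(nrow(genes))
    for (i in seq_len(nrow(sub))) {
      hit <- hit | (genes$chrom == sub$chrom[i] &
                    genes$start <= sub$end[i] & genes$end >= sub$start[i])
    }
    out$gene_load[k] <- length(unique(genes$gene[hit]))
  }
  out
}

#' Case-control CNV burden comparison
#'
#' Nonparametric (Mann-Whitney) two-sided comparison of each burden metric
#' between cases and controls, with group means and SDs. No covariate
#' adjustment is applied; results are exploratory and descriptive.
#'
#' @param metrics a [burden_metrics()] data.frame.
#' @param phenotype logical per sample (aligned with `metrics` rows):
#'   TRUE = case.
#' @return list of class `burden_result`, one element per metric with
#'   `mean_case`, `sd_case`, `mean_control`, `sd_control`, `U`, `p`, plus
#'   `n_case`, `n_control`.
#' @export
burden_test <- function(metrics, phenotype) {
  stopifnot(nrow(metrics) == length(phenotype))
  ph <- as.logical(phenotype)
  if (!any(ph) || !all(is.finite(ph)) || all(ph)) stop("both groups must be non-empty")
  res <- list()
  for (metric in c("cnv_count", "gene_load")) {
    x <- metrics[[metric]]
    mw <- mann_whitney(x[ph], x[!ph])
    res[[metric]] <- list(mean_case = mean(x[ph]), sd_case = stats::sd(x[ph]),
                          mean_control = mean(x[!ph]),
                          sd_control = stats::sd(x[!ph]),
                          U = mw$U, p = mw$p, method = mw$method)
  }
  res$n_case <- sum(ph); res$n_control <- sum(!ph)
  class(res) <- "burden_result"
  res
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("CNV burden, %d cases vs %d controls (exploratory, unadjusted):\n",
              x$n_case, x$n_control))
  for (metric in c("cnv_count", "gene_load")) {
    m <- x[[metric]]
    cat(sprintf("  %-10s cases %.2f +/- %.2f, controls %.2f +/- %.2f, U = %.1f, p = %.3g\n",
                metric, m$mean_case, m$sd_case, m$mean_control,
                m$sd_control, m$U, m$p))
  }
  invisible(x)
}
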