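#' Construct a CNV call set
#'
#' A call set is the pipeline's atomic container: one row per copy-number
#' segment detected in one sample by one caller. Coordinates are 1-based
#' inclusive base pairs throughout the package; conversion to BED's 0-based
#' half-open convention happens only at export ([write_bed()]).
#'
#' @param sample_id character vector of sample labels.
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors, 1-based inclusive endpoints.
#' @param copy_number integer copy number in `{0, 1, 3, 4}` (2 is the diploid
#'   reference state and never appears in a call).
#' @param n_probes integer number of array probes supporting the call.
#' @param caller character label of the calling algorithm.
#'
#' @return A `data.frame` of class `cnv_calls` with columns `sample_id`,
#'   `chrom`, `start`, `end`, `state` (`"deletion"` or `"duplication"`,
#'   derived from `copy_number`), `copy_number`, `n_probes`, `caller`.
#' @examples
#' cnv_calls("S1", "chr6", 31355318L, 31451476L, 1L, 40L, "pennCNV")
#' @export
cnv_calls <- function(sample_id, chrom, start, end, copy_number, n_probes,
                      caller) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    state = ifelse(as.integer(copy_number) < 2L, "deletion", "duplication"),
    copy_number = as.integer(copy_number),
    n_probes = as.integer(n_probes),
    caller = as.character(caller),
    stringsAsFactors = FALSE
  )
  validate_cnv_calls(df)
}

#' @rdname cnv_calls
#' @param x a data.frame with the call-set columns.
#' @export
validate_cnv_calls <- function(x) {
  req <- c("sample_id", "chrom", "start", "end", "copy_number", "n_probes",
           "caller")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("call set is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"state" %in% names(x)) {
    x$state <- ifelse(x$copy_number < 2L, "deletion", "duplication")
  }
  bad <- which(x$start > x$end)
  if (length(bad)) {
    stop("start > end for call row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(x$n_probes < 1L)
  if (length(bad)) {
    stop("n_probes < 1 for call row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(!x$copy_number %in% c(0L, 1L, 3L, 4L))
  if (length(bad)) {
    stop("copy_number outside {0,1,3,4} for call row(s): ",
         paste(bad, collapse = ", "))
  }
  incons <- which((x$copy_number < 2L) != (x$state == "deletion"))
  if (length(incons)) {
    stop("state inconsistent with copy_number for call row(s): ",
         paste(incons, collapse = ", "))
  }
  class(x) <- unique(c("cnv_calls", class(x)))
  x
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d calls, %d samples, caller(s): %s\n",
              nrow(x), length(unique(x$sample_id)),
              paste(unique(x$caller), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Drop exact duplicate (sample, caller, chrom, start, end) records, warning
# once; canonical order: sample, chrom, start, end.
dedup_calls <- function(x, context = "call set") {
  key <- paste(x$sample_id, x$caller, x$chrom, x$start, x$end, x$state)
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicate segment record(s) removed",
                    context, sum(duplicated(key))))
    x <- x[!duplicated(key), , drop = FALSE]
  }
  x[order(x$sample_id, x$chrom, x$start, x$end), , drop = FALSE]
}
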