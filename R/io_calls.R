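#' Read CNV calls from disk
#'
#' Two dialects are supported. `"bed_tsv"` is a tab-separated table with a
#' header line `sample_id chrom start end cn n_probes caller` and 1-based
#' inclusive coordinates. `"penncnv_raw"` is the whitespace-separated segment
#' format produced by HMM-based array CNV callers, one call per line:
#'
#' ```
#' chr6:31355318-31451476  numsnp=40  length=96,159  state2,cn=1  sampleA
#' ```
#'
#' The published tools ship no formal grammar for their text output, so this
#' reader is a reasonable reconstruction of the format: it requires the
#' `chrN:start-end` locus token, a `numsnp=` field, a `cn=` field (bare or as
#' part of a `stateK,cn=N` token) and takes the last bare token as the sample
#' identifier (a trailing `.txt` is stripped). Additional `key=value` tokens
#' (e.g. `startsnp=`, `endsnp=`, `length=`) are ignored.
#'
#' Malformed rows and rows with a copy number outside `{0,1,3,4}` are
#' rejected with their line numbers. Exact duplicate (sample, caller,
#' interval) records are removed with a warning.
#'
#' @param path path to the file.
#' @param dialect `"bed_tsv"` or `"penncnv_raw"`.
#' @param caller caller label to attach when the dialect does not carry one
#'   (`penncnv_raw`); default `"PennCNV"`.
#' @return A [cnv_calls] data.frame, sorted by sample, chrom, start.
#' @seealso [write_cnv_calls()], [write_bed()]
#' @export
read_cnv_calls <- function(path, dialect = c("bed_tsv", "penncnv_raw"),
                           caller = "PennCNV") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c(sample_id = "character",
                                           chrom = "character",
                                           caller = "character"))
    req <- c("sample_id", "chrom", "start", "end", "cn", "n_probes", "caller")
    miss <- setdiff(req, names(df))
    if (length(miss)) {
      stop("bed_tsv is missing column(s): ", paste(miss, collapse = ", "))
    }
    bad_cn <- which(!df$cn %in% c(0L, 1L, 3L, 4L))
    if (length(bad_cn)) {
      stop("unknown copy-number state in ", path, " at data line(s): ",
           paste(bad_cn, collapse = ", "))
    }
    out <- cnv_calls(df$sample_id, df$chrom, df$start, df$end, df$cn,
                     df$n_probes, df$caller)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(seq_along(lines), function(i) {
      parse_penncnv_line(lines[[i]], i)
    })
    errs <- vapply(parsed, function(p) p$error %||% "", character(1))
    if (any(nzchar(errs))) {
      stop("malformed penncnv_raw record(s):\n  ",
           paste(errs[nzchar(errs)], collapse = "\n  "))
    }
    recs <- do.call(rbind, lapply(parsed, `[[`, "row"))
    out <- cnv_calls(recs$sample_id, recs$chrom, recs$start, recs$end,
                     recs$cn, recs$n_probes, caller)
  }
  dedup_calls(out, context = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_penncnv_line <- function(line, lineno) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  fail <- function(msg) list(error = sprintf("line %d: %s", lineno, msg))
  m <- regmatches(toks[1],
                  regexec("^(chr)?([0-9XYMxym]+):([0-9]+)-([0-9]+)$", toks[1]))[[1]]
  if (length(m) == 0) return(fail("expected 'chrN:start-end' locus token"))
  cn_tok <- grep("cn=[0-9]+", toks, value = TRUE)
  if (length(cn_tok) == 0) return(fail("missing cn= field"))
  cn <- as.integer(sub(".*cn=([0-9]+).*", "\\1", cn_tok[1]))
  if (!cn %in% c(0L, 1L, 3L, 4L)) {
    return(fail(sprintf("unknown copy-number state cn=%d", cn)))
  }
  np_tok <- grep("^numsnp=", toks, value = TRUE)
  if (length(np_tok) == 0) return(fail("missing numsnp= field"))
  n_probes <- as.integer(sub("numsnp=", "", np_tok[1]))
  bare <- toks[-1][!grepl("=", toks[-1])]
  if (length(bare) == 0) return(fail("missing sample identifier token"))
  sample_id <- sub("\\.txt$", "", bare[length(bare)])
  list(error = NULL,
       row = data.frame(sample_id = sample_id, chrom = paste0("chr", m[3]),
                        start = as.integer(m[4]), end = as.integer(m[5]),
                        cn = cn, n_probes = n_probes,
                        stringsAsFactors = FALSE))
}

#' Write CNV calls
#'
#' `write_cnv_calls()` writes either dialect accepted by [read_cnv_calls()];
#' a write/read round trip reproduces the call set field by field (for
#' `penncnv_raw` the caller label is not encoded in the file and must be
#' re-supplied at read time). `write_bed()` exports to BED, converting the
#' package's 1-based inclusive coordinates to BED's 0-based half-open
#' convention at this boundary only.
#'
#' @param calls a [cnv_calls] data.frame.
#' @param path output path.
#' @param dialect `"bed_tsv"` or `"penncnv_raw"`.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path,
                            dialect = c("bed_tsv", "penncnv_raw")) {
  dialect <- match.arg(dialect)
  calls <- validate_cnv_calls(calls)
  if (dialect == "bed_tsv") {
    df <- data.frame(sample_id = calls$sample_id, chrom = calls$chrom,
                     start = calls$start, end = calls$end,
                     cn = calls$copy_number, n_probes = calls$n_probes,
                     caller = calls$caller)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    state_code <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)
    lines <- sprintf("%s:%d-%d numsnp=%d length=%s state%d,cn=%d %s",
                     calls$chrom, calls$start, calls$end, calls$n_probes,
                     formatC(calls$end - calls$start + 1L, big.mark = ",",
                             format = "d"),
                     state_code[as.character(calls$copy_number)],
                     calls$copy_number, calls$sample_id)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_cnv_calls
#' @export
write_bed <- function(calls, path) {
  calls <- validate_cnv_calls(calls)
  df <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                   end = calls$end,
                   name = paste(calls$sample_id, calls$state, sep = ":"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED input is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read. Zero-length records are rejected.
#'
#' @param path BED file with at least chrom, start, end and (optionally) a
#'   name column.
#' @return data.frame with columns `chrom`, `start`, `end`, `gene` (1-based
#'   inclusive).
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    gene = if (ncol(df) >= 4) as.character(df[[4]]) else
                      paste0("gene", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  bad <- which(out$end < out$start)
  if (length(bad)) {
    stop("zero-length gene interval(s) at row(s): ",
         paste(bad, collapse = ", "))
  }
  out
}
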