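#' Genetic maps: construction, reading, interpolation
#'
#' A genetic map relates physical position (bp, 1-based) to genetic position
#' (cM) through an ordered set of knots per chromosome. Positions between
#' knots are interpolated piecewise-linearly; positions beyond the terminal
#' knots are extrapolated with the terminal interval's recombination rate.
#' Interfaces use centimorgans; the age estimator works in Morgans
#' (1 M = 100 cM) internally.
#'
#' @param chrom chromosome label per knot.
#' @param pos physical position (bp) per knot; strictly increasing within a
#'   chromosome after sorting.
#' @param cM genetic position per knot; non-decreasing within a chromosome
#'   (a flat stretch encodes a recombination desert).
#' @return An object of class `genetic_map`.
#' @examples
#' gm <- genetic_map("chr1", seq(0, 1e7, by = 1e6), seq(0, 10, by = 1))
#' genetic_position(gm, "chr1", 5e6)  # 5 cM under a uniform 1 cM/Mb map
#' @export
genetic_map <- function(chrom, pos, cM) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   cM = as.numeric(cM), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) stop("genetic map needs >= 2 knots on ", ch)
    if (anyDuplicated(sub$pos)) {
      stop("duplicated physical position in genetic map on ", ch)
    }
    dc <- diff(sub$cM)
    if (any(dc < 0)) {
      i <- which(dc < 0)[1] + 1L
      stop(sprintf(
        "genetic positions decrease on %s at knot %d (pos=%d, cM=%.6g)",
        ch, i, as.integer(sub$pos[i]), sub$cM[i]))
    }
  }
  structure(list(knots = df), class = "genetic_map")
}

#' @rdname genetic_map
#' @param path 3-column table (chrom, bp, cM), tab- or space-separated, with
#'   or without a header; rows may arrive in any order.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "[\t ]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("genetic map needs 3 columns (chrom, bp, cM)")
  genetic_map(df[[1]], df[[2]], df[[3]])
}

#' @export
print.genetic_map <- function(x, ...) {
  k <- x$knots
  for (ch in unique(k$chrom)) {
    sub <- k[k$chrom == ch, ]
    cat(sprintf("<genetic_map> %s: %d knots, %.0f-%.0f bp, %.3f-%.3f cM\n",
                ch, nrow(sub), min(sub$pos), max(sub$pos), min(sub$cM),
                max(sub$cM)))
  }
  invisible(x)
}

#' @rdname genetic_map
#' @param map a `genetic_map`.
#' @param bp physical positions to convert (vector).
#' @export
genetic_position <- function(map, chrom, bp) {
  stopifnot(inherits(map, "genetic_map"))
  sub <- map$knots[map$knots$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stop("chromosome not in map: ", chrom)
  x <- sub$pos; y <- sub$cM
  n <- length(x)
  out <- stats::approx(x, y, xout = bp, rule = 2, ties = "ordered")$y
  r1 <- (y[2] - y[1]) / (x[2] - x[1])
  rn <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  lo <- bp < x[1]; hi <- bp > x[n]
  out[lo] <- y[1] - (x[1] - bp[lo]) * r1
  out[hi] <- y[n] + (bp[hi] - x[n]) * rn
  out
}

#' @rdname genetic_map
#' @param cM_query genetic positions (cM) to convert back to bp. Within a
#'   zero-recombination plateau the left edge of the plateau is returned.
#' @export
physical_position <- function(map, chrom, cM_query) {
  stopifnot(inherits(map, "genetic_map"))
  sub <- map$knots[map$knots$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) stop("chromosome not in map: ", chrom)
  x <- sub$pos; y <- sub$cM
  n <- length(x)
  vapply(cM_query, function(g) {
    if (g <= y[1]) {
      r <- (y[2] - y[1]) / (x[2] - x[1])
      return(x[1] - (y[1] - g) / r)
    }
    if (g >= y[n]) {
      r <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
      if (r <= 0) return(x[n])
      return(x[n] + (g - y[n]) / r)
    }
    i <- findInterval(g, y)          # y[i] <= g < y[i+1]
    if (y[i + 1] == y[i]) return(x[i])
    x[i] + (g - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
  }, numeric(1))
}

#' Genetic length of an interval
#'
#' @inheritParams genetic_position
#' @param start,end 1-based inclusive physical endpoints.
#' @return length in cM.
#' @export
genetic_length <- function(map, chrom, start, end) {
  genetic_position(map, chrom, end) - genetic_position(map, chrom, start)
}
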