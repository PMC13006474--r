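#' Phased haplotype sets
#'
#' Container for phased biallelic SNP haplotypes: an integer matrix with one
#' row per haplotype (two per sample, `"<sample>|1"` and `"<sample>|2"`) and
#' one column per SNP, alleles coded 0/1 with `NA` for missing. Columns are
#' sorted by position and deduplicated on construction.
#'
#' @param alleles integer matrix (haplotypes x SNPs), values in
#'   `{0, 1, NA}`.
#' @param positions physical positions (bp, 1-based), one per column.
#' @param sample_ids sample labels, one per pair of consecutive rows.
#' @param chrom chromosome label (single value or one per SNP).
#' @return An object of class `hap_set` with elements `alleles`,
#'   `positions`, `chrom`, `sample_ids`.
#' @export
hap_set <- function(alleles, positions, sample_ids, chrom = "chr1") {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(sample_ids)) {
    stop("need exactly two haplotype rows per sample")
  }
  if (ncol(alleles) != length(positions)) {
    stop("positions length must equal the number of SNP columns")
  }
  if (any(!alleles %in% c(0L, 1L, NA_integer_))) {
    stop("alleles must be 0, 1 or NA")
  }
  if (length(chrom) == 1L) chrom <- rep(chrom, length(positions))
  ord <- order(positions)
  positions <- positions[ord]; alleles <- alleles[, ord, drop = FALSE]
  chrom <- chrom[ord]
  dup <- duplicated(paste(chrom, positions))
  if (any(dup)) {
    warning(sum(dup), " duplicated SNP position(s) removed")
    alleles <- alleles[, !dup, drop = FALSE]
    positions <- positions[!dup]; chrom <- chrom[!dup]
  }
  dimnames(alleles) <- list(paste0(rep(sample_ids, each = 2), "|",
                                   c(1L, 2L)), NULL)
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 chrom = as.character(chrom),
                 sample_ids = as.character(sample_ids)),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes (%d samples) x %d SNPs, %s:%.0f-%.0f\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles),
              x$chrom[1], min(x$positions), max(x$positions)))
  invisible(x)
}

#' Extract the two haplotype rows of given samples
#'
#' @param haps a [hap_set].
#' @param samples sample ids.
#' @return integer matrix of haplotype rows.
#' @export
sample_haplotypes <- function(haps, samples) {
  miss <- setdiff(samples, haps$sample_ids)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  rows <- as.vector(rbind(paste0(samples, "|1"), paste0(samples, "|2")))
  haps$alleles[rows, , drop = FALSE]
}

#' Read and write phased haplotypes
#'
#' `hap_tsv` is a plain-text matrix dialect: a header line of `hap_id`
#' followed by the SNP physical positions, then one row per haplotype whose
#' first field is `<sample>|<1|2>` and remaining fields are alleles (0/1,
#' `NA` for missing). `phased_vcf` is a standard VCF whose GT fields must all
#' be phased (`a|b`); an unphased genotype is an error naming the sample and
#' site, and multiallelic sites are skipped with a warning.
#'
#' @param path input file.
#' @param dialect `"hap_tsv"` or `"phased_vcf"`.
#' @return A [hap_set].
#' @export
read_phased_haplotypes <- function(path, dialect = c("hap_tsv", "phased_vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "hap_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "hap_id") stop("hap_tsv must start with a hap_id column")
    ids <- df[[1]]
    samp <- sub("\\|[12]$", "", ids)
    sample_ids <- unique(samp)
    m <- as.matrix(df[, -1, drop = FALSE])
    ord <- as.vector(rbind(paste0(sample_ids, "|1"), paste0(sample_ids, "|2")))
    if (!setequal(ids, ord) || anyDuplicated(ids)) {
      stop("hap_tsv must contain exactly haplotypes <sample>|1 and <sample>|2")
    }
    m <- m[match(ord, ids), , drop = FALSE]
    hap_set(m, as.numeric(colnames(df)[-1]), sample_ids)
  } else {
    read_phased_vcf(path)
  }
}

read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(gt) == 0) stop("no biallelic sites in ", path)
  unphased <- matrix(grepl("/", gt), nrow = nrow(gt))
  if (any(unphased)) {
    idx <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype for sample %s at %s:%s",
                 colnames(gt)[idx[2]], fix[idx[1], "CHROM"],
                 fix[idx[1], "POS"]))
  }
  samples <- colnames(gt)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  to_int <- function(a) { a[a == "."] <- NA; matrix(as.integer(a), nrow = nrow(gt)) }
  h1 <- to_int(a1); h2 <- to_int(a2)   # SNPs x samples
  n <- length(samples)
  m <- matrix(NA_integer_, nrow = 2L * n, ncol = nrow(gt))
  m[seq(1, 2 * n, by = 2), ] <- t(h1)
  m[seq(2, 2 * n, by = 2), ] <- t(h2)
  hap_set(m, as.numeric(fix[, "POS"]), samples, chrom = fix[, "CHROM"])
}

#' @rdname read_phased_haplotypes
#' @param haps a [hap_set] to write.
#' @export
write_phased_haplotypes <- function(haps, path,
                                    dialect = c("hap_tsv", "phased_vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "hap_tsv") {
    df <- data.frame(hap_id = rownames(haps$alleles), haps$alleles,
                     check.names = FALSE)
    colnames(df) <- c("hap_id", format(haps$positions, scientific = FALSE,
                                       trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- length(haps$sample_ids)
    h1 <- haps$alleles[seq(1, 2 * n, by = 2), , drop = FALSE]
    h2 <- haps$alleles[seq(2, 2 * n, by = 2), , drop = FALSE]
    code <- function(m) { x <- as.character(m); x[is.na(x)] <- "."; x }
    gt <- matrix(paste0(code(t(h1)), "|", code(t(h2))), ncol = n)
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", haps$sample_ids), collapse = "\t"))
    body <- paste(haps$chrom, format(haps$positions, scientific = FALSE,
                                     trim = TRUE),
                  paste0("snp", seq_along(haps$positions)),
                  "A", "G", ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
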