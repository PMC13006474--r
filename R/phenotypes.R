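#' Phenotype tables
#'
#' One row per sample with age, sex and binary psychiatric diagnosis flags.
#' The derived column `any_psych` is the OR over all diagnosis flags
#' (including `aud`): the "any psychiatric diagnosis" phenotype.
#'
#' @param sample_id unique sample labels.
#' @param age age in years.
#' @param sex `"M"` or `"F"`.
#' @param aud logical, alcohol use disorder.
#' @param ... further named logical diagnosis flag vectors (e.g.
#'   `ptsd = ...`, `mdd = ...`).
#' @return data.frame of class `phenotype_table` with an `any_psych` column.
#' @export
phenotype_table <- function(sample_id, age, sex, aud, ...) {
  flags <- list(...)
  df <- data.frame(sample_id = as.character(sample_id),
                   age = as.numeric(age), sex = as.character(sex),
                   aud = as.logical(aud), stringsAsFactors = FALSE)
  for (nm in names(flags)) df[[nm]] <- as.logical(flags[[nm]])
  validate_phenotype_table(df)
}

#' @rdname phenotype_table
#' @param x data.frame with at least `sample_id`, `age`, `sex`, `aud`.
#' @export
validate_phenotype_table <- function(x) {
  req <- c("sample_id", "age", "sex", "aud")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) stop("sample_ids must be unique")
  if (!all(x$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  flag_cols <- setdiff(names(x), c("sample_id", "age", "sex", "any_psych"))
  for (nm in flag_cols) x[[nm]] <- as.logical(x[[nm]])
  x$any_psych <- Reduce(`|`, x[flag_cols])
  class(x) <- unique(c("phenotype_table", class(x)))
  x
}

#' @rdname phenotype_table
#' @param path TSV with a header: `sample_id`, `age`, `sex`, `aud` plus any
#'   further 0/1 or TRUE/FALSE diagnosis columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         sex = "character"))
  df$any_psych <- NULL
  validate_phenotype_table(df)
}

#' @rdname phenotype_table
#' @param pheno a `phenotype_table` to write.
#' @export
write_phenotypes <- function(pheno, path) {
  df <- as.data.frame(pheno)
  df$any_psych <- NULL
  flag_cols <- setdiff(names(df), c("sample_id", "age", "sex"))
  for (nm in flag_cols) df[[nm]] <- as.integer(df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
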