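#' Read an additive genotype matrix
#'
#' Two plain-text layouts are supported. `tsv_matrix`: tab-delimited, header
#' row of marker IDs, first column of sample IDs, entries 0/1/2 (NA allowed).
#' `plink_raw`: the PLINK `--recode A` additive format — space/tab delimited
#' with header `FID IID PAT MAT SEX PHENOTYPE <marker columns>`; IID is taken
#' as the sample ID.
#'
#' Missing dosages are a hard error by default: upstream imputation (e.g.
#' Beagle) is the norm for these data, and silently filling holes can mask
#' file problems. `impute = "mean"` replaces each missing entry with its
#' marker's mean dosage over non-missing samples (kept un-rounded so that
#' per-marker means are unchanged by imputation).
#'
#' @param path file path.
#' @param format `"tsv_matrix"` or `"plink_raw"`.
#' @param impute `"error"` (default) or `"mean"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv_matrix", "plink_raw"),
                           impute = c("error", "mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv_matrix") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            na.strings = "NA")
    sample_ids <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", na.strings = c("NA", "-9"))
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(df)[1:6]))
      stop("not a PLINK RAW file: expected leading columns ",
           paste(meta, collapse = " "), call. = FALSE)
    sample_ids <- df[["IID"]]
    m <- as.matrix(df[, -(1:6), drop = FALSE])
  }
  suppressWarnings(storage.mode(m) <- "double")
  g <- geno_matrix(m, sample_ids = sample_ids, marker_ids = colnames(m),
                   allow_missing = TRUE)
  if (anyNA(g)) {
    if (impute == "error")
      stop(sum(is.na(g)), " missing dosage(s) in ", path,
           "; re-run with impute = \"mean\" or impute upstream", call. = FALSE)
    g <- impute_mean(g)
  } else if (impute == "mean") {
    g <- impute_mean(g)
  }
  g
}

#' Mean-impute missing dosages per marker
#'
#' Each NA is replaced by the marker's mean dosage over non-missing samples.
#' Imputed values are left fractional so that every marker's mean is exactly
#' preserved; downstream models treat dosages as continuous covariates.
#'
#' @param g a genotype matrix (NA allowed).
#' @return matrix of class `"geno_matrix"` with no missing entries.
#' @export
impute_mean <- function(g) {
  m <- unclass(g)
  if (anyNA(m)) {
    cm <- colMeans(m, na.rm = TRUE)
    if (anyNA(cm))
      stop("marker(s) with all dosages missing: ",
           paste(colnames(m)[is.na(cm)], collapse = ", "), call. = FALSE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- cm[idx[, 2L]]
  }
  class(m) <- c("geno_matrix", class(m))
  m
}

#' Write a genotype matrix as a TSV matrix
#' @param g genotype matrix.
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(sample = rownames(g), unclass(g), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Tab-delimited with columns `genotype`, `environment`, `trait`, `value`
#' (optional `rep`). `NA` values are retained as missing records — they mask
#' untested cells, e.g. a held-out environment — rather than dropped.
#'
#' @param path file path.
#' @return validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA",
                          colClasses = "character")
  pheno_table(df)
}

#' Write a phenotype table
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a daily environmental series
#'
#' Tab-delimited with columns `environment`, `day`, `factor`, `value`.
#' After validation the series is harmonized: days are restricted to the
#' intersection of per-environment day ranges and factors to those present
#' in every environment (dropped factors raise a warning).
#'
#' @param path file path.
#' @param harmonize restrict to the shared day range and factor set
#'   (default TRUE).
#' @return validated (and harmonized) data.frame.
#' @export
read_env_series <- function(path, harmonize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (harmonize) harmonize_env_series(df) else env_series(df)
}

#' Write an environmental series
#' @param series env series data.frame.
#' @param path output path.
#' @export
write_env_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
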